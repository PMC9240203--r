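# shared fixture builders; everything is generated in code at test time

random_ts_image <- function(shape = c(6, 6, 6), Tn = 30, tr = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ts_image(array(rnorm(prod(shape) * Tn), dim = c(shape, Tn)), tr = tr)
}

cube_mask <- function(shape, x, y, z, affine = NULL) {
  m <- array(FALSE, dim = shape)
  m[x, y, z] <- TRUE
  if (is.null(affine)) brain_mask(m) else brain_mask(m, affine)
}

# brute-force NH oracle: full correlation matrix, row means without diagonal
nh_bruteforce <- function(img, mask) {
  d <- dim(img$data)
  idx <- which(mask$data)
  Y <- t(matrix(img$data, prod(d[1:3]), d[4])[idx, , drop = FALSE])
  R <- cor(Y)
  diag(R) <- NA
  nh <- rowMeans(R, na.rm = TRUE)
  atanh(pmin(pmax(nh, -(1 - 1e-7)), 1 - 1e-7))
}

# tiny standardized NH map directly from values on a mask
values_as_nh_map <- function(vals, mask, stage = "standardized", id = "s") {
  arr <- array(NA_real_, dim = dim(mask$data))
  arr[mask$data] <- vals
  nh_map(arr, mask$affine, stage, id)
}

# flood-fill oracle for connected components via repeated dilation
flood_fill_oracle <- function(binary, connectivity) {
  offs <- nethom:::neighbor_offsets(connectivity)
  shape <- dim(binary)
  remaining <- which(binary)
  comps <- list()
  visited <- rep(FALSE, prod(shape))
  to_ijk <- function(l) nethom:::linear_to_ijk(l, shape)
  to_lin <- function(ijk) {
    (ijk[3] - 1L) * shape[1] * shape[2] + (ijk[2] - 1L) * shape[1] + ijk[1]
  }
  for (s in remaining) {
    if (visited[s]) next
    members <- s; visited[s] <- TRUE
    queue <- list(to_ijk(s))
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1L) || any(q > shape)) next
        l <- unname(to_lin(q))
        if (binary[l] && !visited[l]) {
          visited[l] <- TRUE
          members <- c(members, l)
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps[order(vapply(comps, min, 1L))]
}
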