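#' Compute a network-homogeneity map
#'
#' Network homogeneity (NH) of voxel i is the mean Pearson correlation of its
#' time series with the series of every *other* voxel in the network mask
#' (self-correlation excluded, denominator N - 1). The mean correlation is
#' then Fisher z-transformed, `z = atanh(r)`, with |r| clipped at `1 - 1e-7`
#' so degenerate inputs stay finite.
#'
#' The implementation standardizes each in-mask series to zero mean and unit
#' norm, so that `sum_j r_ij = x_i . S` with `S = sum_j x_j`; this is O(N*T)
#' and equals the O(N^2*T) correlation-matrix row mean exactly.
#'
#' @param img a [ts_image].
#' @param mask a [brain_mask] with at least 2 voxels, on the same grid.
#' @param subject_id optional id carried on the result.
#' @return an [nh_map] at stage `"fisher_z"`.
#' @export
compute_nh_map <- function(img, mask, subject_id = NA_character_) {
  stopifnot(inherits(img, "ts_image"), inherits(mask, "brain_mask"))
  d <- dim(img$data)
  if (!all(dim(mask$data) == d[1:3]) ||
      max(abs(mask$affine - img$affine)) > 1e-6)
    stop("mask and image must share grid and affine")
  idx <- which(mask$data)
  N <- length(idx)
  if (N < 2L) stop("mask must contain at least 2 voxels")
  if (d[4] < 3L) stop("need at least 3 time points")
  Y <- matrix(img$data, prod(d[1:3]), d[4])[idx, , drop = FALSE]  # N x T
  Y <- Y - rowMeans(Y)
  nrm <- sqrt(rowSums(Y^2))
  bad <- nrm < .Machine$double.eps * d[4]
  if (any(bad))
    stop("constant time series inside mask at voxel(s): ",
         paste(head(idx[bad], 10L), collapse = ", "))
  X <- Y / nrm
  S <- colSums(X)
  nh <- (as.numeric(X %*% S) - 1) / (N - 1)
  z <- atanh(pmin(pmax(nh, -(1 - 1e-7)), 1 - 1e-7))
  out <- rep(NA_real_, prod(d[1:3]))
  out[idx] <- z
  nh_map(array(out, dim = d[1:3]), img$affine, "fisher_z", subject_id)
}

#' Standardize an NH map over the mask
#'
#' Subtracts the in-mask mean and divides by the in-mask SD, yielding the
#' subject-level standardized map used for group comparison. Out-of-mask
#' voxels stay `NA`.
#'
#' @param nh an [nh_map] at stage `"fisher_z"`.
#' @return an [nh_map] at stage `"standardized"`.
#' @export
standardize_nh_map <- function(nh) {
  stopifnot(inherits(nh, "nh_map"))
  if (nh$stage != "fisher_z")
    stop("expected a 'fisher_z' stage map, got '", nh$stage, "'")
  v <- nh$data[!is.na(nh$data)]
  s <- sd(v)
  if (!is.finite(s) || s == 0) stop("zero SD over the mask")
  out <- (nh$data - mean(v)) / s
  nh_map(out, nh$affine, "standardized", nh$subject_id)
}

#' NH values as a subject x voxel matrix
#'
#' Stacks a list of NH maps (shared mask) into a matrix for auditing or
#' export; column order is the mask's linear voxel order.
#'
#' @param maps list of [nh_map]s on identical grids.
#' @return numeric matrix, one row per map.
#' @export
nh_matrix <- function(maps) {
  stopifnot(length(maps) >= 1L)
  idx <- which(!is.na(maps[[1]]$data))
  out <- matrix(NA_real_, length(maps), length(idx))
  for (i in seq_along(maps)) {
    stopifnot(inherits(maps[[i]], "nh_map"))
    if (!all(dim(maps[[i]]$data) == dim(maps[[1]]$data)))
      stop("maps must share grids")
    out[i, ] <- maps[[i]]$data[idx]
  }
  rownames(out) <- vapply(maps, function(m) as.character(m$subject_id), "")
  out
}
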