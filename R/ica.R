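#' Two-stage dimension reduction for group spatial ICA
#'
#' Standard group-ICA reduction: each subject's time dimension is reduced to
#' `subject_components` principal components, the reduced data are
#' concatenated over subjects along the (reduced) time axis, and a second
#' PCA takes the concatenation down to `n_components` whitened rows. The
#' projection operators are stored for back reconstruction.
#'
#' @param images list of [ts_image]s on a shared grid.
#' @param n_components final (group-level) component count.
#' @param mask optional [brain_mask] restricting the analysis; default all
#'   voxels.
#' @param subject_components per-subject PCA order (default
#'   `max(n_components, min(30, T - 1))` capped at usable rank).
#' @return an object of class `gica_reduction` holding the whitened group
#'   data and projection operators.
#' @export
group_reduce <- function(images, n_components, mask = NULL,
                         subject_components = NULL) {
  if (length(images) < 2L) stop("need at least 2 subjects")
  d0 <- dim(images[[1]]$data)[1:3]
  for (im in images)
    if (!all(dim(im$data)[1:3] == d0) ||
        max(abs(im$affine - images[[1]]$affine)) > 1e-6)
      stop("all images must share grid and affine")
  if (is.null(mask)) {
    maskvec <- rep(TRUE, prod(d0))
  } else {
    if (!all(dim(mask$data) == d0)) stop("mask grid mismatch")
    maskvec <- as.vector(mask$data)
  }
  V <- sum(maskvec)
  Tn <- min(vapply(images, function(im) dim(im$data)[4], 1L))
  if (is.null(subject_components))
    subject_components <- min(max(n_components, min(30L, Tn - 1L)), Tn - 1L)
  p <- as.integer(subject_components)
  if (n_components > p * length(images))
    stop("n_components exceeds total retained dimensions")
  if (p >= Tn) stop("too few time points for ", p, " subject components")

  n <- length(images)
  C <- matrix(0, n * p, V)
  proj <- vector("list", n)
  for (s in seq_len(n)) {
    d <- dim(images[[s]]$data)
    X <- t(matrix(images[[s]]$data, prod(d[1:3]), d[4]))[, maskvec, drop = FALSE]
    X <- X[seq_len(Tn), , drop = FALSE]
    X <- X - rowMeans(X)                  # remove per-volume mean
    X <- sweep(X, 2L, colMeans(X))        # demean voxels over time
    e <- eigen(tcrossprod(X) / V, symmetric = TRUE)
    U <- e$vectors[, seq_len(p), drop = FALSE]
    C[((s - 1) * p + 1):(s * p), ] <- t(U) %*% X
    proj[[s]] <- U
  }
  e2 <- eigen(tcrossprod(C) / V, symmetric = TRUE)
  lam <- pmax(e2$values[seq_len(n_components)], .Machine$double.eps)
  U2 <- e2$vectors[, seq_len(n_components), drop = FALSE]
  G <- diag(1 / sqrt(lam), n_components) %*% t(U2) %*% C
  structure(list(
    white = G,                # n_components x V, rows uncorrelated, unit var
    mask = maskvec, grid = d0, affine = images[[1]]$affine,
    subject_proj = proj, group_proj = U2, group_eigen = lam,
    all_eigen = pmax(e2$values, 0),
    n_components = as.integer(n_components), subject_components = p,
    n_subjects = n, n_time = Tn), class = "gica_reduction")
}

logcosh_g <- function(u) tanh(u)
logcosh_gprime <- function(u) 1 - tanh(u)^2

sym_decorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                     nrow(W)) %*% t(e$vectors) %*% W
}

row_skewness <- function(M) {
  mu <- rowMeans(M)
  X <- M - mu
  s2 <- rowMeans(X^2)
  rowMeans(X^3) / (s2^1.5 + .Machine$double.eps)
}

#' Fixed-point spatial ICA on reduced group data
#'
#' FastICA-style unmixing by negentropy maximization (log-cosh contrast) on
#' the whitened group data, either one component at a time with deflation
#' (default: the most non-Gaussian, i.e. structured, components stabilize
#' first and are unaffected by noise-only directions) or with the symmetric
#' simultaneous update. Deterministic given `seed`. Each spatial map is
#' z-scaled over in-mask voxels and sign-fixed so its skewness is
#' non-negative.
#'
#' @param reduced a `gica_reduction` from [group_reduce()].
#' @param n_components number of components; must equal the reduction order.
#' @param seed integer seed for the random orthogonal initialization.
#' @param method `"deflation"` (default) or `"symmetric"`.
#' @param max_iter,tol fixed-point iteration controls.
#' @param restarts number of fresh (seed-derived) initializations tried
#'   before giving up; non-convergence after all restarts is an error
#'   carrying the iteration count.
#' @param nonconvergence `"error"` (default) or `"warn"`. Components carrying
#'   only Gaussian noise have a flat negentropy objective and can rotate
#'   indefinitely without affecting the structured components, so pipeline
#'   use tolerates non-convergence with a warning while the strict default
#'   keeps the operation's error contract.
#' @return an object of class `component_set`: `maps` (components x voxels,
#'   z-scaled), `unmixing`, per-subject `timecourses`, `explained_variance`.
#' @export
separate_components <- function(reduced, n_components = reduced$n_components,
                                seed = 1L, method = c("deflation", "symmetric"),
                                max_iter = 200L, tol = 1e-6, restarts = 5L,
                                nonconvergence = c("error", "warn")) {
  nonconvergence <- match.arg(nonconvergence)
  method <- match.arg(method)
  stopifnot(inherits(reduced, "gica_reduction"))
  if (n_components != reduced$n_components)
    stop("n_components must match the reduction order")
  X <- reduced$white
  nc <- nrow(X)
  V <- ncol(X)
  fail <- function(it, delta) {
    msg <- paste0("ICA failed to converge after ", restarts, " restarts of ",
                  max_iter, " iterations (last delta = ", signif(delta, 3), ")")
    if (nonconvergence == "error") stop(msg)
    warning(msg, "; returning the final iterate")
  }
  it <- 0L
  if (method == "symmetric") {
    W <- NULL; delta <- Inf
    for (attempt in seq_len(restarts)) {
      set.seed(as.integer((seed + (attempt - 1L) * 104729) %% 2147483647))
      W <- sym_decorrelate(matrix(rnorm(nc * nc), nc, nc))
      it <- 0L
      converged <- FALSE
      while (it < max_iter) {
        it <- it + 1L
        U <- W %*% X
        Wn <- (logcosh_g(U) %*% t(X)) / V -
          diag(rowMeans(logcosh_gprime(U)), nc) %*% W
        Wn <- sym_decorrelate(Wn)
        delta <- max(abs(1 - abs(rowSums(Wn * W))))
        W <- Wn
        if (delta < tol) { converged <- TRUE; break }
      }
      if (converged) break
      if (attempt == restarts) fail(it, delta)
    }
  } else {
    # deflation: extract components one by one, orthogonal to previous ones
    W <- matrix(0, nc, nc)
    total_it <- 0L
    for (comp in seq_len(nc)) {
      done <- FALSE
      for (attempt in seq_len(restarts)) {
        set.seed(as.integer((seed + comp * 7907 +
                             (attempt - 1L) * 104729) %% 2147483647))
        w <- rnorm(nc)
        if (comp > 1L) {
          prev <- W[seq_len(comp - 1L), , drop = FALSE]
          w <- w - as.numeric(t(prev) %*% (prev %*% w))
        }
        w <- w / sqrt(sum(w^2))
        delta <- Inf
        for (i in seq_len(max_iter)) {
          total_it <- total_it + 1L
          u <- as.numeric(w %*% X)
          wn <- as.numeric(X %*% logcosh_g(u)) / V -
            mean(logcosh_gprime(u)) * w
          if (comp > 1L) {
            prev <- W[seq_len(comp - 1L), , drop = FALSE]
            wn <- wn - as.numeric(t(prev) %*% (prev %*% wn))
          }
          wn <- wn / sqrt(sum(wn^2))
          delta <- 1 - abs(sum(wn * w))
          w <- wn
          if (delta < tol) break
        }
        if (delta < tol) { done <- TRUE; W[comp, ] <- w; break }
        W[comp, ] <- w
        if (attempt == restarts) fail(max_iter, delta)
      }
      if (!done && nonconvergence == "error") break
    }
    it <- total_it
  }
  S <- W %*% X
  # z-scale and fix sign by skewness
  S <- (S - rowMeans(S)) / apply(S, 1L, sd)
  flip <- ifelse(row_skewness(S) < 0, -1, 1)
  S <- S * flip

  # per-subject time courses by back reconstruction through the projections
  p <- reduced$subject_components
  A <- t(W)    # whitened mixing (orthogonal)
  tcs <- lapply(seq_len(reduced$n_subjects), function(s) {
    rows <- ((s - 1) * p + 1):(s * p)
    # subject-space mixing: U_s %*% U2[rows,] %*% diag(sqrt(lam)) %*% A
    M <- reduced$subject_proj[[s]] %*%
      reduced$group_proj[rows, , drop = FALSE] %*%
      diag(sqrt(reduced$group_eigen), reduced$n_components) %*% A
    sweep(M, 2L, flip, "*")
  })
  ev <- reduced$group_eigen / sum(reduced$all_eigen)
  structure(list(maps = S, unmixing = W, flip = flip, timecourses = tcs,
                 explained_variance = ev, mask = reduced$mask,
                 grid = reduced$grid, affine = reduced$affine,
                 iterations = it, seed = as.integer(seed)),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components over %d voxels (%d iterations)\n",
              nrow(x$maps), ncol(x$maps), x$iterations))
  invisible(x)
}

component_volume <- function(components, index) {
  v <- rep(NA_real_, prod(components$grid))
  v[components$mask] <- components$maps[index, ]
  array(v, dim = components$grid)
}

#' Select the component best matching a network template
#'
#' Returns the component whose absolute z-map has the highest Pearson
#' correlation with the binary template over in-mask voxels. Ties break to
#' the lower index.
#'
#' @param components a `component_set`.
#' @param template a [brain_mask] on the same grid.
#' @return list with `index` and `score`, plus all per-component scores.
#' @export
select_dmn_component <- function(components, template) {
  stopifnot(inherits(components, "component_set"),
            inherits(template, "brain_mask"))
  if (!all(dim(template$data) == components$grid)) stop("template grid mismatch")
  tv <- as.numeric(template$data)[components$mask]
  if (sum(tv) == 0) stop("empty template")
  if (stats::sd(tv) == 0) {
    # degenerate all-brain template: fall back to mean |z|
    scores <- rowMeans(abs(components$maps))
  } else {
    scores <- apply(abs(components$maps), 1L, function(m) {
      if (stats::sd(m) == 0) return(-Inf)
      stats::cor(m, tv)
    })
  }
  idx <- which.max(scores)          # which.max takes the first (lowest) index
  list(index = unname(idx), score = unname(scores[idx]), scores = scores)
}

#' Threshold a component into a network mask
#'
#' Voxels with component z above `z_threshold` (intersected with the in-brain
#' mask) become the network mask; provenance (component index, threshold,
#' template match score) travels with the result.
#'
#' @param components a `component_set`.
#' @param index component index.
#' @param z_threshold positive z threshold (default 1.5).
#' @param match_score optional template score recorded as provenance.
#' @return a [brain_mask] with a `provenance` attribute.
#' @export
build_dmn_mask <- function(components, index, z_threshold = 1.5,
                           match_score = NA_real_) {
  stopifnot(inherits(components, "component_set"))
  if (z_threshold < 0) stop("'z_threshold' must be >= 0")
  sel <- components$maps[index, ] > z_threshold
  if (!any(sel)) stop("empty mask at z threshold ", z_threshold)
  v <- rep(FALSE, prod(components$grid))
  v[which(components$mask)[sel]] <- TRUE
  m <- brain_mask(array(v, dim = components$grid), affine = components$affine)
  attr(m, "provenance") <- list(component = index, z_threshold = z_threshold,
                                match_score = match_score)
  m
}

#' Derive a DMN mask from a set of subjects by group ICA
#'
#' Convenience wrapper: reduce, unmix, select by template, threshold.
#'
#' @param images list of [ts_image]s (conventionally the control group).
#' @param template a [brain_mask] template of the expected network.
#' @param n_components ICA model order (default 20).
#' @param z_threshold mask threshold (default 1.5).
#' @param seed ICA seed.
#' @param subject_components optional subject-level PCA order.
#' @param nonconvergence see [separate_components()]; the pipeline default
#'   tolerates non-convergence of noise-only components with a warning.
#' @return a [brain_mask] with provenance, as from [build_dmn_mask()].
#' @export
extract_dmn_mask <- function(images, template, n_components = 20L,
                             z_threshold = 1.5, seed = 1L,
                             subject_components = NULL,
                             nonconvergence = "warn") {
  red <- group_reduce(images, n_components,
                      subject_components = subject_components)
  comps <- separate_components(red, seed = seed,
                               nonconvergence = nonconvergence)
  sel <- select_dmn_component(comps, template)
  build_dmn_mask(comps, sel$index, z_threshold, match_score = sel$score)
}
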