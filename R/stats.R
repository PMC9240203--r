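#' Voxel-wise two-sample t map
#'
#' Pooled-variance (Student) two-sample t test at every in-mask voxel, with
#' the sign convention group A minus group B (patients minus controls).
#' Voxels with zero pooled variance get t = 0 with a warning.
#'
#' @param maps_a,maps_b lists of [nh_map]s (standardized stage) per group.
#' @param mask a [brain_mask] shared by all maps.
#' @param welch use Welch's unequal-variance t instead of pooled (default
#'   FALSE).
#' @return an object of class `t_map`: 3-D `t` and `p` arrays (`NA` outside
#'   the mask), degrees of freedom, group sizes.
#' @export
voxelwise_two_sample_t <- function(maps_a, maps_b, mask, welch = FALSE) {
  n1 <- length(maps_a); n2 <- length(maps_b)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 subjects per group")
  idx <- which(mask$data)
  A <- t(vapply(maps_a, function(m) m$data[idx], numeric(length(idx))))
  B <- t(vapply(maps_b, function(m) m$data[idx], numeric(length(idx))))
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- apply(A, 2L, var); v2 <- apply(B, 2L, var)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    tv <- (m1 - m2) / sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    tv <- (m1 - m2) / sqrt(se2)
    df <- rep(n1 + n2 - 2, length(tv))
  }
  zerovar <- !is.finite(tv)
  if (any(zerovar)) {
    warning(sum(zerovar), " voxel(s) with zero pooled variance; t set to 0")
    tv[zerovar] <- 0
  }
  pv <- 2 * pt(-abs(tv), df)
  shape <- dim(mask$data)
  tarr <- array(NA_real_, shape); tarr[idx] <- tv
  parr <- array(NA_real_, shape); parr[idx] <- pv
  structure(list(t = tarr, p = parr, df = if (welch) df else n1 + n2 - 2,
                 n1 = n1, n2 = n2, affine = mask$affine, mask = mask),
            class = "t_map")
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' @param n1,mean1,sd1 first group size, mean, SD.
#' @param n2,mean2,sd2 second group size, mean, SD.
#' @return list with `t`, `df` (= n1 + n2 - 2) and two-sided `p`.
#' @export
ttest_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tv <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tv, df = df, p = 2 * pt(-abs(tv), df))
}

#' Pearson chi-square test for a 2 x 2 table
#'
#' @param counts 2 x 2 matrix of non-negative counts.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with `chisq`, `df` (= 1) and `p`.
#' @export
chi_square_2x2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)) || any(counts < 0))
    stop("'counts' must be a non-negative 2 x 2 table")
  n <- sum(counts)
  if (n == 0) stop("empty table")
  E <- outer(rowSums(counts), colSums(counts)) / n
  if (any(E == 0)) stop("zero marginal")
  dev <- abs(counts - E)
  if (correct) dev <- pmax(dev - 0.5, 0)
  x2 <- sum(dev^2 / E)
  list(chisq = x2, df = 1L, p = pchisq(x2, 1L, lower.tail = FALSE))
}

#' Pearson correlation with two-sided p
#'
#' Pairs with a missing member are dropped listwise.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `n` (pairs used) and two-sided `p` from
#'   `t = r * sqrt((n - 2) / (1 - r^2))`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  r <- cor(x, y)
  if (abs(r) >= 1) return(list(r = r, n = n, p = 0))
  tv <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, n = n, p = 2 * pt(-abs(tv), n - 2))
}

#' Estimate field smoothness from residual maps
#'
#' Kiebel-style estimator: each residual map is standardized to unit
#' variance over the mask, the variance of first spatial differences between
#' adjacent in-mask voxels gives the derivative variance per axis, and
#' `FWHM_axis = sqrt(4 * log(2) / lambda_axis)` voxels (floored at 1 voxel).
#' RESELs = mask voxels / prod(FWHM in voxels).
#'
#' @param residual_maps list of 3-D arrays or [nh_map]s (`NA` outside mask).
#' @param mask a [brain_mask].
#' @return an object of class `smoothness_estimate`: `fwhm_mm`, `fwhm_vox`
#'   (per axis), `resels`, `n_maps`.
#' @export
estimate_smoothness <- function(residual_maps, mask) {
  if (length(residual_maps) < 3L) stop("need at least 3 residual maps")
  shape <- dim(mask$data)
  idx <- mask$data
  if (sum(idx) < 8L) stop("mask too small for gradient estimation")
  # in-mask adjacent pairs per axis, computed once
  pairs <- lapply(1:3, function(a) {
    n <- shape[a]
    if (n < 2L) return(NULL)
    lo <- slice_index(shape, a, 1:(n - 1))
    hi <- slice_index(shape, a, 2:n)
    ok <- idx[lo] & idx[hi]
    cbind(lo[ok], hi[ok])
  })
  ssq <- c(0, 0, 0); cnt <- c(0, 0, 0)
  for (m in residual_maps) {
    arr <- if (inherits(m, "nh_map")) m$data else m
    v <- arr[idx]
    arr <- (arr - mean(v)) / sd(v)
    for (a in 1:3) {
      pr <- pairs[[a]]
      if (is.null(pr) || nrow(pr) == 0L) next
      dd <- (arr[pr[, 2]] - arr[pr[, 1]])^2
      ssq[a] <- ssq[a] + sum(dd); cnt[a] <- cnt[a] + nrow(pr)
    }
  }
  m <- ifelse(cnt > 0, ssq / cnt, Inf)
  # discrete first differences underestimate the derivative variance of a
  # smooth field; invert the Gaussian-ACF relation m = 2(1 - exp(-lambda/2))
  lambda <- ifelse(is.finite(m) & m < 2, -2 * log(pmax(1 - m / 2, 1e-12)), m)
  fwhm_vox <- pmax(sqrt(4 * log(2) / lambda), 1)
  fwhm_vox[!is.finite(fwhm_vox)] <- 1
  vs <- voxel_sizes(mask$affine)
  structure(list(fwhm_vox = fwhm_vox, fwhm_mm = fwhm_vox * vs,
                 resels = sum(idx) / prod(fwhm_vox),
                 n_maps = length(residual_maps)),
            class = "smoothness_estimate")
}

# linear indices of the slab where axis `a` takes values `vals`
slice_index <- function(shape, a, vals) {
  args <- lapply(shape, seq_len)
  args[[a]] <- vals
  g <- as.matrix(do.call(expand.grid, args))
  (g[, 3] - 1L) * shape[1] * shape[2] + (g[, 2] - 1L) * shape[1] + g[, 1]
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(g)) == 1,
                 "18" = rowSums(abs(g)) <= 2,
                 "26" = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Label connected suprathreshold components
#'
#' Flood-fill connected-component labeling of a binary 3-D map under 6-, 18-
#' or 26-neighbourhood connectivity. For each component the extent, the peak
#' |statistic| voxel (ties broken by smallest linear index) and its world
#' coordinates are reported.
#'
#' @param binary logical 3-D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param stat optional 3-D array of statistic values for peak finding;
#'   defaults to the binary map itself.
#' @param affine optional 4x4 affine for world coordinates.
#' @return list of components, each with `voxels` (linear indices), `extent`,
#'   `peak_index` (1-based i, j, k), `peak_stat`, `peak_world`.
#' @export
label_clusters <- function(binary, connectivity = 26, stat = NULL,
                           affine = NULL) {
  shape <- dim(binary)
  if (length(shape) != 3L) stop("'binary' must be 3-D")
  offs <- neighbor_offsets(connectivity)
  if (is.null(stat)) stat <- array(as.numeric(binary), shape)
  remaining <- which(binary)
  labels <- integer(prod(shape))
  comps <- list()
  for (seed in remaining) {
    if (labels[seed] != 0L) next
    lab <- length(comps) + 1L
    frontier <- seed
    labels[seed] <- lab
    members <- seed
    while (length(frontier) > 0L) {
      k0 <- (frontier - 1L) %/% (shape[1] * shape[2])
      r <- (frontier - 1L) %% (shape[1] * shape[2])
      j0 <- r %/% shape[1]
      i0 <- r %% shape[1]
      cand <- integer(0)
      for (o in seq_len(nrow(offs))) {
        ii <- i0 + offs[o, 1]; jj <- j0 + offs[o, 2]; kk <- k0 + offs[o, 3]
        ok <- ii >= 0 & ii < shape[1] & jj >= 0 & jj < shape[2] &
          kk >= 0 & kk < shape[3]
        if (!any(ok)) next
        lin <- ii[ok] + jj[ok] * shape[1] + kk[ok] * shape[1] * shape[2] + 1L
        cand <- c(cand, lin)
      }
      cand <- unique(cand)
      cand <- cand[binary[cand] & labels[cand] == 0L]
      labels[cand] <- lab
      members <- c(members, cand)
      frontier <- cand
    }
    members <- sort(members)
    sv <- stat[members]
    peak <- members[which.max(abs(sv))]   # first max = smallest linear index
    pk <- linear_to_ijk(peak, shape)
    comp <- list(voxels = members, extent = length(members),
                 peak_linear = peak, peak_index = pk,
                 peak_stat = stat[peak],
                 peak_world = if (!is.null(affine))
                   voxel_to_world(pk - 1L, affine) else NULL)
    comps[[lab]] <- comp
  }
  comps
}

linear_to_ijk <- function(lin, shape) {
  k <- (lin - 1L) %/% (shape[1] * shape[2])
  r <- (lin - 1L) %% (shape[1] * shape[2])
  c(r %% shape[1] + 1L, r %/% shape[1] + 1L, k + 1L)
}

# Worsley's EC densities for a t field with df nu, per unit resel,
# dimensions 0..3
ec_density_t <- function(u, nu, dim) {
  base <- (1 + u^2 / nu)^(-(nu - 1) / 2)
  switch(as.character(dim),
    "0" = pt(u, nu, lower.tail = FALSE),
    "1" = sqrt(4 * log(2)) / (2 * pi) * base,
    "2" = 4 * log(2) / (2 * pi)^1.5 *
      exp(lgamma((nu + 1) / 2) - lgamma(nu / 2)) / sqrt(nu / 2) * u * base,
    "3" = (4 * log(2))^1.5 / (2 * pi)^2 *
      ((nu - 1) / nu * u^2 - 1) * base,
    stop("dim must be 0..3"))
}

# Worsley/SPM-style resel counts of a voxel mask: counts of in-mask points,
# edges, faces and cubes combined with the per-axis FWHM (in voxels)
resel_counts <- function(mask, fwhm_vox) {
  m <- mask
  shape <- dim(m)
  r <- fwhm_vox
  shift <- function(arr, axis) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[axis]] <- seq_len(shape[axis] - 1L)
    lo <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    idx[[axis]] <- seq_len(shape[axis] - 1L) + 1L
    hi <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    lo & hi
  }
  P <- sum(m)
  ex <- shift(m, 1); ey <- shift(m, 2); ez <- shift(m, 3)
  Ex <- sum(ex); Ey <- sum(ey); Ez <- sum(ez)
  fxy <- shift(ex, 2); fxz <- shift(ex, 3); fyz <- shift(ey, 3)
  Fxy <- sum(fxy); Fxz <- sum(fxz); Fyz <- sum(fyz)
  C <- sum(shift(fxy, 3))
  c(R0 = P - (Ex + Ey + Ez) + (Fxy + Fxz + Fyz) - C,
    R1 = (Ex - Fxy - Fxz + C) / r[1] + (Ey - Fxy - Fyz + C) / r[2] +
         (Ez - Fxz - Fyz + C) / r[3],
    R2 = (Fxy - C) / (r[1] * r[2]) + (Fxz - C) / (r[1] * r[3]) +
         (Fyz - C) / (r[2] * r[3]),
    R3 = C / prod(r))
}

#' Cluster-level p value under Gaussian random field theory
#'
#' Expected-cluster-count approximation for a thresholded t field: the
#' expected number of clusters is `Em = sum_d R_d * rho_d(u)` over the
#' resel counts of the search region and the t-field Euler-characteristic
#' densities, the expected suprathreshold volume is `R3 * P(T > u)`,
#' cluster sizes follow the standard two-thirds-power exponential form, and
#' the corrected p for a cluster of `k_resels` is `1 - exp(-Em * P(n >= k))`.
#'
#' @param k_resels cluster extent in resel units.
#' @param u cluster-forming threshold (t units, one-sided).
#' @param df t degrees of freedom.
#' @param resels resel counts: either the scalar volume count R3 or the full
#'   length-4 vector `c(R0, R1, R2, R3)`.
#' @return corrected cluster-level p in (0, 1].
#' @export
grf_cluster_p <- function(k_resels, u, df, resels) {
  if (length(resels) == 1L) resels <- c(0, 0, 0, resels)
  Em <- sum(vapply(0:3, function(d) resels[d + 1] * ec_density_t(u, df, d), 1))
  if (!is.finite(Em) || Em <= 0) return(1)
  EN <- resels[4] * pt(u, df, lower.tail = FALSE)
  En <- EN / Em
  if (En <= 0) return(1)
  beta <- (gamma(2.5) / En)^(2 / 3)
  pk <- exp(-beta * k_resels^(2 / 3))
  pmin(1, pmax(1 - exp(-Em * pk), .Machine$double.xmin))
}

#' GRF-corrected cluster inference on a t map
#'
#' Two-sided inference run as two one-sided analyses at `voxel_p / 2`:
#' voxels with `t > u` and voxels with `t < -u` (where
#' `u = qt(1 - voxel_p / 2, df)`) are clustered separately, each cluster's
#' corrected p comes from [grf_cluster_p()], and clusters with corrected
#' p below `cluster_p` survive.
#'
#' @param tmap a `t_map` from [voxelwise_two_sample_t()].
#' @param smoothness a `smoothness_estimate`.
#' @param voxel_p two-sided cluster-forming voxel threshold (default 0.001).
#' @param cluster_p cluster-level significance (default 0.01).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return data frame of surviving clusters: direction, extent, peak t,
#'   peak voxel (i, j, k), peak world x/y/z, corrected p; plus a `clusters`
#'   attribute with the full component lists (including voxel indices).
#' @export
grf_cluster_inference <- function(tmap, smoothness, voxel_p = 0.001,
                                  cluster_p = 0.01, connectivity = 26) {
  stopifnot(inherits(tmap, "t_map"), inherits(smoothness, "smoothness_estimate"))
  if (voxel_p <= 0 || voxel_p >= 1 || cluster_p <= 0 || cluster_p >= 1)
    stop("thresholds must be in (0, 1)")
  df <- tmap$df[1]
  u <- qt(1 - voxel_p / 2, df)
  resel_per_vox <- 1 / prod(smoothness$fwhm_vox)
  rcounts <- resel_counts(tmap$mask$data, smoothness$fwhm_vox)
  rows <- list(); keep <- list()
  tarr <- tmap$t
  for (dir in c("pos", "neg")) {
    bin <- if (dir == "pos") !is.na(tarr) & tarr > u else !is.na(tarr) & tarr < -u
    if (!any(bin)) next
    comps <- label_clusters(bin, connectivity, stat = tarr, affine = tmap$affine)
    for (cl in comps) {
      pcorr <- grf_cluster_p(cl$extent * resel_per_vox, u, df, rcounts)
      if (pcorr < cluster_p) {
        cl$direction <- if (dir == "pos") "A>B" else "A<B"
        cl$p_corrected <- pcorr
        keep[[length(keep) + 1L]] <- cl
        rows[[length(rows) + 1L]] <- data.frame(
          direction = cl$direction, extent = cl$extent,
          peak_t = cl$peak_stat,
          peak_i = cl$peak_index[1], peak_j = cl$peak_index[2],
          peak_k = cl$peak_index[3],
          peak_x_mm = cl$peak_world[1], peak_y_mm = cl$peak_world[2],
          peak_z_mm = cl$peak_world[3],
          p_corrected = pcorr)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(direction = character(), extent = integer(),
               peak_t = numeric(), peak_i = integer(), peak_j = integer(),
               peak_k = integer(), peak_x_mm = numeric(),
               peak_y_mm = numeric(), peak_z_mm = numeric(),
               p_corrected = numeric())
  if (nrow(out)) {
    ord <- order(out$direction, -out$extent)
    out <- out[ord, , drop = FALSE]
    keep <- keep[ord]
    rownames(out) <- NULL
  }
  attr(out, "clusters") <- keep
  attr(out, "threshold_t") <- u
  out
}

#' Mean NH over a cluster, per subject
#'
#' @param nh_maps list of [nh_map]s (all subjects, standardized stage).
#' @param cluster a component from [grf_cluster_inference()] /
#'   [label_clusters()] (needs `voxels` linear indices), or a vector of
#'   linear voxel indices.
#' @return numeric vector, one mean per map, named by subject id.
#' @export
extract_cluster_means <- function(nh_maps, cluster) {
  vox <- if (is.list(cluster)) cluster$voxels else as.integer(cluster)
  if (length(vox) == 0L) stop("empty cluster")
  out <- vapply(nh_maps, function(m) mean(m$data[vox]), 1)
  names(out) <- vapply(nh_maps, function(m) as.character(m$subject_id), "")
  if (anyNA(out)) stop("cluster voxels fall outside the mask of some map")
  out
}

#' Demographics comparison table (Table-1 style)
#'
#' Per numeric variable: group mean +/- SD and a pooled two-sample t test;
#' for sex, group counts and a Pearson chi-square test.
#'
#' @param records data frame with at least `group` (patient/control), `sex`,
#'   and the numeric columns in `variables`.
#' @param variables numeric columns to compare (default age, education,
#'   reaction time, MMSE).
#' @return data frame with one row per variable: per-group summary, the
#'   statistic (t or chi-square) and p value.
#' @export
demographics_table <- function(records,
                               variables = c("age", "education_years",
                                             "reaction_time", "mmse")) {
  stopifnot(all(c("group", "sex") %in% names(records)))
  pat <- records[records$group == "patient", , drop = FALSE]
  con <- records[records$group == "control", , drop = FALSE]
  if (nrow(pat) == 0L || nrow(con) == 0L) stop("both groups must be present")
  rows <- list()
  tab <- rbind(table(factor(pat$sex, c("male", "female"))),
               table(factor(con$sex, c("male", "female"))))
  cs <- chi_square_2x2(tab)
  rows[[1]] <- data.frame(
    variable = "sex (male/female)",
    patients = sprintf("%d/%d", tab[1, 1], tab[1, 2]),
    controls = sprintf("%d/%d", tab[2, 1], tab[2, 2]),
    statistic = cs$chisq, test = "chi-square", p = cs$p)
  for (v in variables) {
    if (!v %in% names(records)) next
    x <- pat[[v]][is.finite(pat[[v]])]
    y <- con[[v]][is.finite(con[[v]])]
    tt <- ttest_from_summary(length(x), mean(x), sd(x),
                             length(y), mean(y), sd(y))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v,
      patients = sprintf("%.2f ± %.2f", mean(x), sd(x)),
      controls = sprintf("%.2f ± %.2f", mean(y), sd(y)),
      statistic = tt$t, test = "two-sample t", p = tt$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group NH comparison with GRF correction, end to end
#'
#' Convenience wrapper: voxel-wise pooled t map, residual smoothness
#' estimation (per-subject maps minus their group mean), and GRF cluster
#' inference.
#'
#' @param maps_patients,maps_controls lists of standardized [nh_map]s.
#' @param mask the analysis [brain_mask].
#' @param voxel_p,cluster_p,connectivity see [grf_cluster_inference()].
#' @return list with `tmap`, `smoothness`, `clusters` (the inference table).
#' @export
nh_group_comparison <- function(maps_patients, maps_controls, mask,
                                voxel_p = 0.001, cluster_p = 0.01,
                                connectivity = 26) {
  tmap <- voxelwise_two_sample_t(maps_patients, maps_controls, mask)
  resid <- group_residual_maps(maps_patients, maps_controls, mask)
  sm <- estimate_smoothness(resid, mask)
  cl <- grf_cluster_inference(tmap, sm, voxel_p, cluster_p, connectivity)
  list(tmap = tmap, smoothness = sm, clusters = cl)
}

group_residual_maps <- function(maps_a, maps_b, mask) {
  idx <- which(mask$data)
  shape <- dim(mask$data)
  resid <- list()
  for (grp in list(maps_a, maps_b)) {
    M <- t(vapply(grp, function(m) m$data[idx], numeric(length(idx))))
    M <- sweep(M, 2L, colMeans(M))
    for (i in seq_len(nrow(M))) {
      arr <- array(NA_real_, shape)
      arr[idx] <- M[i, ]
      resid[[length(resid) + 1L]] <- arr
    }
  }
  resid
}
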