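#' Preprocessing configuration
#'
#' Settings for the standard resting-state chain: initial volume discarding,
#' motion screening, nuisance regression (global signal preserved), Gaussian
#' smoothing, and linear detrending with ideal band-pass filtering.
#'
#' @param n_discard initial volumes to drop (default 5).
#' @param max_translation_mm motion screen translation limit (default 2;
#'   strict inequality — a peak of exactly 2 mm is accepted).
#' @param max_rotation_deg motion screen rotation limit in degrees (default 2).
#' @param band length-2 pass band in Hz (default `c(0.01, 0.08)`).
#' @param fwhm_mm smoothing kernel full width at half maximum (default 8).
#' @param use_motion_regressors include the 6 motion parameters as nuisance
#'   regressors.
#' @param use_wm,use_csf include white-matter / CSF surrogate signals.
#' @param preserve_global keep the global signal (default TRUE; no global
#'   signal regression).
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(n_discard = 5L, max_translation_mm = 2,
                              max_rotation_deg = 2, band = c(0.01, 0.08),
                              fwhm_mm = 8, use_motion_regressors = TRUE,
                              use_wm = TRUE, use_csf = TRUE,
                              preserve_global = TRUE) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("'band' must be (low, high) with 0 < low < high")
  if (fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  if (n_discard < 0) stop("'n_discard' must be >= 0")
  structure(list(n_discard = as.integer(n_discard),
                 max_translation_mm = max_translation_mm,
                 max_rotation_deg = max_rotation_deg,
                 band = band, fwhm_mm = fwhm_mm,
                 use_motion_regressors = use_motion_regressors,
                 use_wm = use_wm, use_csf = use_csf,
                 preserve_global = preserve_global),
            class = "preprocess_config")
}

#' Discard initial volumes
#'
#' Drops the first `n` volumes of a time-series image, keeping the affine and
#' TR unchanged.
#'
#' @param img a [ts_image].
#' @param n number of leading volumes to drop; must be < number of volumes.
#' @return a [ts_image] with `T - n` volumes.
#' @export
discard_initial_volumes <- function(img, n) {
  stopifnot(inherits(img, "ts_image"))
  Tn <- dim(img$data)[4]
  if (n < 0 || n >= Tn) stop("'n' must be in [0, T); T = ", Tn)
  if (n == 0L) return(img)
  ts_image(img$data[, , , (n + 1):Tn, drop = FALSE], img$affine, img$tr)
}

#' Screen a motion trace against displacement limits
#'
#' Rejects the subject if any translation axis exceeds `max_translation_mm`
#' or any rotation axis exceeds `max_rotation_deg` (strict inequalities, so a
#' peak of exactly 2 mm or 2 degrees passes). Reports the offending axis and
#' peak.
#'
#' @param trace T x 6 motion matrix (translations mm, rotations degrees).
#' @param cfg a [preprocess_config].
#' @return list with `accept` (logical), `axis` (1..6 or NA), `peak`
#'   (offending |value| or the overall peak when accepted).
#' @export
screen_motion <- function(trace, cfg = preprocess_config()) {
  if (!is.matrix(trace) || ncol(trace) != 6L || nrow(trace) == 0L)
    stop("'trace' must be a non-empty T x 6 matrix")
  peaks <- apply(abs(trace), 2L, max)
  limits <- c(rep(cfg$max_translation_mm, 3), rep(cfg$max_rotation_deg, 3))
  over <- peaks > limits
  if (any(over)) {
    worst <- which.max(peaks / limits)
    list(accept = FALSE, axis = unname(worst), peak = unname(peaks[worst]))
  } else {
    list(accept = TRUE, axis = NA_integer_, peak = unname(max(peaks)))
  }
}

#' Regress nuisance signals out of every voxel
#'
#' Fits each voxel's series on the regressors (plus an intercept) by least
#' squares and keeps the residual with the voxel's own mean restored, so the
#' global signal level is preserved. Residuals are orthogonal to every
#' (demeaned) regressor column.
#'
#' @param img a [ts_image].
#' @param regressors T x k numeric matrix, or NULL/zero columns for identity.
#' @return a [ts_image] of residuals (+ voxel means).
#' @export
regress_nuisance <- function(img, regressors) {
  stopifnot(inherits(img, "ts_image"))
  d <- dim(img$data)
  if (is.null(regressors) || NCOL(regressors) == 0L) return(img)
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != d[4])
    stop("regressor rows (", nrow(regressors), ") != volume count (", d[4], ")")
  X <- cbind(1, regressors)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dep <- setdiff(seq_len(ncol(X)), q$pivot[seq_len(q$rank)]) - 1L
    stop("rank-deficient nuisance design; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  Y <- matrix(img$data, prod(d[1:3]), d[4])     # V x T
  mu <- rowMeans(Y)
  R <- t(qr.resid(q, t(Y)))                     # residuals per voxel
  out <- R + mu
  ts_image(array(out, dim = d), img$affine, img$tr)
}

#' Linear detrending plus ideal band-pass filtering
#'
#' Per voxel: remove the least-squares linear trend, zero every discrete
#' Fourier component outside `[low, high]` Hz (an ideal frequency-domain
#' mask), and re-orthogonalize against the in-band component of the trend
#' line so the whole operation is an exact orthogonal projection (applying
#' it twice equals applying it once). The DC component is outside any
#' positive band, so output series have mean ~0.
#'
#' @param img a [ts_image].
#' @param band length-2 pass band in Hz; must lie in (0, Nyquist).
#' @return a filtered [ts_image].
#' @export
detrend_bandpass <- function(img, band = c(0.01, 0.08)) {
  stopifnot(inherits(img, "ts_image"))
  d <- dim(img$data)
  Tn <- d[4]
  nyq <- 1 / (2 * img$tr)
  if (band[1] <= 0 || band[2] > nyq || band[1] >= band[2])
    stop("band must satisfy 0 < low < high <= Nyquist (", nyq, " Hz)")
  Y <- t(matrix(img$data, prod(d[1:3]), Tn))    # T x V (series in columns)
  tt <- seq_len(Tn)
  X <- cbind(1, tt - mean(tt))
  beta <- solve(crossprod(X)) %*% crossprod(X, Y)   # 2 x V
  Y <- Y - X %*% beta
  freqs <- (0:(Tn - 1)) / (Tn * img$tr)
  freqs <- pmin(freqs, 1 / img$tr - freqs)      # fold to [0, Nyquist]
  keep <- freqs >= band[1] & freqs <= band[2]
  Fm <- stats::mvfft(Y)
  Fm[!keep, ] <- 0
  Y <- Re(stats::mvfft(Fm, inverse = TRUE)) / Tn
  # subtract the projection onto the in-band part of the trend line, making
  # the detrend+bandpass combination a single orthogonal projection
  fw <- stats::fft(X[, 2]); fw[!keep] <- 0
  w <- Re(stats::fft(fw, inverse = TRUE)) / Tn
  w2 <- sum(w^2)
  if (w2 > 0) Y <- Y - w %*% (crossprod(w, Y) / w2)
  ts_image(array(t(Y), dim = d), img$affine, img$tr)
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma_vox))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# convolve along the first axis of a matrix whose rows are that axis.
# Replicate (nearest-edge) boundary handling is folded into a dense n x n
# convolution operator so the whole axis is one matrix product.
conv_axis <- function(M, kernel) {
  if (length(kernel) == 1L) return(M)
  half <- (length(kernel) - 1L) / 2L
  n <- nrow(M)
  K <- matrix(0, n, n)
  for (tap in seq_along(kernel)) {
    src <- pmin(pmax(seq_len(n) + tap - half - 1L, 1L), n)
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + kernel[tap]
  }
  K %*% M
}

#' Volume-wise 3-D Gaussian smoothing
#'
#' Separable Gaussian convolution of every volume with
#' `sigma_axis = fwhm / (voxel_size_axis * 2 * sqrt(2 * log(2)))` voxels per
#' axis. Boundaries use replicate (nearest-edge) padding, so a constant
#' volume is exactly invariant.
#'
#' @param img a [ts_image].
#' @param fwhm_mm kernel full width at half maximum in mm (0 = identity).
#' @return a smoothed [ts_image].
#' @export
gaussian_smooth <- function(img, fwhm_mm = 8) {
  stopifnot(inherits(img, "ts_image"))
  if (fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  if (fwhm_mm == 0) return(img)
  d <- dim(img$data)
  vs <- voxel_sizes(img$affine)
  sig <- fwhm_mm / (vs * 2 * sqrt(2 * log(2)))
  A <- img$data
  # axis 1
  M <- matrix(A, d[1], prod(d[2:4]))
  M <- conv_axis(M, gaussian_kernel_1d(sig[1]))
  A <- array(M, d)
  # axis 2
  A <- aperm(A, c(2, 1, 3, 4))
  M <- matrix(A, d[2], prod(d[c(1, 3, 4)]))
  M <- conv_axis(M, gaussian_kernel_1d(sig[2]))
  A <- aperm(array(M, d[c(2, 1, 3, 4)]), c(2, 1, 3, 4))
  # axis 3
  A <- aperm(A, c(3, 1, 2, 4))
  M <- matrix(A, d[3], prod(d[c(1, 2, 4)]))
  M <- conv_axis(M, gaussian_kernel_1d(sig[3]))
  A <- aperm(array(M, d[c(3, 1, 2, 4)]), c(2, 3, 1, 4))
  ts_image(A, img$affine, img$tr)
}

roi_mean_series <- function(img, roi) {
  d <- dim(img$data)
  idx <- vox_linear_index(roi$voxels, d[1:3])
  Y <- matrix(img$data, prod(d[1:3]), d[4])
  colMeans(Y[idx, , drop = FALSE])
}

#' Run the full preprocessing chain on one subject
#'
#' Applies, in order: volume discarding, motion screening (on the trace rows
#' kept after discarding), nuisance regression (motion parameters plus
#' white-matter and CSF surrogate signals; global signal preserved),
#' Gaussian smoothing, and detrending + band-pass filtering. Rejection by
#' the motion screen is a typed outcome, not an error.
#'
#' @param img a [ts_image].
#' @param trace T x 6 motion matrix aligned with the *un-discarded* image.
#' @param cfg a [preprocess_config].
#' @param wm_roi,csf_roi optional ROIs ([box_roi()]) whose mean series act as
#'   white-matter / CSF nuisance signals.
#' @return a list: `status` (`"ok"` or `"rejected"`), `image` (preprocessed
#'   [ts_image] or NULL), `screen` (motion screen result), `log` (per-stage
#'   character records).
#' @export
preprocess_subject <- function(img, trace, cfg = preprocess_config(),
                               wm_roi = NULL, csf_roi = NULL) {
  stopifnot(inherits(img, "ts_image"))
  log <- character()
  stage <- function(msg) log <<- c(log, msg)

  img <- discard_initial_volumes(img, cfg$n_discard)
  if (!is.null(trace)) {
    if (nrow(trace) < dim(img$data)[4]) stop("motion trace shorter than image")
    trace <- trace[(cfg$n_discard + 1):nrow(trace), , drop = FALSE]
  }
  stage(sprintf("discard: dropped %d volumes, %d remain",
                cfg$n_discard, dim(img$data)[4]))

  screen <- list(accept = TRUE, axis = NA_integer_, peak = 0)
  if (!is.null(trace)) {
    screen <- screen_motion(trace, cfg)
    if (!screen$accept) {
      stage(sprintf("screen: REJECTED (axis %d, peak %.3f)",
                    screen$axis, screen$peak))
      return(list(status = "rejected", image = NULL, screen = screen, log = log))
    }
    stage(sprintf("screen: accepted (peak %.3f)", screen$peak))
  }

  reg <- NULL
  if (cfg$use_motion_regressors && !is.null(trace)) reg <- cbind(reg, trace)
  if (cfg$use_wm && !is.null(wm_roi)) reg <- cbind(reg, wm = roi_mean_series(img, wm_roi))
  if (cfg$use_csf && !is.null(csf_roi)) reg <- cbind(reg, csf = roi_mean_series(img, csf_roi))
  img <- regress_nuisance(img, reg)
  stage(sprintf("nuisance: %d regressors removed, global signal preserved",
                NCOL(reg)))

  img <- gaussian_smooth(img, cfg$fwhm_mm)
  stage(sprintf("smooth: FWHM %g mm", cfg$fwhm_mm))

  img <- detrend_bandpass(img, cfg$band)
  stage(sprintf("bandpass: detrended, %g-%g Hz retained", cfg$band[1], cfg$band[2]))

  list(status = "ok", image = img, screen = screen, log = log)
}
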