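#' Define a rectangular ROI on the simulation grid
#'
#' ROIs are axis-aligned boxes given by inclusive 1-based index ranges.
#'
#' @param label character ROI label.
#' @param x,y,z integer index ranges (e.g. `13:18`).
#' @return a list with the label and an n x 3 matrix of voxel indices.
#' @export
box_roi <- function(label, x, y, z) {
  vox <- as.matrix(expand.grid(i = x, j = y, k = z))
  colnames(vox) <- NULL
  list(label = label, voxels = vox)
}

#' Desk-scale demonstration cohort specification
#'
#' A compact study condition for effect-recovery experiments: a 14 x 16 x 14
#' grid (3 mm voxels) carrying six DMN-like context boxes plus two small
#' dedicated effect ROIs — `R_PCu` (increase, precuneus-like) and `R_ITG_a`
#' (decrease, inferior-temporal-like) — each about 7% of the ~400-voxel
#' network mask, mirroring the proportion that significant clusters occupy
#' in a whole-brain DMN mask. Couplings follow the generator defaults
#' (base 0.5, delta 0.3); the scan length keeps the generator default of
#' 240 volumes, whose in-band information content sets the attainable
#' group-level t values.
#'
#' @param seed master seed.
#' @param n_patients,n_controls group sizes (default 20 each).
#' @param n_volumes volumes per run (default 240).
#' @param delta coupling delta for both effect ROIs (default 0.3).
#' @param ... further arguments passed to [cohort_spec()].
#' @return a [cohort_spec].
#' @export
desk_cohort_spec <- function(seed = 1L, n_patients = 20L, n_controls = 20L,
                             n_volumes = 240L, delta = 0.3, ...) {
  rois <- list(
    box_roi("MPFC",     5:8,  12:15,  8:11),
    box_roi("PCC_PCu",  5:8,   2:5,   9:12),
    box_roi("L_IPL",    1:3,   2:5,   8:11),
    box_roi("R_IPL",   12:14, 12:15,  8:11),
    box_roi("L_MTG",    1:3,   8:11,  3:6),
    box_roi("R_ITG",   11:14,  7:10,  2:5),
    box_roi("R_PCu",   11:13,  2:4,  10:12),
    box_roi("R_ITG_a", 11:13, 13:15,  2:4)
  )
  cohort_spec(n_patients = n_patients, n_controls = n_controls,
              grid_shape = c(14L, 16L, 14L), n_volumes = n_volumes,
              dmn_roi_set = rois,
              effect_rois = list(
                list(label = "R_PCu", direction = "increase", delta = delta),
                list(label = "R_ITG_a", direction = "decrease", delta = delta)),
              seed = seed, ...)
}

roi_mask <- function(roi, shape) {
  m <- array(FALSE, dim = shape)
  m[roi$voxels] <- TRUE
  m
}

#' Default DMN-like ROI set for a simulation grid
#'
#' Axis-aligned boxes standing in for the canonical default-mode regions:
#' medial prefrontal cortex, posterior cingulate / precuneus, bilateral
#' inferior parietal lobes, left middle temporal gyrus and right inferior
#' temporal gyrus, plus two small subregions — `R_PCu` (right precuneus) and
#' `R_ITG_a` (anterior right inferior temporal) — that serve as the default
#' effect ROIs: group differences in real data occupy cluster-sized
#' subregions of the large network nodes, not entire nodes. Box positions
#' are fractions of the grid, so the layout scales with `grid_shape`.
#'
#' @param grid_shape integer length-3 voxel grid (default `c(30, 36, 30)`).
#' @return a list of ROIs as produced by [box_roi()].
#' @export
default_dmn_rois <- function(grid_shape = c(30L, 36L, 30L)) {
  fb <- function(label, xf, yf, zf) {
    rng <- function(f, n) max(1L, round(f[1] * n)):min(n, round(f[2] * n))
    box_roi(label, rng(xf, grid_shape[1]), rng(yf, grid_shape[2]),
            rng(zf, grid_shape[3]))
  }
  list(
    fb("MPFC",    c(0.43, 0.60), c(0.78, 0.92), c(0.47, 0.63)),
    fb("PCC_PCu", c(0.43, 0.60), c(0.17, 0.31), c(0.53, 0.70)),
    fb("L_IPL",   c(0.13, 0.27), c(0.22, 0.33), c(0.60, 0.73)),
    fb("R_IPL",   c(0.77, 0.90), c(0.22, 0.33), c(0.60, 0.73)),
    fb("L_MTG",   c(0.13, 0.27), c(0.39, 0.53), c(0.27, 0.40)),
    fb("R_ITG",   c(0.77, 0.90), c(0.39, 0.53), c(0.20, 0.33)),
    fb("R_PCu",   c(0.63, 0.74), c(0.08, 0.16), c(0.55, 0.68)),
    fb("R_ITG_a", c(0.77, 0.88), c(0.62, 0.72), c(0.20, 0.30))
  )
}

#' Specification of a synthetic two-group resting-state cohort
#'
#' Encodes the study conditions for a simulated patient/control cohort: grid
#' geometry, scan timing, the DMN-like ROI layout, the shared-signal coupling
#' model with group-dependent effects in designated ROIs, AR(1) voxel noise,
#' scanner drift and rigid-body motion traces.
#'
#' Each in-network voxel's series is
#' `c * s(t) + sqrt(1 - c^2) * e(t) + a * d(t)`, where `s` is a subject-level
#' band-limited (0.01-0.08 Hz) network signal, `e` is unit-variance AR(1)
#' noise, `d` a unit-variance linear drift with amplitude `a`, and `c` the
#' voxel's coupling weight. In-band correlation between voxels i and j is then
#' `c_i * c_j`. Effect ROIs move patients' coupling to
#' `base_coupling +/- coupling delta`; controls always sit at `base_coupling`.
#'
#' @param n_patients,n_controls group sizes (defaults 43 and 42).
#' @param grid_shape integer length-3 voxel grid (default `c(30, 36, 30)`).
#' @param voxel_size_mm length-3 voxel edge lengths in mm (default 3 mm).
#' @param n_volumes number of volumes (default 240).
#' @param tr_seconds repetition time in seconds (default 2).
#' @param dmn_roi_set list of ROIs ([box_roi()]) defining the network.
#' @param effect_rois list of `list(label=, direction=, delta=)` entries;
#'   direction is `"increase"` or `"decrease"` and applies to patients.
#' @param base_coupling baseline coupling weight in (0, 1).
#' @param ar1_coefficient AR(1) coefficient of the voxel noise in [0, 1).
#' @param drift_amplitude linear-drift amplitude (SD units; >= 0).
#' @param motion_sigma_mm random-walk step scale for the motion trace
#'   (mm for translations, degrees for rotations).
#' @param regional_sigma amplitude of regional background fluctuations:
#'   every 4-voxel cubic block of the grid carries its own AR(1) signal with
#'   this SD, shared by the block's voxels. Models spatially structured
#'   physiological/neural background activity that spatial smoothing does not
#'   remove; without it, smoothing annihilates the independent voxel noise
#'   and baseline in-network correlations saturate near 1, which real
#'   resting-state data never show.
#' @param coupling_jitter SD of a per-subject, per-ROI random offset added to
#'   the coupling weights (truncated to keep weights in (0, 1)). Models
#'   between-subject variability in regional network coherence; at the
#'   default 0.15 the group comparison yields peak t values of the magnitude
#'   the method reports on real cohorts (|t| about 4-6) rather than the
#'   arbitrarily large values a noise-free cohort would give.
#' @param nuisance_leak amplitude with which the white-matter and CSF
#'   surrogate signals leak into every voxel (>= 0).
#' @param seed integer master seed; all subject-level seeds derive from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 43, n_controls = 42,
                        grid_shape = c(30L, 36L, 30L),
                        voxel_size_mm = c(3, 3, 3),
                        n_volumes = 240L, tr_seconds = 2,
                        dmn_roi_set = default_dmn_rois(grid_shape),
                        effect_rois = list(
                          list(label = "R_PCu", direction = "increase", delta = 0.3),
                          list(label = "R_ITG_a", direction = "decrease", delta = 0.3)),
                        base_coupling = 0.5, ar1_coefficient = 0.5,
                        drift_amplitude = 0.5, motion_sigma_mm = 0.05,
                        regional_sigma = 0.8, coupling_jitter = 0.07,
                        nuisance_leak = 0.1, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0L))
    stop("'grid_shape' must be 3 positive integers")
  if (length(dmn_roi_set) == 0L) stop("'dmn_roi_set' must not be empty")
  labels <- vapply(dmn_roi_set, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate ROI labels")
  for (roi in dmn_roi_set) {
    if (nrow(roi$voxels) == 0L) stop("empty ROI: ", roi$label)
    if (any(roi$voxels < 1L) ||
        any(sweep(roi$voxels, 2L, grid_shape, ">")))
      stop("ROI '", roi$label, "' falls outside the grid")
  }
  deltas <- 0
  for (ef in effect_rois) {
    if (!ef$label %in% labels)
      stop("effect ROI '", ef$label, "' is not in the DMN ROI set")
    if (!ef$direction %in% c("increase", "decrease"))
      stop("effect direction must be 'increase' or 'decrease'")
    if (ef$delta < 0 || ef$delta >= 1) stop("coupling delta must be in [0, 1)")
    deltas <- max(deltas, ef$delta)
  }
  if (base_coupling <= 0 || base_coupling >= 1)
    stop("'base_coupling' must be in (0, 1)")
  if (base_coupling + deltas >= 1)
    stop("base_coupling + max coupling delta must be < 1")
  if (base_coupling - deltas < 0)
    stop("base_coupling - max coupling delta must be >= 0")
  if (ar1_coefficient < 0 || ar1_coefficient >= 1)
    stop("'ar1_coefficient' must be in [0, 1)")
  if (n_volumes <= 5L) stop("'n_volumes' must exceed the discarded volumes")
  if (drift_amplitude < 0 || motion_sigma_mm < 0 || nuisance_leak < 0 ||
      coupling_jitter < 0 || regional_sigma < 0)
    stop("amplitudes must be non-negative")
  if (regional_sigma >= 1) stop("'regional_sigma' must be < 1")
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    grid_shape = grid_shape, voxel_size_mm = as.numeric(voxel_size_mm),
    n_volumes = as.integer(n_volumes), tr_seconds = tr_seconds,
    dmn_roi_set = dmn_roi_set, effect_rois = effect_rois,
    base_coupling = base_coupling, ar1_coefficient = ar1_coefficient,
    drift_amplitude = drift_amplitude, motion_sigma_mm = motion_sigma_mm,
    regional_sigma = regional_sigma, coupling_jitter = coupling_jitter,
    nuisance_leak = nuisance_leak,
    seed = as.integer(seed)),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d patients / %d controls, grid %s, ",
                     "T = %d @ TR %g s, base coupling %g, seed %d\n"),
              x$n_patients, x$n_controls,
              paste(x$grid_shape, collapse = "x"),
              x$n_volumes, x$tr_seconds, x$base_coupling, x$seed))
  invisible(x)
}

spec_affine <- function(spec) {
  default_affine(spec$grid_shape, spec$voxel_size_mm)
}

#' Union mask of the DMN ROI set
#'
#' @param spec a [cohort_spec].
#' @return a [brain_mask] covering every DMN ROI voxel.
#' @export
dmn_truth_mask <- function(spec) {
  m <- array(FALSE, dim = spec$grid_shape)
  for (roi in spec$dmn_roi_set) m[roi$voxels] <- TRUE
  brain_mask(m, affine = spec_affine(spec))
}

# white-matter / CSF surrogate boxes, deliberately outside the default DMN set
nuisance_rois <- function(spec) {
  s <- spec$grid_shape
  cx <- max(1L, round(s[1] / 2)); cy <- max(1L, round(s[2] / 2))
  zl <- max(1L, round(s[3] * 0.1)); zh <- min(s[3], zl + 1L)
  wm <- box_roi("WM", clamp_range(cx - 1L, cx + 1L, s[1]),
                clamp_range(cy - 1L, cy + 1L, s[2]),
                clamp_range(zl, zh, s[3]))
  csf <- box_roi("CSF", clamp_range(1L, 2L, s[1]),
                 clamp_range(1L, 2L, s[2]),
                 clamp_range(s[3] - 1L, s[3], s[3]))
  list(wm = wm, csf = csf)
}

clamp_range <- function(lo, hi, n) max(1L, lo):min(n, hi)

# band-limited signal built directly in the frequency domain: random complex
# amplitudes on the DFT bins inside [low, high] Hz, zero elsewhere
bandlimited_signal <- function(n, tr, low = 0.01, high = 0.08) {
  freqs <- (0:(n - 1)) / (n * tr)
  pos <- freqs <= 1 / (2 * tr)
  sel <- which(pos & freqs >= low & freqs <= high)
  if (length(sel) == 0L) stop("no DFT bin falls inside the band")
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  amp <- complex(real = rnorm(length(sel)), imaginary = rnorm(length(sel)))
  spec[sel] <- amp
  # mirror for a real signal
  spec[n + 2 - sel] <- Conj(amp)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# stationary AR(1): x_1 from the stationary law, innovations scaled so the
# marginal variance is 1; recursion vectorized across series
ar1_noise <- function(n, n_series, phi) {
  e <- matrix(rnorm(n * n_series), n, n_series)
  if (phi == 0) return(e)
  s <- sqrt(1 - phi^2)
  e[-1, ] <- e[-1, , drop = FALSE] * s
  for (t in 2:n) e[t, ] <- e[t, ] + phi * e[t - 1L, ]
  e
}

coupling_map <- function(spec, group) {
  w <- array(0, dim = spec$grid_shape)
  for (roi in spec$dmn_roi_set) w[roi$voxels] <- spec$base_coupling
  if (group == "patient") {
    rois <- setNames(spec$dmn_roi_set,
                     vapply(spec$dmn_roi_set, `[[`, "", "label"))
    for (ef in spec$effect_rois) {
      sgn <- if (ef$direction == "increase") 1 else -1
      w[rois[[ef$label]]$voxels] <- spec$base_coupling + sgn * ef$delta
    }
  }
  w
}

#' Generate one synthetic subject
#'
#' Draws a 4-D BOLD image, a 6-column motion trace and the ground-truth
#' coupling map for a single subject under the cohort's generative model.
#'
#' @param spec a [cohort_spec].
#' @param group `"patient"` or `"control"`.
#' @param subject_seed integer seed for this subject's random stream.
#' @return a list with elements `image` ([ts_image]), `motion` (T x 6
#'   matrix: translations mm, rotations degrees), and `truth` (list with the
#'   realized and nominal coupling arrays, group, and effect-ROI masks).
#' @export
generate_subject <- function(spec, group = c("patient", "control"),
                             subject_seed = spec$seed) {
  group <- match.arg(group)
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(subject_seed %% 2147483647))
  Tn <- spec$n_volumes
  shape <- spec$grid_shape
  nvox <- prod(shape)

  s <- bandlimited_signal(Tn, spec$tr_seconds)
  w <- coupling_map(spec, group)
  nominal <- w
  if (spec$coupling_jitter > 0) {
    for (roi in spec$dmn_roi_set) {
      eta <- rnorm(1, 0, spec$coupling_jitter)
      w[roi$voxels] <- pmin(pmax(w[roi$voxels] + eta, 0.02), 0.97)
    }
  }
  wv <- as.vector(w)

  noise <- ar1_noise(Tn, nvox, spec$ar1_coefficient)
  drift <- seq(-1, 1, length.out = Tn)
  drift <- drift / sd(drift)

  # smooth regional background field (correlation length ~4 voxels)
  a <- spec$regional_sigma
  if (a > 0) u <- regional_field(shape, Tn, spec$ar1_coefficient)

  nuis <- nuisance_rois(spec)
  wm_sig <- as.numeric(scale(ar1_noise(Tn, 1L, 0.5)))
  csf_sig <- as.numeric(scale(ar1_noise(Tn, 1L, 0.5)))

  # T x V: coupled network signal + regional background + voxel AR(1) noise
  # + drift + nuisance leak; component weights keep total variance near 1
  if (a > 0) {
    a_eff <- pmin(a, sqrt(pmax(1 - wv^2, 0)))
    resid_sd <- sqrt(pmax(1 - wv^2 - a_eff^2, 0))
    y <- outer(s, wv) + sweep(u, 2L, a_eff, "*") +
      sweep(noise, 2L, resid_sd, "*")
  } else {
    y <- outer(s, wv) + sweep(noise, 2L, sqrt(1 - wv^2), "*")
  }
  y <- y + spec$drift_amplitude * drift +
    spec$nuisance_leak * (wm_sig + csf_sig)
  # the WM/CSF surrogate boxes carry their own signals strongly
  for (nm in c("wm", "csf")) {
    sig <- if (nm == "wm") wm_sig else csf_sig
    idx <- vox_linear_index(nuis[[nm]]$voxels, shape)
    y[, idx] <- 0.6 * sig + 0.8 * noise[, idx]
  }

  img <- ts_image(array(t(y), dim = c(shape, Tn)),
                  affine = spec_affine(spec), tr = spec$tr_seconds)

  motion <- bounded_random_walk(Tn, 6L, spec$motion_sigma_mm, bound = 1.5)
  colnames(motion) <- c("tx_mm", "ty_mm", "tz_mm",
                        "pitch_deg", "roll_deg", "yaw_deg")

  effect_masks <- lapply(spec$effect_rois, function(ef) {
    rois <- setNames(spec$dmn_roi_set,
                     vapply(spec$dmn_roi_set, `[[`, "", "label"))
    list(label = ef$label, direction = ef$direction,
         mask = roi_mask(rois[[ef$label]], shape))
  })
  truth <- list(coupling = w, nominal_coupling = nominal, group = group,
                effect_masks = effect_masks)
  list(image = img, motion = motion, truth = truth)
}

# Smooth regional background field: independent AR(1) series on a coarse
# node lattice (spacing voxels apart), trilinearly interpolated to voxels and
# re-normalized to unit marginal variance. Yields a stationary spatially
# smooth noise field with correlation length ~ spacing voxels.
regional_field <- function(shape, Tn, phi, spacing = 4L) {
  axis_nodes <- function(n) {
    nd <- seq(1L, n, by = spacing)
    if (nd[length(nd)] < n) nd <- c(nd, n)
    nd
  }
  nx <- axis_nodes(shape[1]); ny <- axis_nodes(shape[2]); nz <- axis_nodes(shape[3])
  nn <- c(length(nx), length(ny), length(nz))
  U <- ar1_noise(Tn, prod(nn), phi)

  axis_w <- function(pos, nodes) {
    # lower node index and weight of the lower node for each voxel position
    i0 <- findInterval(pos, nodes, rightmost.closed = TRUE)
    i0 <- pmin(i0, length(nodes) - 1L)
    span <- nodes[i0 + 1L] - nodes[i0]
    w0 <- (nodes[i0 + 1L] - pos) / span
    list(i0 = i0, w0 = w0)
  }
  ax <- axis_w(seq_len(shape[1]), nx)
  ay <- axis_w(seq_len(shape[2]), ny)
  az <- axis_w(seq_len(shape[3]), nz)

  V <- prod(shape)
  gi <- rep.int(seq_len(shape[1]), shape[2] * shape[3])
  gj <- rep.int(rep(seq_len(shape[2]), each = shape[1]), shape[3])
  gk <- rep(seq_len(shape[3]), each = shape[1] * shape[2])

  out <- matrix(0, Tn, V)
  nrm2 <- numeric(V)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) ax$w0[gi] else 1 - ax$w0[gi]
    wy <- if (dy == 0) ay$w0[gj] else 1 - ay$w0[gj]
    wz <- if (dz == 0) az$w0[gk] else 1 - az$w0[gk]
    w <- wx * wy * wz
    node <- (ax$i0[gi] + dx) +
      (ay$i0[gj] + dy - 1L) * nn[1] +
      (az$i0[gk] + dz - 1L) * nn[1] * nn[2]
    out <- out + sweep(U[, node, drop = FALSE], 2L, w, "*")
    nrm2 <- nrm2 + w^2
  }
  sweep(out, 2L, sqrt(nrm2), "/")
}

vox_linear_index <- function(vox, shape) {
  (vox[, 3] - 1L) * shape[1] * shape[2] + (vox[, 2] - 1L) * shape[1] + vox[, 1]
}

bounded_random_walk <- function(n, k, sigma, bound) {
  steps <- matrix(rnorm(n * k, sd = sigma), n, k)
  x <- apply(steps, 2L, cumsum)
  # reflect into [-bound, bound]
  x <- abs((x + bound) %% (4 * bound) - 2 * bound) - bound
  matrix(x, n, k)
}

#' Inject gross head motion into a motion trace
#'
#' Rescales (or, for an all-zero axis, spikes) one axis so that its maximal
#' absolute value equals `magnitude`, leaving the other five axes untouched.
#' Used to create subjects that the motion screen must reject.
#'
#' @param trace T x 6 motion matrix.
#' @param axis column index in 1..6.
#' @param magnitude target peak absolute value (> 0); mm for axes 1-3,
#'   degrees for axes 4-6.
#' @return the modified trace.
#' @export
inject_gross_motion <- function(trace, axis, magnitude) {
  if (!is.matrix(trace) || ncol(trace) != 6L)
    stop("'trace' must be a T x 6 matrix")
  if (length(axis) != 1L || !axis %in% 1:6) stop("invalid axis")
  if (magnitude <= 0) stop("'magnitude' must be positive")
  peak <- max(abs(trace[, axis]))
  if (peak > 0) {
    trace[, axis] <- trace[, axis] * (magnitude / peak)
  } else {
    trace[ceiling(nrow(trace) / 2), axis] <- magnitude
  }
  trace
}

# Table-1-style phenotype distributions (means and SDs)
phenotype_defaults <- function() {
  list(
    patient = list(age = c(27.91, 6.48), education = c(13.01, 2.67),
                   male_frac = 23 / 43, duration = c(8.49, 7.1),
                   rt = c(91.60, 54.85), mmse = c(28, 1.5)),
    control = list(age = c(26.96, 5.31), education = c(13.67, 1.88),
                   male_frac = 22 / 42, duration = NULL,
                   rt = c(91.60, 54.85), mmse = c(28, 1.5))
  )
}

rtrunc_norm <- function(n, mean, sd, lower = 0) {
  pmax(lower, rnorm(n, mean, sd))
}

simulate_phenotype <- function(spec) {
  defs <- phenotype_defaults()
  rows <- list()
  counts <- c(patient = spec$n_patients, control = spec$n_controls)
  for (grp in names(counts)) {
    n <- counts[[grp]]
    if (n == 0L) next
    d <- defs[[grp]]
    age <- round(rtrunc_norm(n, d$age[1], d$age[2], lower = 16), 1)
    dur <- if (grp == "patient")
      round(pmin(age - 1, rtrunc_norm(n, d$duration[1], d$duration[2], 0.2)), 1)
    else rep(NA_real_, n)
    rows[[grp]] <- data.frame(
      subject_id = sprintf("sub-%s%02d", if (grp == "patient") "P" else "C", seq_len(n)),
      group = grp,
      age = age,
      sex = ifelse(runif(n) < d$male_frac, "male", "female"),
      education_years = round(rtrunc_norm(n, d$education[1], d$education[2], 5), 1),
      illness_duration = dur,
      onset_age = if (grp == "patient") round(age - dur, 1) else NA_real_,
      reaction_time = round(rtrunc_norm(n, d$rt[1], d$rt[2], 1), 2),
      mmse = round(pmin(30, rtrunc_norm(n, d$mmse[1], d$mmse[2], 20))),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

subject_seed_for <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 1000003 + index * 7919) %% 2147483647)
}

#' Generate a full cohort on disk
#'
#' Writes one 4-D NIfTI and one motion text file per subject, a phenotype
#' TSV, the ground-truth coupling maps (one per group) and a JSON sidecar
#' describing ROIs and seeds. Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec].
#' @param out_dir output directory; must not already contain a cohort unless
#'   `force = TRUE`.
#' @param force overwrite an existing cohort directory.
#' @param compress write gzipped NIfTI (`.nii.gz`, default) or plain `.nii`
#'   (faster for large throwaway cohorts).
#' @return invisibly, a list with the phenotype table and file paths.
#' @export
generate_cohort <- function(spec, out_dir, force = FALSE, compress = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (dir.exists(out_dir) && file.exists(file.path(out_dir, "phenotype.tsv"))) {
    if (!force) stop("cohort already exists in '", out_dir,
                     "'; use force = TRUE to overwrite")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  set.seed(spec$seed)
  pheno <- simulate_phenotype(spec)
  pheno_path <- file.path(out_dir, "phenotype.tsv")
  write.table(pheno, pheno_path, sep = "\t", quote = FALSE, row.names = FALSE)

  ext <- if (compress) "_bold.nii.gz" else "_bold.nii"
  img_paths <- character(nrow(pheno)); mot_paths <- character(nrow(pheno))
  for (i in seq_len(nrow(pheno))) {
    sub <- generate_subject(spec, pheno$group[i],
                            subject_seed = subject_seed_for(spec$seed, i))
    img_paths[i] <- file.path(out_dir, paste0(pheno$subject_id[i], ext))
    mot_paths[i] <- file.path(out_dir, paste0(pheno$subject_id[i], "_motion.txt"))
    write_ts_image(sub$image, img_paths[i])
    write.table(format(sub$motion, digits = 8), mot_paths[i],
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }

  aff <- spec_affine(spec)
  for (grp in c("patient", "control")) {
    w <- coupling_map(spec, grp)
    nii <- RNifti::asNifti(w)
    RNifti::sform(nii) <- structure(aff, code = 2L)
    RNifti::writeNifti(nii, file.path(out_dir, paste0("truth_coupling_", grp, ".nii.gz")))
  }
  truth <- list(
    seed = spec$seed,
    base_coupling = spec$base_coupling,
    effect_rois = spec$effect_rois,
    dmn_labels = vapply(spec$dmn_roi_set, `[[`, "", "label"),
    tr_seconds = spec$tr_seconds,
    subject_seeds = vapply(seq_len(nrow(pheno)),
                           function(i) subject_seed_for(spec$seed, i), 1))
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(phenotype = pheno, images = img_paths, motion = mot_paths,
                 dir = out_dir))
}
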