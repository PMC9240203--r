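small_spec <- function(seed = 1, ...) {
  cohort_spec(n_patients = 3, n_controls = 3, grid_shape = c(10, 12, 10),
              n_volumes = 40, seed = seed, ...)
}

test_that("cohort specifications are validated", {
  expect_error(cohort_spec(grid_shape = c(0, 10, 10)), "positive")
  expect_error(cohort_spec(dmn_roi_set = list()), "empty")
  expect_error(small_spec(effect_rois = list(
    list(label = "NOPE", direction = "increase", delta = 0.2))), "not in the DMN")
  expect_error(small_spec(base_coupling = 0.8,
    effect_rois = list(list(label = "MPFC", direction = "increase", delta = 0.3))),
    "delta")
  expect_error(cohort_spec(n_volumes = 4), "discarded")
  expect_error(cohort_spec(ar1_coefficient = 1.2), "ar1")
})

test_that("generated subjects are deterministic and well-formed", {
  spec <- small_spec()
  a <- generate_subject(spec, "patient", subject_seed = 99)
  b <- generate_subject(spec, "patient", subject_seed = 99)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$motion, b$motion)
  d <- dim(a$image$data)
  expect_equal(d[4], spec$n_volumes)
  expect_equal(d[1:3], spec$grid_shape)
  expect_equal(ncol(a$motion), 6L)
  expect_equal(nrow(a$motion), spec$n_volumes)
  c2 <- generate_subject(spec, "patient", subject_seed = 100)
  expect_false(identical(a$image$data, c2$image$data))
})

test_that("ground-truth coupling encodes group effects with the right sign", {
  spec <- small_spec()
  pt <- generate_subject(spec, "patient", 1)$truth
  pat <- pt$nominal_coupling
  con <- generate_subject(spec, "control", 1)$truth$nominal_coupling
  rois <- setNames(spec$dmn_roi_set,
                   vapply(spec$dmn_roi_set, `[[`, "", "label"))
  for (ef in spec$effect_rois) {
    vox <- rois[[ef$label]]$voxels
    expected <- spec$base_coupling +
      (if (ef$direction == "increase") ef$delta else -ef$delta)
    expect_equal(unique(pat[vox]), expected)
    expect_equal(unique(con[vox]), spec$base_coupling)
  }
  expect_true(all(pat >= 0 & pat < 1))
  expect_true(all(pt$coupling >= 0 & pt$coupling < 1))   # jittered weights
})

test_that("network signal power is confined to the 0.01-0.08 Hz band", {
  for (seed in 1:5) {
    set.seed(seed)
    s <- nethom:::bandlimited_signal(240, 2)
    P <- Mod(stats::fft(s))^2
    freqs <- (0:239) / 480
    freqs <- pmin(freqs, 1 / 2 - freqs)         # fold to [0, Nyquist]
    inband <- freqs >= 0.01 - 1e-12 & freqs <= 0.08 + 1e-12
    expect_lt(sum(P[!inband]) / sum(P), 0.01)
  }
})

test_that("in-ROI correlation increases monotonically with coupling delta", {
  # simulation over a grid of deltas; expected pairwise r rises with delta
  deltas <- c(0, 0.15, 0.3, 0.45)
  mean_r <- vapply(deltas, function(d) {
    spec <- small_spec(seed = 42, coupling_jitter = 0, drift_amplitude = 0,
      effect_rois = if (d > 0)
        list(list(label = "PCC_PCu", direction = "increase", delta = d))
      else list())
    rois <- setNames(spec$dmn_roi_set,
                     vapply(spec$dmn_roi_set, `[[`, "", "label"))
    idx <- nethom:::vox_linear_index(rois[["PCC_PCu"]]$voxels, spec$grid_shape)
    rs <- vapply(1:6, function(s) {
      img <- generate_subject(spec, "patient", subject_seed = s)$image
      d4 <- dim(img$data)
      Y <- t(matrix(img$data, prod(d4[1:3]), d4[4])[idx, ])
      R <- cor(Y); mean(R[upper.tri(R)])
    }, 1)
    mean(rs)
  }, 1)
  expect_true(all(diff(mean_r) > 0))
})

test_that("null cohorts show no systematic group difference in NH", {
  spec <- small_spec(seed = 7, effect_rois = list())
  mask <- dmn_truth_mask(spec)
  diffs <- vapply(1:6, function(s) {
    p <- generate_subject(spec, "patient", subject_seed = s)$image
    c0 <- generate_subject(spec, "control", subject_seed = s + 100)$image
    mean(compute_nh_map(p, mask)$data, na.rm = TRUE) -
      mean(compute_nh_map(c0, mask)$data, na.rm = TRUE)
  }, 1)
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.05)
})

test_that("gross-motion injection hits the requested peak on one axis only", {
  spec <- small_spec()
  tr0 <- generate_subject(spec, "control", 5)$motion
  tr1 <- inject_gross_motion(tr0, axis = 2, magnitude = 2.5)
  expect_equal(max(abs(tr1[, 2])), 2.5)
  expect_identical(tr1[, -2], tr0[, -2])
  expect_false(screen_motion(tr1, preprocess_config())$accept)
  tr2 <- inject_gross_motion(tr0, axis = 2, magnitude = 0.5)
  expect_true(screen_motion(tr2, preprocess_config())$accept)
  # exactly at the threshold: accepted (strict inequality)
  tr3 <- inject_gross_motion(tr0, axis = 1, magnitude = 2.0)
  expect_true(screen_motion(tr3, preprocess_config())$accept)
  expect_error(inject_gross_motion(tr0, axis = 7, magnitude = 1), "axis")
  expect_error(inject_gross_motion(tr0, axis = 1, magnitude = 0), "positive")
})

test_that("cohort generation writes a complete, reproducible bundle", {
  spec <- cohort_spec(n_patients = 2, n_controls = 2, grid_shape = c(8, 8, 8),
                      n_volumes = 20, seed = 3)
  d1 <- withr::local_tempdir()
  out <- generate_cohort(spec, d1, force = TRUE)
  expect_equal(nrow(out$phenotype), 4L)
  expect_true(all(file.exists(out$images)))
  expect_true(all(file.exists(out$motion)))
  expect_true(file.exists(file.path(d1, "ground_truth.json")))
  expect_error(generate_cohort(spec, d1), "force")

  d2 <- withr::local_tempdir()
  generate_cohort(spec, d2, force = TRUE)
  p1 <- readLines(file.path(d1, "phenotype.tsv"))
  p2 <- readLines(file.path(d2, "phenotype.tsv"))
  expect_identical(p1, p2)
  i1 <- read_ts_image(out$images[1])
  i2 <- read_ts_image(file.path(d2, basename(out$images[1])))
  expect_identical(i1$data, i2$data)
})

test_that("phenotype distributions track the configured group means", {
  spec <- cohort_spec(n_patients = 43, n_controls = 42,
                      grid_shape = c(6, 6, 6), n_volumes = 10, seed = 1)
  set.seed(10)
  ages_p <- c(); ages_c <- c()
  for (k in 1:12) {
    ph <- nethom:::simulate_phenotype(spec)
    ages_p <- c(ages_p, ph$age[ph$group == "patient"])
    ages_c <- c(ages_c, ph$age[ph$group == "control"])
  }
  # sample means within 3 SE of the configured 27.91 / 26.96
  expect_lt(abs(mean(ages_p) - 27.91), 3 * 6.48 / sqrt(length(ages_p)) + 0.05)
  expect_lt(abs(mean(ages_c) - 26.96), 3 * 5.31 / sqrt(length(ages_c)) + 0.05)
})
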