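test_that("volume discarding shifts the time index exactly", {
  img <- random_ts_image(Tn = 12, seed = 1)
  out <- discard_initial_volumes(img, 3)
  expect_equal(dim(out$data)[4], 9L)
  expect_identical(out$data[2, 3, 4, 1], img$data[2, 3, 4, 4])
  expect_identical(out$data[, , , 5], img$data[, , , 8])
  expect_identical(discard_initial_volumes(img, 0), img)
  expect_error(discard_initial_volumes(img, 12), "T")
})

test_that("motion screening applies strict thresholds per axis", {
  cfg <- preprocess_config()
  tr <- matrix(0, 20, 6)
  expect_true(screen_motion(tr, cfg)$accept)
  tr[5, 2] <- 2.3
  res <- screen_motion(tr, cfg)
  expect_false(res$accept)
  expect_equal(res$axis, 2L)
  expect_equal(res$peak, 2.3)
  # boundary value 2.0 on a rotation axis: strictly "more than" rejects
  tr2 <- matrix(0, 20, 6); tr2[3, 5] <- 2.0
  expect_true(screen_motion(tr2, cfg)$accept)
  tr2[3, 5] <- 2.0001
  expect_false(screen_motion(tr2, cfg)$accept)
  expect_error(screen_motion(matrix(0, 5, 4), cfg), "6")
})

test_that("nuisance regression produces residuals orthogonal to regressors", {
  img <- random_ts_image(shape = c(4, 4, 4), Tn = 40, seed = 5)
  X <- matrix(rnorm(40 * 8), 40, 8)
  out <- regress_nuisance(img, X)
  Y <- matrix(out$data, 64, 40)
  Yc <- Y - rowMeans(Y)
  Xc <- scale(X, scale = FALSE)
  expect_lt(max(abs(Yc %*% Xc)) / 40, 1e-8)
  # voxel mean preserved (global level untouched)
  expect_equal(rowMeans(Y), rowMeans(matrix(img$data, 64, 40)), tolerance = 1e-10)
  # a regressor equal to a voxel's own series removes that voxel's variance
  v <- img$data[1, 1, 1, ]
  out2 <- regress_nuisance(img, cbind(v - mean(v)))
  expect_lt(var(out2$data[1, 1, 1, ]), 1e-16)
  # identity on empty regressor set
  expect_identical(regress_nuisance(img, NULL), img)
  # rank-deficient design is refused
  expect_error(regress_nuisance(img, cbind(X[, 1], X[, 1])), "rank")
})

test_that("detrend + ideal bandpass keeps in-band and kills out-of-band power", {
  Tn <- 200; tr <- 2
  tt <- (0:(Tn - 1)) * tr
  shape <- c(2, 2, 2)
  power <- function(x) sum(x^2)
  mk <- function(series) {
    a <- array(0, c(shape, Tn))
    for (i in 1:2) for (j in 1:2) for (k in 1:2) a[i, j, k, ] <- series
    ts_image(a, tr = tr)
  }
  in_band <- sin(2 * pi * 0.05 * tt)
  out1 <- detrend_bandpass(mk(in_band), c(0.01, 0.08))
  expect_gt(power(out1$data[1, 1, 1, ]) / power(in_band), 0.99)

  out_band <- sin(2 * pi * 0.2 * tt)
  out2 <- detrend_bandpass(mk(out_band), c(0.01, 0.08))
  expect_lt(power(out2$data[1, 1, 1, ]) / power(out_band), 0.01)

  ramp <- seq(-3, 3, length.out = Tn)
  out3 <- detrend_bandpass(mk(ramp), c(0.01, 0.08))
  expect_lt(power(out3$data[1, 1, 1, ]) / power(ramp), 1e-6)

  expect_lt(max(abs(apply(out1$data, 1:3, mean))), 1e-10)
  expect_error(detrend_bandpass(mk(ramp), c(0.01, 0.5)), "Nyquist")
})

test_that("bandpass filtering is idempotent and linear", {
  img <- random_ts_image(shape = c(3, 3, 3), Tn = 60, seed = 9)
  once <- detrend_bandpass(img, c(0.01, 0.08))
  twice <- detrend_bandpass(once, c(0.01, 0.08))
  expect_equal(twice$data, once$data, tolerance = 1e-8)

  img2 <- random_ts_image(shape = c(3, 3, 3), Tn = 60, seed = 10)
  lhs <- detrend_bandpass(
    ts_image(2 * img$data + 3 * img2$data, img$affine, img$tr), c(0.01, 0.08))
  expect_equal(lhs$data,
               2 * once$data + 3 * detrend_bandpass(img2, c(0.01, 0.08))$data,
               tolerance = 1e-8)
})

test_that("Gaussian smoothing matches the closed-form separable kernel", {
  shape <- c(15, 15, 15)
  a <- array(0, c(shape, 1)); a[8, 8, 8, 1] <- 1
  img <- ts_image(a, tr = 2)               # 3 mm voxels by default
  out <- gaussian_smooth(img, 8)
  sigma <- 8 / (3 * 2 * sqrt(2 * log(2)))  # ~1.1327 voxels
  k <- exp(-((-7):7)^2 / (2 * sigma^2)); k <- k / sum(k)
  expected <- outer(outer(k, k), k)
  expect_lt(max(abs(array(out$data[, , , 1], shape) - expected)), 1e-6)
  expect_equal(sum(out$data), 1, tolerance = 1e-6)   # interior impulse mass
  # identity and constant-volume invariance
  expect_identical(gaussian_smooth(img, 0), img)
  cimg <- ts_image(array(5, c(6, 6, 6, 2)))
  expect_equal(gaussian_smooth(cimg, 8)$data, cimg$data, tolerance = 1e-10)
  expect_error(gaussian_smooth(img, -1), "fwhm")
})

test_that("smoothing commutes with axis transposition", {
  img <- random_ts_image(shape = c(7, 7, 7), Tn = 2, seed = 3)
  sm <- gaussian_smooth(img, 8)
  perm <- c(2, 3, 1)
  pimg <- ts_image(aperm(img$data, c(perm, 4)), img$affine, img$tr)
  psm <- gaussian_smooth(pimg, 8)
  expect_equal(psm$data, aperm(sm$data, c(perm, 4)), tolerance = 1e-10)
})

test_that("the full chain composes the stages in order and keeps metadata", {
  spec <- cohort_spec(n_patients = 2, n_controls = 2, grid_shape = c(8, 10, 8),
                      n_volumes = 30, seed = 2)
  sub <- generate_subject(spec, "control", 7)
  nuis <- nethom:::nuisance_rois(spec)
  cfg <- preprocess_config(n_discard = 5, fwhm_mm = 6)
  res <- preprocess_subject(sub$image, sub$motion, cfg, nuis$wm, nuis$csf)
  expect_equal(res$status, "ok")
  expect_equal(dim(res$image$data)[4], 25L)
  expect_identical(res$image$affine, sub$image$affine)
  expect_identical(res$image$tr, sub$image$tr)
  expect_length(res$log, 5L)

  # stage-by-stage equality with manual composition
  img <- discard_initial_volumes(sub$image, 5)
  trace <- sub$motion[6:30, ]
  reg <- cbind(trace,
               wm = nethom:::roi_mean_series(img, nuis$wm),
               csf = nethom:::roi_mean_series(img, nuis$csf))
  img <- regress_nuisance(img, reg)
  img <- gaussian_smooth(img, 6)
  img <- detrend_bandpass(img, c(0.01, 0.08))
  expect_equal(res$image$data, img$data, tolerance = 1e-12)

  # injected gross motion produces a typed rejection
  bad <- inject_gross_motion(sub$motion, 1, 2.5)
  rej <- preprocess_subject(sub$image, bad, cfg, nuis$wm, nuis$csf)
  expect_equal(rej$status, "rejected")
  expect_null(rej$image)
  expect_equal(rej$screen$axis, 1L)
})
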