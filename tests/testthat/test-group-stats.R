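std_maps <- function(n, mask, f = function(i) rnorm(sum(mask$data)), tag = "s") {
  lapply(seq_len(n), function(i)
    values_as_nh_map(f(i), mask, id = paste0(tag, i)))
}

test_that("voxel-wise t equals the scalar t-test oracle per voxel", {
  set.seed(31)
  mask <- cube_mask(c(4, 4, 4), 1:3, 1:3, 1:2)
  A <- std_maps(10, mask)
  B <- std_maps(10, mask)
  tm <- voxelwise_two_sample_t(A, B, mask)
  idx <- which(mask$data)
  for (v in idx[c(1, 5, 9, 18)]) {
    a <- vapply(A, function(m) m$data[v], 1)
    b <- vapply(B, function(m) m$data[v], 1)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(tm$t[v], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(tm$p[v], ref$p.value, tolerance = 1e-10)
  }
  expect_equal(tm$df, 18)
})

test_that("identical groups give t = 0 and swapped labels negate the map", {
  set.seed(32)
  mask <- cube_mask(c(3, 3, 3), 1:3, 1:3, 1:3)
  A <- std_maps(5, mask)
  tm0 <- voxelwise_two_sample_t(A, A, mask)
  expect_true(all(abs(tm0$t[mask$data]) < 1e-12))

  B <- std_maps(5, mask)
  tab <- voxelwise_two_sample_t(A, B, mask)
  tba <- voxelwise_two_sample_t(B, A, mask)
  expect_equal(tab$t[mask$data], -tba$t[mask$data], tolerance = 1e-12)
  expect_equal(tab$p[mask$data], tba$p[mask$data], tolerance = 1e-12)
})

test_that("summary-statistic t reproduces raw-data pooled t tests", {
  set.seed(33)
  x <- rnorm(15, 1, 2); y <- rnorm(12, 0.2, 1.5)
  ref <- t.test(x, y, var.equal = TRUE)
  got <- ttest_from_summary(15, mean(x), sd(x), 12, mean(y), sd(y))
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_equal(got$df, 25)
  expect_equal(ttest_from_summary(5, 3, 1, 5, 3, 1)$t, 0)
  expect_error(ttest_from_summary(1, 0, 1, 5, 0, 1), "n")
})

test_that("chi-square matches the O-E oracle and closed forms", {
  expect_equal(chi_square_2x2(matrix(c(10, 10, 10, 10), 2))$chisq, 0)
  expect_equal(chi_square_2x2(matrix(c(10, 0, 0, 10), 2))$chisq, 20)
  set.seed(34)
  for (i in 1:5) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chi_square_2x2(tab)$chisq, sum((tab - E)^2 / E),
                 tolerance = 1e-12)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(chi_square_2x2(tab)$chisq, unname(ref$statistic),
                 tolerance = 1e-10)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("pearson_corr matches the covariance-formula oracle", {
  expect_equal(pearson_corr(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_corr(1:10, -(1:10))$r, -1)
  set.seed(35)
  x <- rnorm(30); y <- rnorm(30)
  got <- pearson_corr(x, y)
  ref <- cor.test(x, y)
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  # listwise deletion of missing pairs
  x2 <- c(x, NA, 5); y2 <- c(y, 3, NA)
  expect_equal(pearson_corr(x2, y2)$r, got$r)
  expect_equal(pearson_corr(x2, y2)$n, 30)
  expect_error(pearson_corr(rep(1, 5), rnorm(5)), "variance")
})

test_that("smoothness estimation recovers a known kernel within 15%", {
  set.seed(36)
  shape <- c(16, 16, 16)
  mask <- cube_mask(shape, 2:15, 2:15, 2:15)
  fw <- 8
  maps <- lapply(1:8, function(i) {
    img <- ts_image(array(rnorm(prod(shape)), c(shape, 1)))
    gaussian_smooth(img, fw)$data[, , , 1]
  })
  est <- estimate_smoothness(maps, mask)
  expect_true(all(abs(est$fwhm_mm - fw) / fw < 0.15))

  # unsmoothed white noise: estimate close to one voxel (floor enforced)
  maps2 <- lapply(1:8, function(i) array(rnorm(prod(shape)), shape))
  est2 <- estimate_smoothness(maps2, mask)
  expect_true(all(est2$fwhm_vox >= 1 & est2$fwhm_vox < 1.35))

  # doubling voxel size doubles FWHM in mm, resels unchanged
  mask2 <- brain_mask(mask$data, affine = diag(c(6, 6, 6, 1)))
  est3 <- estimate_smoothness(maps, mask2)
  expect_equal(est3$fwhm_mm, 2 * est$fwhm_mm, tolerance = 1e-12)
  expect_equal(est3$resels, est$resels, tolerance = 1e-12)
})

test_that("cluster labeling obeys connectivity semantics and the flood-fill oracle", {
  shape <- c(5, 5, 5)
  b <- array(FALSE, shape)
  b[2, 2, 2] <- TRUE; b[3, 3, 2] <- TRUE   # diagonal in-plane touch
  expect_length(label_clusters(b, 6), 2L)
  expect_length(label_clusters(b, 26), 1L)

  one <- array(FALSE, shape); one[4, 4, 4] <- TRUE
  cl <- label_clusters(one, 26)
  expect_equal(cl[[1]]$extent, 1L)
  expect_equal(cl[[1]]$peak_index, c(4L, 4L, 4L))

  set.seed(37)
  for (conn in c(6, 18, 26)) {
    rb <- array(runif(prod(shape)) < 0.3, shape)
    got <- label_clusters(rb, conn)
    want <- flood_fill_oracle(rb, conn)
    expect_equal(lapply(got, `[[`, "voxels"), want)
  }
  expect_error(label_clusters(b, 10), "connectivity")
})

test_that("cluster peak reporting uses |t| with deterministic tie-breaks", {
  shape <- c(4, 4, 4)
  b <- array(FALSE, shape); b[1:3, 1, 1] <- TRUE
  stat <- array(0, shape)
  stat[1, 1, 1] <- -5; stat[2, 1, 1] <- 5; stat[3, 1, 1] <- 2
  cl <- label_clusters(b, 26, stat = stat, affine = diag(c(3, 3, 3, 1)))
  # tie on |t|: smallest linear index wins
  expect_equal(cl[[1]]$peak_linear, 1L)
  expect_equal(cl[[1]]$peak_stat, -5)
  expect_equal(cl[[1]]$peak_world, c(0, 0, 0))
})

test_that("GRF cluster p is monotone in extent and threshold", {
  df <- 38; resels <- 50
  ks <- seq(0.1, 5, length.out = 12)
  ps <- vapply(ks, function(k) grf_cluster_p(k, 3.9, df, resels), 1)
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))
  # a higher cluster-forming threshold makes any fixed extent rarer
  us <- c(3.2, 3.6, 4.0, 4.4)
  ps2 <- vapply(us, function(u) grf_cluster_p(1, u, df, resels), 1)
  expect_true(all(diff(ps2) < 0))
})

test_that("group comparison finds nothing on equal groups and respects direction swap", {
  set.seed(38)
  shape <- c(8, 8, 8)
  mask <- cube_mask(shape, 1:8, 1:8, 1:8)
  mk <- function(i) {
    img <- ts_image(array(rnorm(prod(shape)), c(shape, 1)))
    array(gaussian_smooth(img, 6)$data, shape)[mask$data]
  }
  A <- std_maps(6, mask, mk, tag = "a")
  B <- std_maps(6, mask, mk, tag = "b")
  cmpAB <- nh_group_comparison(A, B, mask)
  cmpBA <- nh_group_comparison(B, A, mask)
  # swapping group labels swaps directions, keeps extents and p values
  ab <- cmpAB$clusters; ba <- cmpBA$clusters
  expect_equal(nrow(ab), nrow(ba))
  if (nrow(ab)) {
    flip <- c("A>B" = "A<B", "A<B" = "A>B")
    ord <- function(x) x[order(x$extent, x$peak_t), ]
    ab2 <- ord(transform(ab, direction = unname(flip[direction]),
                         peak_t = -peak_t))
    expect_equal(ord(ba)$extent, ab2$extent)
    expect_equal(ord(ba)$p_corrected, ab2$p_corrected, tolerance = 1e-12)
  }
  # t = 0 map yields an empty table
  t0 <- voxelwise_two_sample_t(A, A, mask)
  sm <- cmpAB$smoothness
  expect_equal(nrow(grf_cluster_inference(t0, sm)), 0L)
})

test_that("cluster means equal the per-voxel average oracle", {
  set.seed(39)
  mask <- cube_mask(c(4, 4, 4), 1:4, 1:4, 1:4)
  maps <- std_maps(7, mask)
  cluster <- list(voxels = which(mask$data)[c(3, 9, 17)])
  got <- extract_cluster_means(maps, cluster)
  want <- vapply(maps, function(m) mean(m$data[cluster$voxels]), 1)
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
  # single-voxel cluster returns that voxel's values
  single <- list(voxels = which(mask$data)[5])
  expect_equal(unname(extract_cluster_means(maps, single)),
               vapply(maps, function(m) unname(m$data[single$voxels]), 1))
  # constant map gives the constant
  cmap <- values_as_nh_map(rep(2.5, sum(mask$data)), mask)
  expect_equal(unname(extract_cluster_means(list(cmap), cluster)), 2.5)
})

test_that("demographics table reproduces group statistics", {
  set.seed(40)
  rec <- data.frame(
    group = rep(c("patient", "control"), c(12, 10)),
    sex = sample(c("male", "female"), 22, TRUE),
    age = c(rnorm(12, 28, 6), rnorm(10, 27, 5)),
    education_years = c(rnorm(12, 13, 2), rnorm(10, 13.5, 2)),
    reaction_time = rnorm(22, 90, 50),
    mmse = rnorm(22, 28, 1))
  tab <- demographics_table(rec)
  expect_equal(nrow(tab), 5L)
  age_row <- tab[tab$variable == "age", ]
  ref <- t.test(age ~ factor(rec$group, c("patient", "control")), data = rec,
                var.equal = TRUE)
  expect_equal(age_row$statistic, unname(ref$statistic), tolerance = 1e-6)
  # identical groups: all statistics vanish
  rec2 <- rec; rec2$group <- rep(c("patient", "control"), 11)
  rec2[rec2$group == "control", c("age", "education_years", "reaction_time", "mmse")] <-
    rec2[rec2$group == "patient", c("age", "education_years", "reaction_time", "mmse")]
  rec2$sex <- rep("male", 22); rec2$sex[c(1, 2)] <- "female"
  tab2 <- demographics_table(rec2)
  expect_true(all(abs(tab2$statistic[tab2$test == "two-sample t"]) < 1e-10))
})
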