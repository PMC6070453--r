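grid_for_seg <- function(n = 61, sp = 1) {
  voxel_image(array(0, dim = c(n, n, n)), sp, role = "counts")
}

test_that("spherical VOIs use a radial margin and respect grid bounds", {
  g <- grid_for_seg()
  voi <- sphere_voi(c(0, 0, 0), 36, 10, g)
  # radius 28 mm -> volume of a 28-mm sphere
  expect_rel_equal(mask_volume(voi), 4 / 3 * pi * 2.8^3, 0.01)
  # margin 0 recovers the physical volume within voxelization error
  voi0 <- sphere_voi(c(0, 0, 0), 36, 0, g)
  expect_rel_equal(mask_volume(voi0), 4 / 3 * pi * 1.8^3, 0.01)
  expect_error(sphere_voi(c(0, 0, 0), 80, 0, grid_for_seg(n = 21)),
               "bounds")
})

test_that("fixed 8-cm sphere VOI has the textbook volume and covers the source", {
  g <- grid_for_seg(n = 91)
  voi <- fixed_sphere_voi(c(0, 0, 0), 80, g)
  expect_rel_equal(mask_volume(voi), 4 / 3 * pi * 4^3, 0.01)  # ~268 ml
  # contains the whole shell source (outer diameter < 80 mm)
  src <- shell_source_spec()
  outer <- sphere_voi(c(0, 0, 0), 2 * src$r_outer, 0, g)
  expect_equal(sum(outer$values * (1 - voi$values)), 0)
  # symmetric under axis reflection
  expect_equal(voi$values, voi$values[91:1, , ])
})

test_that("iso-contours of a Gaussian blob sit at the closed-form radius", {
  n <- 61
  co <- seq_len(n) - 31
  sigma <- 6
  d2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  blob <- voxel_image(array(100 * exp(-d2 / (2 * sigma^2)), dim = rep(n, 3)),
                      1, role = "counts")
  voi50 <- iso_contour_voi(blob, 0.5)
  r50 <- (3 * mask_volume(voi50) * 1000 / (4 * pi))^(1 / 3)
  expect_equal(r50, sigma * sqrt(2 * log(2)), tolerance = 1 / r50)
  # threshold 1.0 keeps only the unique maximum
  expect_equal(sum(iso_contour_voi(blob, 1.0)$values), 1)
  # lower thresholds strictly contain higher ones
  voi35 <- iso_contour_voi(blob, 0.35)
  voi10 <- iso_contour_voi(blob, 0.10)
  expect_equal(sum(voi35$values * (1 - voi10$values)), 0)
  expect_gt(mask_volume(voi10), mask_volume(voi35))
  # an all-zero region cannot be contoured
  z <- grid_for_seg(n = 11)
  expect_error(iso_contour_voi(z, 0.5), "positive")
})

test_that("Otsu threshold equals the brute-force between-class-variance maximiser", {
  set.seed(4)
  vals <- c(rnorm(400, 10, 2), rnorm(150, 40, 5))
  thr <- otsu_threshold(vals)
  # brute force over the same 256-bin candidate cuts
  edges <- seq(min(vals), max(vals), length.out = 257)
  bcv <- vapply(edges[2:256], function(t) {
    lo <- vals <= t; hi <- !lo
    if (!any(lo) || !any(hi)) return(-Inf)
    sum(lo) * sum(hi) * (mean(vals[lo]) - mean(vals[hi]))^2
  }, numeric(1))
  best <- edges[2:256][which.max(bcv)]
  bin_w <- diff(edges[1:2])
  expect_lt(abs(thr - best), bin_w + 1e-9)
  # shifting all values shifts the threshold by the same constant
  expect_equal(otsu_threshold(vals + 7.5), thr + 7.5, tolerance = 1e-9)
  # two-valued region: threshold strictly between the classes
  tv <- c(rep(0, 30), rep(100, 12))
  t2 <- otsu_threshold(tv)
  expect_gt(t2, 0); expect_lt(t2, 100)
  expect_error(otsu_threshold(rep(3, 10)), "degenerate")
})

test_that("Otsu VOI selects the bright class", {
  n <- 31
  vals <- array(0, dim = rep(n, 3))
  vals[10:20, 10:20, 10:20] <- 100
  img <- voxel_image(vals, 2, role = "counts")
  voi <- otsu_voi(img)
  expect_equal(voi$values, array(as.numeric(vals > 0), dim = rep(n, 3)))
  const <- voxel_image(array(5, dim = rep(n, 3)), 2, role = "counts")
  expect_error(otsu_voi(const), "degenerate")
})

test_that("shell subtraction is an exact set difference", {
  g <- grid_for_seg(n = 41)
  outer <- sphere_voi(c(0, 0, 0), 30, 0, g)
  inner <- sphere_voi(c(0, 0, 0), 16, 0, g)
  shell <- shell_subtract(outer, inner)
  expect_equal(mask_volume(shell), mask_volume(outer) - mask_volume(inner))
  expect_equal(sum(shell_subtract(outer, outer)$values), 0)
  disjoint <- sphere_voi(c(15, 0, 0), 6, 0, g)
  expect_equal(shell_subtract(outer, disjoint)$values,
               outer$values * (1 - disjoint$values))
})

test_that("every VOI rule is monotone in its size parameter", {
  g <- grid_for_seg()
  v_margin <- vapply(c(0, 4, 8, 12), function(m) {
    mask_volume(sphere_voi(c(0, 0, 0), 30, m, g))
  }, numeric(1))
  expect_true(all(diff(v_margin) > 0))
  v_diam <- vapply(c(20, 30, 40, 50), function(d) {
    mask_volume(fixed_sphere_voi(c(0, 0, 0), d, g))
  }, numeric(1))
  expect_true(all(diff(v_diam) > 0))
  co <- seq_len(61) - 31
  d2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  blob <- voxel_image(array(exp(-d2 / 72), dim = rep(61, 3)), 1,
                      role = "counts")
  v_thr <- vapply(c(0.1, 0.3, 0.5, 0.7), function(f) {
    mask_volume(iso_contour_voi(blob, f))
  }, numeric(1))
  expect_true(all(diff(v_thr) < 0))   # inverse for the threshold fraction
})

test_that("mask perturbation dilates and erodes by whole voxel layers", {
  g <- grid_for_seg(n = 31)
  m <- sphere_voi(c(0, 0, 0), 16, 0, g)
  up <- perturb_mask(m, 1)
  dn <- perturb_mask(m, -1)
  expect_gt(mask_volume(up), mask_volume(m))
  expect_lt(mask_volume(dn), mask_volume(m))
  expect_equal(sum(m$values * (1 - up$values)), 0)   # m subset of dilation
  expect_equal(sum(dn$values * (1 - m$values)), 0)   # erosion subset of m
  expect_equal(perturb_mask(m, 0)$values, m$values)
})

test_that("SPECT-threshold segmentation is less accurate than CT geometry on volume", {
  runs <- noisy_runs()
  src <- shell_source_spec()
  err_ct <- c(); err_spect <- c()
  for (r in runs) {
    truth_v <- mask_volume(r$phantom$truth_masks$inner)
    voi_ct <- sphere_voi(c(0, 0, 0), 2 * src$r_inner, 0, r$recon)
    region <- sphere_voi(c(0, 0, 0), 4 * src$r_outer, 0, r$recon)
    voi_iso <- iso_contour_voi(r$recon, 0.35, region)
    voi_otsu <- otsu_voi(r$recon, region)
    err_ct <- c(err_ct, abs(percent_difference(mask_volume(voi_ct),
                                               truth_v)))
    err_spect <- c(err_spect,
                   abs(percent_difference(mask_volume(voi_iso), truth_v)),
                   abs(percent_difference(mask_volume(voi_otsu), truth_v)))
  }
  expect_gte(mean(err_spect), mean(err_ct))
})

test_that("threshold calibration finds a fraction matching a known volume", {
  co <- seq_len(61) - 31
  d2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  blob <- voxel_image(array(exp(-d2 / 200), dim = rep(61, 3)), 1,
                      role = "counts")
  target <- 30  # ml
  f <- calibrate_iso_threshold(blob, target)
  got <- mask_volume(iso_contour_voi(blob, f))
  expect_rel_equal(got, target, 0.1)
})
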