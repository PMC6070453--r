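test_that("cps/MBq factor arithmetic and multi-position averaging", {
  cal <- calib_factor_from_voi(3.6e5, 600, 20)
  expect_equal(cal$factor, 30)
  expect_equal(calib_factor_from_voi(7.2e5, 600, 20)$factor, 60)
  multi <- calib_factor_from_voi(c(3.6e5, 3.6e5, 3.6e5), 600, 20)
  expect_equal(multi$factor, 30)
  expect_equal(multi$sigma, 0)
  expect_equal(multi$n_measurements, 3L)
  expect_error(calib_factor_from_voi(0, 600, 20), "positive")
  expect_error(calib_factor_from_voi(100, 600, -1), "positive")
})

test_that("planar petri calibration: replicate spread and background invariance", {
  cfg <- acquisition_config(n_projections = 1, matrix = 48, rng_seed = 1)
  disc <- disc_source(40, spacing = 4.8, n = 48)
  # five noisy replicates of the same dish: spread consistent with Poisson
  set.seed(99)
  imgs <- lapply(1:5, function(i) planar_acquire(disc, cfg, noise = TRUE))
  cal <- calib_factor_planar(imgs, 100, 40, cfg$time_per_projection, 4.8)
  expect_rel_equal(cal$factor, 10, 0.02)     # the configured sensitivity
  total <- 40 * 10 * cfg$time_per_projection
  expect_lt(cal$sigma / cal$factor, 5 / sqrt(total))
  # a uniform background is removed exactly in the noise-free case
  img0 <- planar_acquire(disc, cfg, noise = FALSE)
  cal0 <- calib_factor_planar(list(img0), 100, 40,
                              cfg$time_per_projection, 4.8)
  calb <- calib_factor_planar(list(img0 + 7), 100, 40,
                              cfg$time_per_projection, 4.8)
  expect_rel_equal(calb$factor, cal0$factor, 1e-6)
  expect_error(calib_factor_planar(list(img0), 100, 0,
                                   cfg$time_per_projection, 4.8),
               "positive")
  expect_error(calib_factor_planar(list(img0), 500, 40,
                                   cfg$time_per_projection, 4.8), "ROI")
})

test_that("calibration factor is invariant to the activity level", {
  cfg <- acquisition_config(n_projections = 1, matrix = 48, rng_seed = 1)
  f <- vapply(c(10, 40, 160), function(a) {
    img <- planar_acquire(disc_source(a, spacing = 4.8, n = 48), cfg)
    calib_factor_planar(list(img), 100, a, cfg$time_per_projection,
                        4.8)$factor
  }, numeric(1))
  expect_lt(diff(range(f)) / mean(f), 1e-9)
})

test_that("recovery-curve fitting recovers known parameters to 3 s.f.", {
  v0 <- 18.5; p <- 1.4
  vols <- c(2, 5, 10, 20, 40, 80, 150)
  rc <- 1 - exp(-(vols / v0)^p)
  fit <- fit_recovery_curve(vols, rc)
  expect_rel_equal(fit$v0, v0, 5e-4)
  expect_rel_equal(fit$p, p, 5e-4)
  # fitted curve is monotone on [1, 300] ml (flat only once saturated at 1)
  grid <- seq(1, 300, length.out = 200)
  expect_true(all(diff(rc_value(fit, grid)) >= 0))
  expect_true(all(diff(rc_value(fit, seq(1, 60, by = 1))) > 0))
  # all-RC-1 data degenerate to the identity correction
  fit1 <- fit_recovery_curve(c(5, 20, 80), c(1, 1, 1))
  expect_rel_equal(apply_recovery(10, 50, fit1), 10, 0.01)
  expect_error(fit_recovery_curve(c(5, 5, 5), c(0.5, 0.6, 0.7)),
               "distinct")
  expect_error(fit_recovery_curve(c(5, 10, 20), c(0.5, 0.6, 1.5)), "")
})

test_that("recovery application divides by RC with an extrapolation guard", {
  fit <- fit_recovery_curve(c(2, 5, 10, 20, 40),
                            1 - exp(-(c(2, 5, 10, 20, 40) / 10)))
  v_rc1 <- 10 * (-log(1 - 0.999))^(1)       # essentially RC = 1
  expect_rel_equal(apply_recovery(5, 500, fit), 5, 0.01)
  v_half <- 10 * (-log(0.5))                 # RC = 0.5 for p = 1, v0 = 10
  expect_rel_equal(apply_recovery(5, v_half, fit), 10, 0.02)
  expect_error(apply_recovery(5, 0.05, fit), "floor")
})

test_that("the PVC-threshold volume matches a numeric root of the curve", {
  fit <- fit_recovery_curve(c(2, 5, 10, 20, 40, 80),
                            1 - exp(-(c(2, 5, 10, 20, 40, 80) / 12)^1.3))
  v95 <- pvc_threshold_volume(fit, 0.95)
  root <- uniroot(function(v) rc_value(fit, v) - 0.95, c(0.1, 1000))$root
  expect_rel_equal(v95, root, 1e-4)
  expect_rel_equal(rc_value(fit, v95), 0.95, 1e-6)
})

test_that("an end-to-end recovery correction fixes a 26-ml sphere within 10%", {
  # fit the curve on four spheres, then correct an independent 26-ml sphere
  cfg <- acquisition_config(n_projections = 24, matrix = 32, rng_seed = 9)
  rcfg <- recon_config(8, 6, "ideal", resolution_recovery = FALSE)
  measure <- function(volume_ml) {
    sp <- sphere_phantom_fixture(volume_ml, 2, 9.6, 32)
    proj <- acquire(sp$phantom$activity, sp$phantom$density, cfg,
                    noise = FALSE)
    rec <- osem_reconstruct(proj, sp$phantom$density, rcfg)
    est <- counts_in_voi(rec, sp$mask) / rec$factor_truth
    list(rc = est / sp$activity_mbq, est = est, truth = sp$activity_mbq,
         vol = sp$volume_ml)
  }
  cal_vols <- c(8, 16, 40, 100)
  rcs <- lapply(cal_vols, measure)
  fit <- fit_recovery_curve(cal_vols, vapply(rcs, `[[`, numeric(1), "rc"))
  probe <- measure(26)
  corrected <- apply_recovery(probe$est, probe$vol, fit)
  expect_rel_equal(corrected, probe$truth, 0.10)
})

test_that("a geometry-matched calibration beats a small-sphere calibration", {
  # shell-matched factor vs 16-ml-sphere factor, applied to the same
  # comparison reconstruction (noise-free, identical acquisition settings)
  cfg <- acquisition_config(n_projections = 24, matrix = 32, rng_seed = 13)
  rcfg <- recon_config(8, 6, "ideal", resolution_recovery = FALSE)
  ph <- small_phantom()
  rec <- osem_reconstruct(
    acquire(ph$activity, ph$density, cfg, noise = FALSE), ph$density, rcfg)
  src <- shell_source_spec()
  voi <- sphere_voi(c(0, 0, 0), 2 * src$r_outer, 5, rec)
  cps <- counts_in_voi(rec, voi)
  a_true <- total_activity(ph$activity)

  # shell-matched: same geometry, same VOI rule
  ph_cal <- make_body_phantom(source = shell_source_spec(site = "H2"),
                              spacing = 9.6, fov = 32 * 9.6)
  rec_cal <- osem_reconstruct(
    acquire(ph_cal$activity, ph_cal$density, cfg, noise = FALSE),
    ph_cal$density, rcfg)
  src_cal <- shell_source_spec(site = "H2")
  f_shell <- counts_in_voi(rec_cal,
                           sphere_voi(c(0, 0, 0), 2 * src_cal$r_outer, 5,
                                      rec_cal)) /
    total_activity(ph_cal$activity)

  # 16-ml sphere with a tight VOI (partial-volume-loaded factor)
  sp16 <- sphere_phantom_fixture(16, 2, 9.6, 32)
  rec16 <- osem_reconstruct(
    acquire(sp16$phantom$activity, sp16$phantom$density, cfg,
            noise = FALSE), sp16$phantom$density, rcfg)
  f_16 <- counts_in_voi(rec16, sp16$mask) / sp16$activity_mbq

  err_shell <- abs(cps / f_shell - a_true) / a_true
  err_16 <- abs(cps / f_16 - a_true) / a_true
  expect_lte(err_shell, err_16 + 0.02)
})
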