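fake_projection_set <- function(c_low, c_up, w_low = 17.8, w_up = 21.4,
                                w_pk = 41.6) {
  structure(list(
    counts = list(pp208 = array(0, dim = c(2, 2, 1)),
                  ls208 = array(c_low, dim = c(2, 2, 1)),
                  us208 = array(c_up, dim = c(2, 2, 1))),
    windows = list(pp208 = list(width_kev = w_pk),
                   ls208 = list(width_kev = w_low),
                   us208 = list(width_kev = w_up))),
    class = "projection_set")
}

test_that("TEW trapezoid reproduces the hand-computed cases", {
  # zero neighbours give zero scatter
  expect_equal(max(tew_estimate(fake_projection_set(0, 0))), 0)
  # equal widths and equal counts: the trapezoid collapses to S = C
  expect_equal(max(tew_estimate(fake_projection_set(70, 70, 20, 20, 20))),
               70)
  # the clinical 178/214/208 windows, C_low = 100, C_up = 50
  s <- tew_estimate(fake_projection_set(100, 50))
  expect_equal(max(s), (100 / 17.8 + 50 / 21.4) / 2 * 41.6,
               tolerance = 1e-12)
  expect_equal(max(s), 165.45, tolerance = 1e-3)
  expect_error(tew_estimate(fake_projection_set(1, 1), lower = "nope"),
               "window")
})

test_that("MLEM leaves a consistent initial image unchanged (fixed point)", {
  n <- 24; sp <- 9.6
  cfg <- acquisition_config(n_projections = 8, matrix = n, rng_seed = 1,
                            scatter = list(photopeak_fraction = 0,
                                           window_fraction = 0,
                                           kernel_fwhm_mm = 60))
  # activity identical to the reconstructor's uniform-disk initial image
  cx <- (n - 1) / 2
  disk <- outer((seq_len(n) - 1 - cx)^2, (seq_len(n) - 1 - cx)^2,
                "+") <= (n / 2 - 1)^2
  vox_ml <- sp^3 / 1000
  vals <- array(0, dim = c(n, n, n))
  vals[rep(disk, n)] <- 1 / vox_ml          # 1 MBq per voxel
  act <- voxel_image(vals, sp, role = "activity")
  dens <- voxel_image(array(0, dim = c(n, n, n)), sp, role = "density")
  proj <- acquire(act, dens, cfg, noise = FALSE)
  rec <- osem_reconstruct(proj, dens,
                          recon_config(1, 1, "none",
                                       resolution_recovery = TRUE))
  x <- rec$values / rec$factor_truth        # back to MBq per voxel
  expect_lt(max(abs(x[rep(disk, n)] - 1)), 1e-8)
  expect_equal(max(abs(x[!rep(disk, n)])), 0)
})

test_that("all-zero projections reconstruct to a zero image", {
  n <- 16
  act <- voxel_image(array(0, dim = c(n, n, n)), 9.6, role = "activity")
  dens <- voxel_image(array(0, dim = c(n, n, n)), 9.6, role = "density")
  cfg <- acquisition_config(n_projections = 4, matrix = n, rng_seed = 1)
  proj <- acquire(act, dens, cfg, noise = FALSE)
  rec <- osem_reconstruct(proj, dens, recon_config(3, 2, "none"))
  expect_equal(max(abs(rec$values)), 0)
})

test_that("MLEM log-likelihood is non-decreasing on Poisson data", {
  ph <- small_phantom()
  proj <- acquire(ph$activity, ph$density,
                  small_config(n_projections = 8, seed = 6), noise = TRUE)
  rec <- osem_reconstruct(proj, ph$density,
                          recon_config(8, 1, "ideal",
                                       resolution_recovery = FALSE),
                          track_loglik = TRUE)
  expect_true(all(diff(rec$loglik) >= -1e-7 * abs(rec$loglik[1])))
})

test_that("a matched model recovers a uniform cylinder away from the edges", {
  cyl <- luquant:::cylinder_phantom(9.6, 32)
  cfg <- acquisition_config(n_projections = 24, matrix = 32, rng_seed = 2)
  proj <- acquire(cyl$activity, cyl$density, cfg, noise = FALSE)
  rec <- osem_reconstruct(proj, cyl$density,
                          recon_config(15, 8, "ideal",
                                       resolution_recovery = TRUE))
  interior <- perturb_mask(cyl$mask, -2)
  conc <- rec$values / rec$factor_truth / voxel_volume_ml(rec)
  m <- sum(conc * interior$values) / sum(interior$values)
  expect_rel_equal(m, cyl$concentration, 0.05)
})

test_that("invalid reconstruction settings are rejected", {
  ph <- small_phantom()
  proj <- small_noisefree_proj()   # 24 projections
  expect_error(osem_reconstruct(proj, ph$density, recon_config(2, 7)),
               "divide")
  bad_term <- list(pp208 = array(-1, dim = dim(proj$counts$pp208)))
  expect_error(osem_reconstruct(proj, ph$density, recon_config(2, 6),
                                scatter_term = bad_term), "nonnegative")
})

test_that("photopeak volumes sum voxelwise and commute", {
  ph <- make_body_phantom(source = shell_source_spec(), spacing = 9.6,
                          fov = 32 * 9.6)
  cfg <- acquisition_config(n_projections = 12, matrix = 32, rng_seed = 3,
                            photopeaks = c(113, 208))
  proj <- acquire(ph$activity, ph$density, cfg, noise = FALSE)
  r113 <- osem_reconstruct(proj, ph$density,
                           recon_config(4, 6, "ideal", photopeaks = 113))
  r208 <- osem_reconstruct(proj, ph$density,
                           recon_config(4, 6, "ideal", photopeaks = 208))
  s12 <- sum_photopeaks(list(r113, r208))
  s21 <- sum_photopeaks(list(r208, r113))
  expect_equal(s12$values, s21$values)
  expect_rel_equal(sum(s12$values), sum(r113$values) + sum(r208$values),
                   0.001)
  # summing with a zero volume is the identity
  zero <- luquant:::with_values(r208, r208$values * 0)
  expect_equal(sum_photopeaks(list(r208, zero))$values, r208$values)
  # a dual-peak reconstruction equals the sum of the single-peak ones
  both <- osem_reconstruct(proj, ph$density,
                           recon_config(4, 6, "ideal",
                                        photopeaks = c(113, 208)))
  expect_equal(both$values, s12$values, tolerance = 1e-9)
})

test_that("the Gaussian post-filter preserves counts and has the right width", {
  n <- 33; sp <- 2
  vals <- array(0, dim = c(n, n, n)); vals[17, 17, 17] <- 100
  img <- voxel_image(vals, sp, role = "counts")
  out <- gaussian_postfilter(img, 8)
  expect_rel_equal(sum(out$values), sum(vals), 0.001)
  # FWHM of the filtered delta from the second moment of the x-profile
  prof <- apply(out$values, 1, sum)
  x <- (seq_len(n) - 17) * sp
  sigma <- sqrt(sum(prof * x^2) / sum(prof))
  expect_equal(2.354820045 * sigma, 8, tolerance = 0.5 / 8)
  # fwhm 0 is the identity, negative is an error
  expect_equal(gaussian_postfilter(img, 0)$values, vals)
  expect_error(gaussian_postfilter(img, -1), ">= 0")
})

test_that("scatter corrections rank ideal <= TEW <= none in total-activity error", {
  ph <- small_phantom()
  cfg <- small_config(seed = 21)
  proj <- acquire(ph$activity, ph$density, cfg, noise = TRUE)
  a_true <- total_activity(ph$activity)
  body_voi <- ph$truth_masks$body
  err <- vapply(c("ideal", "TEW", "none"), function(mode) {
    rec <- osem_reconstruct(proj, ph$density,
                            recon_config(8, 6, mode,
                                         resolution_recovery = TRUE))
    est <- counts_in_voi(rec, body_voi) / rec$factor_truth
    abs(est - a_true) / a_true
  }, numeric(1))
  expect_lte(err[["ideal"]], err[["TEW"]] + 0.01)
  expect_lte(err[["TEW"]], err[["none"]] + 0.01)
})
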