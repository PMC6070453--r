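test_that("energy windows carry their keV widths", {
  w <- energy_window(208, 0.10, "photopeak")
  expect_equal(w$width_kev, 41.6)
  expect_equal(energy_window(178, 0.05, "lower_scatter")$width_kev, 17.8)
  expect_error(energy_window(-10, 0.05), "")
})

test_that("forward projection conserves counts and is linear", {
  n <- 32; sp <- 4.8
  cfg <- small_config()
  vals <- array(0, dim = c(n, n, n))
  vals[14:18, 14:18, 14:18] <- 3   # small cube source, MBq/ml
  a <- voxel_image(vals, sp, role = "activity")
  mu0 <- voxel_image(array(0, dim = c(n, n, n)), sp, role = "mu")
  A <- total_activity(a)
  expected <- A * cfg$sensitivity[["208"]] * cfg$time_per_projection
  for (ang in c(0, 37, 101.5)) {
    p <- forward_project(a, mu0, cfg, ang, use_psf = FALSE, use_att = FALSE)
    expect_rel_equal(sum(p), expected, 0.001)
  }
  # blur never changes the total by more than 0.5%
  p0 <- forward_project(a, mu0, cfg, 37, use_psf = FALSE, use_att = FALSE)
  pb <- forward_project(a, mu0, cfg, 37, use_psf = TRUE, use_att = FALSE)
  expect_rel_equal(sum(pb), sum(p0), 0.005)
  # linearity in activity
  a2 <- luquant:::with_values(a, a$values * 3.5)
  expect_equal(forward_project(a2, mu0, cfg, 37),
               3.5 * forward_project(a, mu0, cfg, 37), tolerance = 1e-10)
  # zero activity projects to zeros
  z <- luquant:::with_values(a, a$values * 0)
  expect_equal(sum(abs(forward_project(z, mu0, cfg, 63))), 0)
})

test_that("attenuation follows Beer-Lambert through a uniform slab", {
  n <- 32; sp <- 4.8
  cfg <- small_config()
  vals <- array(0, dim = c(n, n, n)); vals[16, 16, 16] <- 5
  a <- voxel_image(vals, sp, role = "activity")
  mu0 <- voxel_image(array(0, dim = c(n, n, n)), sp, role = "mu")
  muv <- array(0, dim = c(n, n, n))
  muv[, 17:26, ] <- 0.15            # 10 voxels = 4.8 cm of mu = 0.15/cm
  mus <- voxel_image(muv, sp, role = "mu")
  p_air <- forward_project(a, mu0, cfg, 0, use_psf = FALSE, use_att = FALSE)
  p_att <- forward_project(a, mus, cfg, 0, use_psf = FALSE, use_att = TRUE)
  expect_rel_equal(sum(p_att) / sum(p_air), exp(-0.15 * 10 * sp / 10), 1e-6)
})

test_that("scatter model scales with its fractions and conserves its kernel", {
  ph <- small_phantom()
  cfg <- small_config()
  mu <- mu_map_from_density(ph$density, 208)
  sc <- scatter_project(ph$activity, mu, cfg, 30)
  broad <- forward_project(ph$activity,
                           luquant:::with_values(mu, mu$values * 0, "mu"),
                           cfg, 30, use_psf = FALSE, use_att = FALSE)
  # photopeak scatter total = fraction x broad-beam total (kernel normalised)
  expect_rel_equal(sum(sc$pp),
                   cfg$scatter$photopeak_fraction * sum(broad), 0.005)
  # halving the fraction halves the scatter everywhere
  cfg2 <- cfg
  cfg2$scatter$photopeak_fraction <- cfg$scatter$photopeak_fraction / 2
  sc2 <- scatter_project(ph$activity, mu, cfg2, 30)
  expect_equal(sc2$pp, sc$pp / 2, tolerance = 1e-12)
  # zero fraction yields zero scatter in every window
  cfg0 <- cfg
  cfg0$scatter <- list(photopeak_fraction = 0, window_fraction = 0,
                       kernel_fwhm_mm = 60)
  sc0 <- scatter_project(ph$activity, mu, cfg0, 30)
  expect_true(all(vapply(sc0, function(m) sum(abs(m)) == 0, logical(1))))
})

test_that("acquire is deterministic under its seed and separates components", {
  ph <- small_phantom()
  p1 <- acquire(ph$activity, ph$density, small_config(seed = 42))
  p2 <- acquire(ph$activity, ph$density, small_config(seed = 42))
  expect_identical(p1$counts, p2$counts)
  # counts are nonnegative integers after noise
  expect_true(all(p1$counts$pp208 >= 0))
  expect_true(all(p1$counts$pp208 == round(p1$counts$pp208)))
  # components sum to the pre-noise mean
  p0 <- acquire(ph$activity, ph$density, small_config(seed = 42),
                noise = FALSE)
  expect_equal(p0$counts$pp208,
               p0$components$primary$pp208 + p0$components$scatter$pp208,
               tolerance = 1e-12)
})

test_that("Poisson sampling has the right first two moments", {
  # a flat source gives a pixel of known mean; replicate over seeds
  n <- 16
  vals <- array(0, dim = c(n, n, n)); vals[8, 8, 8] <- 1
  a <- voxel_image(vals, 4.8, role = "activity")
  d <- voxel_image(array(0, dim = c(n, n, n)), 4.8, role = "density")
  cfg0 <- acquisition_config(n_projections = 2, matrix = n, rng_seed = 1)
  m0 <- acquire(a, d, cfg0, noise = FALSE)$counts$pp208
  px <- which(m0 == max(m0), arr.ind = TRUE)[1, ]
  mean_true <- max(m0)
  reps <- vapply(1:400, function(s) {
    cfg <- acquisition_config(n_projections = 2, matrix = n, rng_seed = s)
    acquire(a, d, cfg)$counts$pp208[px[1], px[2], px[3]]
  }, numeric(1))
  expect_lt(abs(mean(reps) - mean_true), 3.5 * sqrt(mean_true / 400))
})

test_that("the shell-only annulus projects positive counts (spill-in source)", {
  ph <- small_phantom()
  p <- small_noisefree_proj()
  src <- shell_source_spec()
  sp <- ph$activity$spacing[1]
  n <- dim(ph$activity$values)[1]
  co <- (seq_len(n) - (n + 1) / 2) * sp
  r2 <- outer(co^2, co^2, "+")     # (x, z) radius in the projection plane
  annulus <- r2 > src$r_inner^2 & r2 < src$r_outer^2
  expect_true(all(p$counts$pp208[, , 1][annulus] > 0))
})

test_that("planar acquisition conserves counts into a 10-cm ROI", {
  cfg <- acquisition_config(n_projections = 1, matrix = 48, rng_seed = 1)
  disc <- disc_source(40, spacing = 4.8, n = 48)
  img <- planar_acquire(disc, cfg, distance = 100)
  expected <- 40 * cfg$sensitivity[["208"]] * cfg$time_per_projection
  expect_rel_equal(sum(img), expected, 0.005)
  # >= 99% of the counts inside a 10-cm-diameter circle around the dish
  n <- nrow(img)
  co <- (seq_len(n) - (n + 1) / 2) * 4.8
  roi <- outer(co^2, co^2, "+") <= 50^2
  expect_gte(sum(img[roi]) / sum(img), 0.99)
  # zero activity -> zeros
  expect_equal(sum(abs(planar_acquire(disc_source(0), cfg))), 0)
})

test_that("acquisition means are linear in the activity level", {
  ph <- small_phantom()
  cfg <- small_config(n_projections = 4)
  p1 <- acquire(ph$activity, ph$density, cfg, noise = FALSE)
  a3 <- luquant:::with_values(ph$activity, ph$activity$values * 3)
  p3 <- acquire(a3, ph$density, cfg, noise = FALSE)
  for (w in names(p1$counts)) {
    expect_equal(p3$counts[[w]], 3 * p1$counts[[w]], tolerance = 1e-9)
  }
})
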