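# Shared desk-scale fixtures, built once per test run and cached.
# Grids are deliberately small (32^3 at 9.6 mm, 24 angles) so the whole
# suite stays within a desktop time budget; the acceptance tests use the
# full 64^3 / 60-angle scale.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_phantom <- function() {
  fixture("small_phantom", function() {
    make_body_phantom(source = shell_source_spec(), spacing = 9.6,
                      fov = 32 * 9.6)
  })
}

small_config <- function(n_projections = 24, seed = 1, ...) {
  acquisition_config(n_projections = n_projections, matrix = 32,
                     rng_seed = seed, ...)
}

small_noisefree_proj <- function() {
  fixture("small_noisefree_proj", function() {
    ph <- small_phantom()
    acquire(ph$activity, ph$density, small_config(seed = 11), noise = FALSE)
  })
}

small_ideal_recon <- function() {
  fixture("small_ideal_recon", function() {
    ph <- small_phantom()
    osem_reconstruct(small_noisefree_proj(), ph$density,
                     recon_config(10, 6, "ideal",
                                  resolution_recovery = TRUE))
  })
}

# ten noisy medium-scale runs (48^3 at 6.4 mm) shared by the segmentation
# and quantification ordering properties
noisy_runs <- function(n_seeds = 10) {
  fixture("noisy_runs", function() {
    ph <- make_body_phantom(source = shell_source_spec(), spacing = 6.4,
                            fov = 48 * 6.4)
    lapply(seq_len(n_seeds), function(s) {
      cfg <- acquisition_config(n_projections = 24, matrix = 48,
                                rng_seed = 100 + s)
      proj <- acquire(ph$activity, ph$density, cfg, noise = TRUE)
      rec <- osem_reconstruct(proj, ph$density,
                              recon_config(6, 6, "ideal",
                                           resolution_recovery = TRUE))
      list(phantom = ph, recon = rec)
    })
  })
}

# uniform activity sphere in the water body phantom on a small grid
sphere_phantom_fixture <- function(volume_ml = 26, conc = 2, spacing = 9.6,
                                   grid_n = 32) {
  ph <- make_body_phantom(body_phantom_spec(), source = NULL,
                          spacing = spacing, fov = grid_n * spacing)
  luquant:::add_sphere_source(ph, c(0, 0, 0), volume_ml, conc)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
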