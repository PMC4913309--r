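test_that("empty scene is baseline everywhere with no emitters", {
  sc <- simulate_scene(scene_spec(field_shape = c(64, 64), n_slices = 4,
                                  n_cells = 0, baseline_offset = 100,
                                  read_noise_sd = 0, shot_noise = FALSE,
                                  seed = 1))
  expect_equal(nrow(sc$truth$emitters), 0L)
  expect_true(all(sc$stack$voxels == 100))
  expect_true(all(sc$truth$cell_masks == 0L))
})

test_that("single noiseless emitter peaks at its recorded position", {
  sc <- simulate_scene(scene_spec(field_shape = c(64, 64), n_slices = 8,
                                  n_cells = 1, cell_radius_range = c(10, 10),
                                  fixed_counts = 1L, autofluor_amplitude = 0,
                                  read_noise_sd = 0, shot_noise = FALSE,
                                  baseline_offset = 0, seed = 3))
  em <- sc$truth$emitters
  expect_equal(nrow(em), 1L)
  idx <- arrayInd(which.max(sc$stack$voxels), dim(sc$stack$voxels))
  expect_lte(abs(idx[1] - 1 - em$y), 1)   # y
  expect_lte(abs(idx[2] - 1 - em$x), 1)   # x
  expect_lte(abs(idx[3] - 1 - em$z), 1)   # z
})

test_that("scene generation is deterministic and self-consistent", {
  spec <- scene_spec(field_shape = c(160, 160), n_slices = 8, n_cells = 4,
                     cell_radius_range = c(12, 16),
                     mean_spots_per_cell = 50, seed = 17)
  a <- simulate_scene(spec)
  b <- simulate_scene(spec)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$emitters, b$truth$emitters)
  expect_equal(nrow(a$truth$emitters), sum(a$truth$cells$true_count))
  # every emitter inside its cell's footprint
  labs <- a$truth$cell_masks
  at <- labs[cbind(round(a$truth$emitters$y) + 1,
                   round(a$truth$emitters$x) + 1)]
  expect_true(all(at == a$truth$emitters$cell))
})

test_that("adding a cell does not perturb earlier cells", {
  base <- scene_spec(field_shape = c(200, 200), n_slices = 6, n_cells = 3,
                     cell_radius_range = c(12, 16),
                     mean_spots_per_cell = 20, seed = 23)
  more <- scene_spec(field_shape = c(200, 200), n_slices = 6, n_cells = 4,
                     cell_radius_range = c(12, 16),
                     mean_spots_per_cell = 20, seed = 23)
  a <- simulate_scene(base)$truth
  b <- simulate_scene(more)$truth
  expect_equal(a$cells[, c("cell", "cx", "cy", "radius", "true_count")],
               b$cells[1:3, c("cell", "cx", "cy", "radius", "true_count")])
  expect_equal(a$emitters, b$emitters[b$emitters$cell <= 3, ],
               ignore_attr = TRUE)
})

test_that("rendered emitter conserves photons to 1%", {
  # amplitude large enough that 16-bit rounding is negligible relative to
  # the total; seed chosen so the PSF support fits inside the volume
  sxy <- 1.5; sz <- 1.5; amp <- 20000
  sc <- simulate_scene(scene_spec(field_shape = c(96, 96), n_slices = 30,
                                  n_cells = 1, cell_radius_range = c(8, 8),
                                  fixed_counts = 1L, psf_sigma_xy = sxy,
                                  psf_sigma_z = sz, spot_peak_photons = amp,
                                  autofluor_amplitude = 0, read_noise_sd = 0,
                                  shot_noise = FALSE, baseline_offset = 0,
                                  seed = 3))
  em <- sc$truth$emitters
  expect_true(em$z > 6 && em$z < 23)  # PSF fits axially
  expected <- amp * (2 * pi)^1.5 * sxy^2 * sz
  expect_lt(abs(sum(sc$stack$voxels) - expected) / expected, 0.01)
})

test_that("crowded fields fail with an explicit placement error", {
  expect_error(
    simulate_scene(scene_spec(field_shape = c(64, 64), n_cells = 30,
                              cell_radius_range = c(12, 14), seed = 1)),
    "non-overlapping|too large")
})

test_that("population spec validates its fractions and means", {
  expect_error(population_spec(inhibition = 1.2), "fraction")
  expect_error(population_spec(insensitive_fraction = -0.1), "fraction")
  expect_error(population_spec(mu_untreated = 0), "> 0")
  expect_error(population_spec(dispersion = -1), "> 0")
})

test_that("degenerate mixtures collapse to the untreated distribution", {
  ref <- simulate_count_populations(population_spec(inhibition = 0,
                                                    seed = 11))
  # inhibition 0: treated is numerically the same draw whatever the
  # insensitive fraction
  alt <- simulate_count_populations(
    population_spec(inhibition = 0, insensitive_fraction = 0.7, seed = 11))
  expect_identical(ref$treated, alt$treated)
  # insensitive_fraction 1 neutralizes any inhibition
  full <- simulate_count_populations(
    population_spec(inhibition = 0.9, insensitive_fraction = 1, seed = 11))
  expect_identical(ref$treated, full$treated)
})

test_that("treated sample mean follows the mixture law", {
  # pure inhibition: mean -> mu * (1 - inhibition)
  p <- simulate_count_populations(population_spec(
    mu_untreated = 100, dispersion = 5, inhibition = 0.8,
    insensitive_fraction = 0, n_cells = 10000, seed = 31))
  se <- sd(p$treated) / sqrt(length(p$treated))
  expect_lt(abs(mean(p$treated) - 20), 3 * se)
  # mixture: mean -> f * mu + (1 - f) * mu * (1 - inhibition)
  q <- simulate_count_populations(population_spec(
    mu_untreated = 100, dispersion = 5, inhibition = 0.8,
    insensitive_fraction = 0.3, n_cells = 10000, seed = 32))
  se <- sd(q$treated) / sqrt(length(q$treated))
  expect_lt(abs(mean(q$treated) - (0.3 * 100 + 0.7 * 20)), 3 * se)
})
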