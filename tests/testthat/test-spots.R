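test_that("flat slices yield no candidates", {
  st <- image_stack(array(100, c(32, 32, 2)), 160, 300)
  cand <- detect_candidates(st)
  expect_equal(nrow(cand), 0L)
})

test_that("a noiseless Gaussian spot yields one candidate at its pixel", {
  sl <- gaussian_patch(41, x0 = 17, y0 = 23, sigma = 1.2, amp = 50, bg = 10)
  st <- image_stack(array(sl, c(41, 41, 1)), 160, 300)
  cand <- detect_candidates(st)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$x, 17)
  expect_equal(cand$y, 23)
  expect_equal(cand$z, 0L)
})

test_that("stacks smaller than the filter support are rejected", {
  st <- image_stack(array(1, c(6, 6, 1)), 160, 300)
  expect_error(detect_candidates(st), "filter support")
})

test_that("radial symmetry is exact for a centered symmetric spot", {
  p <- gaussian_patch(9, 4, 4, sigma = 1.5)
  ctr <- localize_radial_symmetry(p)
  expect_lt(abs(ctr[["x"]] - 4), 1e-6)
  expect_lt(abs(ctr[["y"]] - 4), 1e-6)
})

test_that("radial symmetry recovers sub-pixel offsets and matches the
           grid-search minimizer of its own objective", {
  offsets <- rbind(c(0.3, -0.2), c(-0.45, 0.1), c(0.25, 0.35))
  for (i in seq_len(nrow(offsets))) {
    p <- gaussian_patch(9, 4 + offsets[i, 1], 4 + offsets[i, 2],
                        sigma = 1.2, amp = 100, bg = 5)
    ctr <- localize_radial_symmetry(p)
    expect_lt(abs(ctr[["x"]] - (4 + offsets[i, 1])), 0.05)
    expect_lt(abs(ctr[["y"]] - (4 + offsets[i, 2])), 0.05)
    bf <- grid_search_center(p, start = c(4, 4))
    expect_lt(abs(ctr[["x"]] - bf[1]), 1e-3)
    expect_lt(abs(ctr[["y"]] - bf[2]), 1e-3)
  }
})

test_that("localization is equivariant to integer translations", {
  big <- matrix(0, 25, 25)
  spot <- gaussian_patch(25, 10.4, 11.7, sigma = 1.2, amp = 80)
  for (shift in c(0, 3)) {
    sub <- spot[(4 + shift):(18 + shift), (3 + shift):(17 + shift)]
    ctr <- localize_radial_symmetry(sub)
    expect_lt(abs((ctr[["x"]] + 2 + shift) - 10.4), 0.02)
    expect_lt(abs((ctr[["y"]] + 3 + shift) - 11.7), 0.02)
  }
})

test_that("degenerate patches raise errors", {
  expect_error(localize_radial_symmetry(matrix(5, 9, 9)), "degenerate")
})

test_that("localization stays under 0.5 px RMS at peak S/N 5", {
  set.seed(123)
  amp <- 25; bg <- 0  # Poisson at peak: SD = 5 = amp / 5
  err2 <- replicate(500, {
    x0 <- 5 + runif(1, -0.5, 0.5); y0 <- 5 + runif(1, -0.5, 0.5)
    p <- gaussian_patch(11, x0, y0, sigma = 1.2, amp = amp, bg = bg)
    noisy <- matrix(rpois(length(p), p), nrow(p))
    ctr <- localize_radial_symmetry(noisy)
    (ctr[["x"]] - x0)^2 + (ctr[["y"]] - y0)^2
  })
  expect_lt(sqrt(mean(err2) / 2), 0.5)  # per-axis RMS
})

test_that("candidates in adjacent slices collapse into one spot", {
  st <- array(10, c(31, 31, 5))
  for (z in 2:4)
    st[, , z] <- gaussian_patch(31, 15, 15, sigma = 1.2,
                                amp = c(30, 60, 30)[z - 1], bg = 10)
  stk <- image_stack(st, 160, 300)
  spots <- link_across_slices(stk, detect_candidates(stk))
  expect_equal(nrow(spots), 1L)
  expect_equal(spots$n_slices_spanned, 3L)
  expect_equal(spots$z_slice, 2L)  # brightest slice (0-based)
})

test_that("well-separated emitters stay separate", {
  p <- detection_params()
  sep <- ceiling(3 * p$link_radius_xy) + 2
  sl <- gaussian_patch(41, 12, 20, sigma = 1.2, amp = 50, bg = 10) +
        gaussian_patch(41, 12 + sep, 20, sigma = 1.2, amp = 50, bg = 0)
  stk <- image_stack(array(sl, c(41, 41, 1)), 160, 300)
  spots <- link_across_slices(stk, detect_candidates(stk, p), p)
  expect_equal(nrow(spots), 2L)
})

test_that("aggregate classification follows the modal-intensity rule", {
  mk <- function(int) data.frame(x = seq_along(int), y = 1, z_slice = 0L,
                                 intensity = int, n_slices_spanned = 1L,
                                 aggregate_class = "single_or_few")
  p <- detection_params(aggregate_intensity_factor = 4,
                        min_spots_for_mode = 10)
  same <- classify_aggregates(mk(rep(7, 30)), p)
  expect_true(all(same$aggregate_class == "single_or_few"))

  int <- c(rnorm(40, 1, 0.05), 10)
  one <- classify_aggregates(mk(int), p)
  expect_equal(one$aggregate_class[41], "aggregate")
  expect_true(all(one$aggregate_class[1:40] == "single_or_few"))

  expect_warning(classify_aggregates(mk(c(1, 2, 3)), p), "modal intensity")
})

test_that("mixture of unit and 5x spots is classified accurately", {
  set.seed(5)
  n <- 400
  truth <- runif(n) < 0.1
  int <- ifelse(truth, rnorm(n, 5, 0.25), rnorm(n, 1, 0.1))
  spots <- data.frame(x = seq_len(n), y = 1, z_slice = 0L, intensity = int,
                      n_slices_spanned = 1L, aggregate_class = "")
  out <- classify_aggregates(spots, detection_params(
    aggregate_intensity_factor = 3))
  acc <- mean((out$aggregate_class == "aggregate") == truth)
  expect_gte(acc, 0.95)
})

test_that("per-cell counting conserves and assigns correctly", {
  labels <- matrix(0L, 40, 40)
  labels[5:15, 5:15] <- 1L
  labels[25:35, 25:35] <- 2L
  reg <- regions_from_labels(labels)
  none <- count_spots_per_cell(
    data.frame(x = numeric(0), y = numeric(0), z_slice = integer(0),
               intensity = numeric(0), n_slices_spanned = integer(0),
               aggregate_class = character(0)), reg)
  expect_true(all(none$counts$qd_count == 0))

  spots <- data.frame(x = c(6.2, 9.8, 12.1, 20, 30),
                      y = c(7.5, 10.3, 6.6, 20, 30),
                      z_slice = 0L, intensity = 5,
                      n_slices_spanned = 1L,
                      aggregate_class = "single_or_few")
  cc <- count_spots_per_cell(spots, reg)
  expect_equal(cc$counts$qd_count[cc$counts$cell == 1], 3L)
  expect_equal(cc$counts$qd_count[cc$counts$cell == 2], 1L)
  expect_equal(cc$n_orphans, 1L)
  expect_equal(sum(cc$counts$qd_count) + cc$n_orphans, nrow(spots))
})

test_that("an added emitter inside a cell increments its count by one", {
  spec0 <- scene_spec(field_shape = c(96, 96), n_slices = 8, n_cells = 1,
                      cell_radius_range = c(20, 20), fixed_counts = 3L,
                      autofluor_amplitude = 0, read_noise_sd = 0,
                      shot_noise = FALSE, baseline_offset = 10,
                      min_separation = 8, seed = 55)
  spec1 <- scene_spec(field_shape = c(96, 96), n_slices = 8, n_cells = 1,
                      cell_radius_range = c(20, 20), fixed_counts = 4L,
                      autofluor_amplitude = 0, read_noise_sd = 0,
                      shot_noise = FALSE, baseline_offset = 10,
                      min_separation = 8, seed = 55)
  count_of <- function(spec) {
    sc <- simulate_scene(spec)
    reg <- regions_from_labels(sc$truth$cell_masks)
    spots <- link_across_slices(sc$stack, detect_candidates(sc$stack))
    suppressWarnings(
      count_spots_per_cell(classify_aggregates(spots), reg))$counts$qd_count
  }
  expect_equal(count_of(spec1), count_of(spec0) + 1L)
})
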