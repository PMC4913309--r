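# Shared fixtures and independent oracles.

# Noiseless 2D Gaussian spot on a constant background, pixel centers at
# integer (x, y); patch[row, col] with x = col - 1, y = row - 1.
gaussian_patch <- function(size, x0, y0, sigma = 1.2, amp = 1, bg = 0) {
  outer(0:(size - 1), 0:(size - 1),
        function(y, x) bg + amp * exp(-((x - x0)^2 + (y - y0)^2) /
                                        (2 * sigma^2)))
}

# Brute-force double-sum index of insensitivity (the defining formula).
bf_index <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y)
    s <- s + (xi < yj) + 0.5 * (xi == yj)
  s / (length(x) * length(y))
}

# Brute-force grid minimizer of the radial-symmetry weighted line-distance
# objective (three zoom rounds, final resolution 1e-4 px). Shares the
# gradient-line construction with the implementation; minimization is
# independent of the closed-form solve it checks.
grid_search_center <- function(patch, start) {
  ln <- qdcount:::radial_symmetry_lines(patch)
  obj <- function(xc, yc)
    sum(ln$w * (yc - ln$m * xc - ln$b)^2 / (ln$m^2 + 1))
  ctr <- start
  span <- 0.7
  for (round in 1:4) {
    gx <- seq(ctr[1] - span, ctr[1] + span, length.out = 29)
    gy <- seq(ctr[2] - span, ctr[2] + span, length.out = 29)
    vals <- outer(gx, gy, Vectorize(obj))
    best <- arrayInd(which.min(vals), dim(vals))
    ctr <- c(gx[best[1]], gy[best[2]])
    span <- span / 10
  }
  ctr
}

# Small quick scene used by several suites.
quick_scene <- function(seed = 5, n_cells = 3, mean_spots = 10,
                        autofluor = 15, noise = TRUE) {
  simulate_scene(scene_spec(
    field_shape = c(128L, 128L), n_slices = 10L, n_cells = n_cells,
    cell_radius_range = c(12, 15), mean_spots_per_cell = mean_spots,
    autofluor_amplitude = autofluor, shot_noise = noise,
    read_noise_sd = if (noise) 3 else 0, seed = seed))
}
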