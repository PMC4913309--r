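#' Specify a synthetic imaging scene
#'
#' Builds a validated specification for [simulate_scene()]. Defaults emulate
#' a typical acquisition: ~160 nm pixels, 300 nm inter-slice spacing, 60
#' slices (18 um total depth), diffraction-limited point-spread function,
#' per-cell diffuse autofluorescence, Poisson shot noise, Gaussian read
#' noise and 16-bit quantization. Per-cell true spot counts are negative
#' binomial unless `fixed_counts` pins them.
#'
#' @param field_shape integer pair `(ny, nx)`, field size in pixels.
#' @param n_slices number of z slices.
#' @param slice_spacing inter-slice distance, nm.
#' @param pixel_size lateral pixel size, nm.
#' @param n_cells number of (non-overlapping, circular) cells to place.
#' @param cell_radius_range pixel radius range `(min, max)`; radii drawn
#'   uniformly.
#' @param mean_spots_per_cell mean of the negative-binomial true count.
#' @param spot_dispersion negative-binomial size (dispersion) parameter.
#' @param fixed_counts optional integer vector of length `n_cells` that
#'   overrides the count model (handy for controlled tests).
#' @param psf_sigma_xy lateral Gaussian PSF sigma, pixels.
#' @param psf_sigma_z axial Gaussian PSF sigma, slices.
#' @param spot_peak_photons expected photons at an emitter's central voxel.
#' @param autofluor_amplitude mean diffuse autofluorescence, photons per
#'   pixel per slice inside a cell footprint (0 disables).
#' @param autofluor_smoothness Gaussian correlation scale of the diffuse
#'   field, pixels.
#' @param read_noise_sd Gaussian read noise SD, camera counts.
#' @param baseline_offset camera baseline added after shot noise, counts.
#' @param bit_depth quantization depth; intensities clip to `2^bit_depth - 1`.
#' @param shot_noise logical; apply Poisson noise to expected photons.
#' @param min_separation minimum emitter-emitter 3D distance in pixels/slices
#'   (0 = unconstrained uniform placement).
#' @param seed master seed; every randomness source derives from it, with
#'   one sub-stream per cell so adding a cell does not perturb earlier ones.
#' @return An object of class `scene_spec` (a validated list).
#' @seealso [simulate_scene()]
#' @export
scene_spec <- function(field_shape = c(512L, 512L),
                       n_slices = 60L,
                       slice_spacing = 300,
                       pixel_size = 160,
                       n_cells = 20L,
                       cell_radius_range = c(24, 32),
                       mean_spots_per_cell = 100,
                       spot_dispersion = 5,
                       fixed_counts = NULL,
                       psf_sigma_xy = 1.1,
                       psf_sigma_z = 1.2,
                       spot_peak_photons = 50,
                       autofluor_amplitude = 15,
                       autofluor_smoothness = 40,
                       read_noise_sd = 3,
                       baseline_offset = 100,
                       bit_depth = 16L,
                       shot_noise = TRUE,
                       min_separation = 0,
                       seed = 1L) {
  spec <- list(
    field_shape = as.integer(field_shape), n_slices = as.integer(n_slices),
    slice_spacing = slice_spacing, pixel_size = pixel_size,
    n_cells = as.integer(n_cells), cell_radius_range = cell_radius_range,
    mean_spots_per_cell = mean_spots_per_cell,
    spot_dispersion = spot_dispersion, fixed_counts = fixed_counts,
    psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
    spot_peak_photons = spot_peak_photons,
    autofluor_amplitude = autofluor_amplitude,
    autofluor_smoothness = autofluor_smoothness,
    read_noise_sd = read_noise_sd, baseline_offset = baseline_offset,
    bit_depth = as.integer(bit_depth), shot_noise = isTRUE(shot_noise),
    min_separation = min_separation, seed = as.integer(seed))
  validate_scene_spec(spec)
  class(spec) <- "scene_spec"
  spec
}

validate_scene_spec <- function(spec) {
  if (length(spec$field_shape) != 2L || any(spec$field_shape < 8L))
    stop("'field_shape' must be two pixel dimensions (ny, nx), each >= 8",
         call. = FALSE)
  stopifnot_scalar(spec$n_slices, "n_slices", positive = TRUE, integerish = TRUE)
  stopifnot_scalar(spec$slice_spacing, "slice_spacing", positive = TRUE)
  stopifnot_scalar(spec$pixel_size, "pixel_size", positive = TRUE)
  if (spec$n_cells < 0L) stop("'n_cells' must be >= 0", call. = FALSE)
  if (length(spec$cell_radius_range) != 2L ||
      spec$cell_radius_range[1] <= 0 ||
      spec$cell_radius_range[1] > spec$cell_radius_range[2])
    stop("'cell_radius_range' must be (min, max) with 0 < min <= max",
         call. = FALSE)
  stopifnot_scalar(spec$psf_sigma_xy, "psf_sigma_xy", positive = TRUE)
  stopifnot_scalar(spec$psf_sigma_z, "psf_sigma_z", positive = TRUE)
  stopifnot_scalar(spec$spot_peak_photons, "spot_peak_photons", positive = TRUE)
  if (spec$autofluor_amplitude < 0)
    stop("'autofluor_amplitude' must be >= 0", call. = FALSE)
  if (spec$read_noise_sd < 0) stop("'read_noise_sd' must be >= 0", call. = FALSE)
  if (spec$baseline_offset < 0) stop("'baseline_offset' must be >= 0", call. = FALSE)
  if (!spec$bit_depth %in% c(8L, 12L, 14L, 16L))
    stop("'bit_depth' must be one of 8, 12, 14, 16", call. = FALSE)
  if (!is.null(spec$fixed_counts)) {
    if (length(spec$fixed_counts) != spec$n_cells ||
        any(spec$fixed_counts < 0) || any(spec$fixed_counts != round(spec$fixed_counts)))
      stop("'fixed_counts' must be n_cells non-negative integers", call. = FALSE)
  } else {
    stopifnot_scalar(spec$mean_spots_per_cell, "mean_spots_per_cell", positive = TRUE)
    stopifnot_scalar(spec$spot_dispersion, "spot_dispersion", positive = TRUE)
  }
  if (spec$min_separation < 0) stop("'min_separation' must be >= 0", call. = FALSE)
  invisible(spec)
}

# Rejection-sample non-overlapping circular cells. Each cell consumes only
# its own RNG sub-stream, so cell i's geometry is invariant to n_cells > i.
place_cells <- function(spec) {
  ny <- spec$field_shape[1]; nx <- spec$field_shape[2]
  rmin <- spec$cell_radius_range[1]; rmax <- spec$cell_radius_range[2]
  out <- data.frame(cell = integer(0), cx = numeric(0), cy = numeric(0),
                    radius = numeric(0))
  margin <- 2  # keep footprints strictly inside the field
  for (i in seq_len(spec$n_cells)) {
    placed <- with_seed(derive_seed(spec$seed, i), {
      r <- runif(1, rmin, rmax)
      if (nx - 1 - r - margin < r + margin || ny - 1 - r - margin < r + margin)
        stop("cell radius too large for field: cells must fit fully inside ",
             "the field with a 2 px margin", call. = FALSE)
      ok <- FALSE
      for (attempt in seq_len(2000L)) {
        cx <- runif(1, r + margin, nx - 1 - r - margin)
        cy <- runif(1, r + margin, ny - 1 - r - margin)
        # 6 px clearance: footprints must not merge after the ~2 px
        # autofluorescence edge softening; the assay counts isolated cells
        if (nrow(out) == 0L ||
            all(sqrt((out$cx - cx)^2 + (out$cy - cy)^2) > out$radius + r + 6)) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf(paste0(
          "failed to place cell %d after 2000 attempts: the field is too ",
          "crowded for %d non-overlapping cells of radius %.0f-%.0f px"),
          i, spec$n_cells, rmin, rmax), call. = FALSE)
      list(cx = cx, cy = cy, r = r)
    })
    out <- rbind(out, data.frame(cell = i, cx = placed$cx, cy = placed$cy,
                                 radius = placed$r))
  }
  out
}

# Labeled mask from circular footprints; pixel centers at integer (x, y).
cells_to_label_map <- function(cells, ny, nx) {
  labels <- matrix(0L, ny, nx)
  x <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  y <- matrix(rep(0:(ny - 1), nx), ny, nx)
  for (i in seq_len(nrow(cells))) {
    inside <- (x - cells$cx[i])^2 + (y - cells$cy[i])^2 <= cells$radius[i]^2
    labels[inside] <- cells$cell[i]
  }
  labels
}

# Support and values of one emitter's separable 3D Gaussian (peak `amp`
# photons), truncated at ~4 sigma laterally and ~3.5 sigma axially.
# Returned as 0-based index vectors plus per-slice lateral patches; the
# caller adds them into the expected-photon array in place (passing the
# full array through a function would copy it per emitter).
emitter_psf_patch <- function(x0, y0, z0, amp, sxy, sz, ny, nx, nz) {
  hx <- ceiling(4 * sxy); hz <- ceiling(3.5 * sz)
  cols <- max(0, floor(x0) - hx):min(nx - 1, ceiling(x0) + hx)
  rows <- max(0, floor(y0) - hx):min(ny - 1, ceiling(y0) + hx)
  zs   <- max(0, floor(z0) - hz):min(nz - 1, ceiling(z0) + hz)
  gx <- exp(-(cols - x0)^2 / (2 * sxy^2))
  gy <- exp(-(rows - y0)^2 / (2 * sxy^2))
  gz <- exp(-(zs - z0)^2 / (2 * sz^2))
  list(rows = rows, cols = cols, zs = zs,
       patch = amp * outer(gy, gx), gz = gz)
}

# Smooth unit-mean positive field for diffuse autofluorescence: Gaussian-
# filtered white noise, standardized, squashed through pnorm into
# [0.7, 1.3] so the field stays positive and has mean ~1.
smooth_unit_field <- function(ny, nx, scale, seed) {
  g <- with_seed(seed, matrix(rnorm(ny * nx), ny, nx))
  radius <- min(2L * ceiling(3 * scale) + 1L,
                2L * ((min(ny, nx) - 1L) %/% 2L) + 1L)
  g <- as.matrix(EBImage::gblur(EBImage::Image(g), sigma = scale,
                                radius = radius))
  g <- (g - mean(g)) / stats::sd(g)
  0.7 + 0.6 * stats::pnorm(g)
}

#' Simulate a ground-truth-annotated fluorescence z-stack
#'
#' Generates one field of view: non-overlapping circular cells, per-cell
#' discrete emitters placed uniformly inside each footprint at random depth,
#' each rendered as a separable 3D Gaussian PSF; a smooth diffuse
#' autofluorescence field inside each footprint on every slice; Poisson shot
#' noise on expected photons; Gaussian read noise and a camera baseline; and
#' quantization to the configured bit depth. Identical spec (including seed)
#' gives a bit-identical stack.
#'
#' @param spec a [scene_spec()].
#' @return A list with components
#'   \describe{
#'     \item{stack}{an [image_stack()] of quantized intensities,}
#'     \item{truth}{a `ground_truth` list: `cells` (cell, cx, cy, radius,
#'       true_count, autofluor_factor, autofluor_integral), `emitters`
#'       (cell, x, y, z; sub-pixel/sub-slice), and `cell_masks`
#'       (labeled ny x nx matrix).}
#'   }
#' @examples
#' sc <- simulate_scene(scene_spec(field_shape = c(96, 96), n_slices = 8,
#'                                 n_cells = 2, cell_radius_range = c(10, 12),
#'                                 mean_spots_per_cell = 5, seed = 7))
#' dim(sc$stack$voxels)
#' sc$truth$cells$true_count
#' @export
simulate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  validate_scene_spec(spec)
  ny <- spec$field_shape[1]; nx <- spec$field_shape[2]; nz <- spec$n_slices
  cells <- place_cells(spec)
  labels <- cells_to_label_map(cells, ny, nx)
  E <- array(0, dim = c(ny, nx, nz))

  emitters <- vector("list", spec$n_cells)
  af_factor <- numeric(spec$n_cells)
  counts <- integer(spec$n_cells)
  for (i in seq_len(spec$n_cells)) {
    drawn <- with_seed(derive_seed(spec$seed, 100000L + i), {
      cnt <- if (!is.null(spec$fixed_counts)) spec$fixed_counts[i] else
        rnbinom(1, size = spec$spot_dispersion, mu = spec$mean_spots_per_cell)
      fac <- runif(1, 0.7, 1.3)
      pos <- matrix(numeric(0), ncol = 3)
      if (cnt > 0) {
        # uniform over the cell's pixelated footprint (pixel + sub-pixel
        # jitter), so every emitter provably lies inside the mask
        idx <- which(labels == i)
        px0 <- (idx - 1L) %/% ny  # 0-based x
        py0 <- (idx - 1L) %% ny   # 0-based y
        xs <- numeric(cnt); ys <- numeric(cnt); zs <- numeric(cnt)
        for (e in seq_len(cnt)) {
          for (attempt in seq_len(5000L)) {
            j <- sample.int(length(idx), 1)
            ex <- px0[j] + runif(1, -0.499, 0.499)
            ey <- py0[j] + runif(1, -0.499, 0.499)
            ez <- runif(1, 0, nz - 1)
            if (spec$min_separation <= 0 || e == 1L ||
                all(sqrt((xs[seq_len(e - 1)] - ex)^2 +
                         (ys[seq_len(e - 1)] - ey)^2 +
                         (zs[seq_len(e - 1)] - ez)^2) >= spec$min_separation))
              break
            if (attempt == 5000L)
              stop("could not satisfy 'min_separation' emitter placement",
                   call. = FALSE)
          }
          xs[e] <- ex; ys[e] <- ey; zs[e] <- ez
        }
        pos <- cbind(xs, ys, zs)
      }
      list(cnt = cnt, fac = fac, pos = pos)
    })
    counts[i] <- drawn$cnt
    af_factor[i] <- drawn$fac
    emitters[[i]] <- if (drawn$cnt > 0)
      data.frame(cell = i, x = drawn$pos[, 1], y = drawn$pos[, 2],
                 z = drawn$pos[, 3])
    else
      data.frame(cell = integer(0), x = numeric(0), y = numeric(0),
                 z = numeric(0))
  }
  emitters <- do.call(rbind, c(emitters,
    list(data.frame(cell = integer(0), x = numeric(0), y = numeric(0),
                    z = numeric(0)))))
  rownames(emitters) <- NULL

  for (e in seq_len(nrow(emitters))) {
    p <- emitter_psf_patch(emitters$x[e], emitters$y[e], emitters$z[e],
                           spec$spot_peak_photons, spec$psf_sigma_xy,
                           spec$psf_sigma_z, ny, nx, nz)
    for (k in seq_along(p$zs))
      E[p$rows + 1, p$cols + 1, p$zs[k] + 1] <-
        E[p$rows + 1, p$cols + 1, p$zs[k] + 1] + p$patch * p$gz[k]
  }

  af_integral <- numeric(spec$n_cells)
  if (spec$autofluor_amplitude > 0 && spec$n_cells > 0) {
    field <- smooth_unit_field(ny, nx, spec$autofluor_smoothness,
                               derive_seed(spec$seed, 900001L))
    af2d <- matrix(0, ny, nx)
    for (i in seq_len(spec$n_cells)) {
      m <- labels == i
      af2d[m] <- spec$autofluor_amplitude * af_factor[i] * field[m]
    }
    # soften the footprint edge (~2 px): cellular autofluorescence has no
    # hard step at the membrane
    af2d <- as.matrix(EBImage::gblur(EBImage::Image(af2d), sigma = 2,
                                     radius = min(13L, 2L * ((min(ny, nx) - 1L) %/% 2L) + 1L)))
    for (i in seq_len(spec$n_cells))
      af_integral[i] <- sum(af2d[labels == i]) * nz
    E <- E + as.vector(af2d)  # recycles the 2D field across slices
  }

  E[E < 0] <- 0  # guard against filter ringing in the autofluorescence field
  img <- with_seed(derive_seed(spec$seed, 900002L), {
    v <- if (spec$shot_noise) rpois(length(E), lambda = E) else as.vector(E)
    v <- v + spec$baseline_offset
    if (spec$read_noise_sd > 0) v <- v + rnorm(length(v), 0, spec$read_noise_sd)
    v
  })
  img <- round(img)
  img[img < 0] <- 0
  vmax <- 2^spec$bit_depth - 1
  img[img > vmax] <- vmax
  stack <- image_stack(array(img, dim = c(ny, nx, nz)),
                       pixel_size = spec$pixel_size,
                       slice_spacing = spec$slice_spacing,
                       channel_label = "QD")

  cells$true_count <- counts
  cells$autofluor_factor <- af_factor
  cells$autofluor_integral <- af_integral
  truth <- structure(list(cells = cells, emitters = emitters,
                          cell_masks = labels),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic scene spec: %d x %d px, %d slices (%.0f nm spacing, ",
    "%.0f nm pixels)\n  %d cells (radius %.0f-%.0f px), PSF sigma %.2f px ",
    "/ %.2f slices\n  peak %.0f photons, autofluorescence %.1f ph/px/slice, ",
    "read noise %.1f, baseline %.0f, %d-bit, seed %d\n"),
    x$field_shape[1], x$field_shape[2], x$n_slices, x$slice_spacing,
    x$pixel_size, x$n_cells, x$cell_radius_range[1], x$cell_radius_range[2],
    x$psf_sigma_xy, x$psf_sigma_z, x$spot_peak_photons,
    x$autofluor_amplitude, x$read_noise_sd, x$baseline_offset, x$bit_depth,
    x$seed))
  invisible(x)
}
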