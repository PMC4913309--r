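# Discrete spot detection, sub-pixel localization, slice linking,
# aggregate discrimination and per-cell counting.

#' Detection parameter set
#'
#' All tunables of the digitized counting stage in one validated object.
#'
#' @param dog_sigma_small,dog_sigma_large band-pass (difference of
#'   Gaussians) scales, pixels; small < large.
#' @param candidate_threshold_k candidate threshold in robust SDs
#'   (median + k * 1.4826 * MAD) of each slice's filtered image.
#' @param candidate_floor absolute lower bound (camera counts) on the
#'   threshold's offset above the median; on (near-)noiseless quantized
#'   data the MAD collapses to 0 and sub-quantization filter ripple would
#'   otherwise count as candidates.
#' @param link_radius_xy lateral radius (pixels) within which candidates in
#'   neighboring slices are considered the same emitter.
#' @param link_max_gap maximum number of consecutive missing slices a chain
#'   may bridge.
#' @param patch_halfwidth half-width `h` of the `(2h+1) x (2h+1)`
#'   localization patch, pixels (>= 2).
#' @param aggregate_intensity_factor spots brighter than this multiple of
#'   the modal single-spot intensity are classed `aggregate`.
#' @param min_spots_for_mode minimum spot population needed to estimate the
#'   modal intensity; below it, all spots are classed `single_or_few` with
#'   a warning.
#' @param count_aggregates `"exclude"` (default: aggregates never counted)
#'   or `"one"` (each aggregate counts as one complex).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(dog_sigma_small = 1.0, dog_sigma_large = 2.5,
                             candidate_threshold_k = 8.5,
                             candidate_floor = 1,
                             link_radius_xy = 1.5, link_max_gap = 1L,
                             patch_halfwidth = 3L,
                             aggregate_intensity_factor = 3,
                             min_spots_for_mode = 20L,
                             count_aggregates = c("exclude", "one")) {
  p <- list(dog_sigma_small = dog_sigma_small,
            dog_sigma_large = dog_sigma_large,
            candidate_threshold_k = candidate_threshold_k,
            candidate_floor = candidate_floor,
            link_radius_xy = link_radius_xy,
            link_max_gap = as.integer(link_max_gap),
            patch_halfwidth = as.integer(patch_halfwidth),
            aggregate_intensity_factor = aggregate_intensity_factor,
            min_spots_for_mode = as.integer(min_spots_for_mode),
            count_aggregates = match.arg(count_aggregates))
  if (p$dog_sigma_small <= 0 || p$dog_sigma_large <= p$dog_sigma_small)
    stop("need 0 < dog_sigma_small < dog_sigma_large", call. = FALSE)
  if (p$link_radius_xy <= 0) stop("'link_radius_xy' must be > 0", call. = FALSE)
  if (p$link_max_gap < 0) stop("'link_max_gap' must be >= 0", call. = FALSE)
  if (p$patch_halfwidth < 2L) stop("'patch_halfwidth' must be >= 2", call. = FALSE)
  if (p$candidate_threshold_k <= 0)
    stop("'candidate_threshold_k' must be > 0", call. = FALSE)
  if (p$candidate_floor < 0)
    stop("'candidate_floor' must be >= 0", call. = FALSE)
  if (p$aggregate_intensity_factor <= 1)
    stop("'aggregate_intensity_factor' must be > 1", call. = FALSE)
  class(p) <- "detection_params"
  p
}

#' Detect per-slice spot candidates
#'
#' Each slice is band-pass filtered with a difference of Gaussians; strict
#' local maxima over the in-slice 3x3 neighborhood whose filtered value
#' exceeds `median + k * 1.4826 * MAD` of that slice's filtered image
#' become candidates. The robust (median/MAD) threshold is insensitive to
#' the bright tail the spots themselves induce.
#'
#' @param stack an [image_stack()].
#' @param params a [detection_params()].
#' @return Data frame `x`, `y` (integer, 0-based), `z` (0-based slice),
#'   `filtered_value`.
#' @export
detect_candidates <- function(stack, params = detection_params()) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(params, "detection_params"))
  d <- dim(stack$voxels)
  support <- 2 * ceiling(2 * params$dog_sigma_large) + 1
  if (d[1] < support || d[2] < support)
    stop(sprintf("stack (%d x %d px) smaller than filter support (%d px)",
                 d[1], d[2], support), call. = FALSE)
  out <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    sl <- stack$voxels[, , k]
    f <- as.matrix(EBImage::gblur(EBImage::Image(sl),
                                  sigma = params$dog_sigma_small)) -
         as.matrix(EBImage::gblur(EBImage::Image(sl),
                                  sigma = params$dog_sigma_large))
    thr <- median(f) + max(params$candidate_threshold_k * mad(f),
                           params$candidate_floor)
    out[[k]] <- local_maxima(f, thr, k - 1L)
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L)
    return(data.frame(x = integer(0), y = integer(0), z = integer(0),
                      filtered_value = numeric(0)))
  rownames(res) <- NULL
  res
}

# Strict 3x3 local maxima above thr; border pixels excluded.
local_maxima <- function(f, thr, z0) {
  ny <- nrow(f); nx <- ncol(f)
  core <- f[2:(ny - 1), 2:(nx - 1)]
  is_max <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- f[(2 + dy):(ny - 1 + dy), (2 + dx):(nx - 1 + dx)]
    is_max <- is_max & (core > nb)
  }
  idx <- which(is_max)
  if (!length(idx))
    return(data.frame(x = integer(0), y = integer(0), z = integer(0),
                      filtered_value = numeric(0)))
  r <- (idx - 1L) %% (ny - 2L) + 1L   # 0-based y in full image
  c <- (idx - 1L) %/% (ny - 2L) + 1L  # 0-based x in full image
  data.frame(x = c, y = r, z = z0, filtered_value = core[idx])
}

# Gradient lines of the radial-symmetry localizer for one patch: for each
# 2x2 pixel block, the intensity gradient at the block midpoint (from the
# two diagonal differences, 3x3 mean-smoothed) defines a line through the
# midpoint along the gradient direction. Returns slopes m, intercepts b
# and weights w (squared gradient magnitude / distance to the
# gradient-magnitude centroid), plus the midpoint grid.
radial_symmetry_lines <- function(patch) {
  ny <- nrow(patch); nx <- ncol(patch)
  if (ny < 3 || nx < 3) stop("patch too small for localization", call. = FALSE)
  # midpoint coordinates (0-based pixel frame)
  xm <- matrix(rep(seq_len(nx - 1) - 0.5, each = ny - 1), ny - 1, nx - 1)
  ym <- matrix(rep(seq_len(ny - 1) - 0.5, nx - 1), ny - 1, nx - 1)
  dIdu <- patch[1:(ny - 1), 2:nx] - patch[2:ny, 1:(nx - 1)]
  dIdv <- patch[1:(ny - 1), 1:(nx - 1)] - patch[2:ny, 2:nx]
  fdu <- mean_filter3(dIdu)
  fdv <- mean_filter3(dIdv)
  mag2 <- fdu^2 + fdv^2
  if (sum(mag2) <= 0)
    stop("degenerate patch: no intensity gradients", call. = FALSE)
  m <- -(fdv + fdu) / (fdu - fdv)
  # 0/0 -> no direction: zero weight; x/0 -> vertical line: huge slope
  bad <- !is.finite(m)
  vertical <- bad & (abs(fdv + fdu) > 0)
  m[bad] <- 0
  m[vertical] <- 1e12
  w0 <- mag2
  w0[bad & !vertical] <- 0
  b <- ym - m * xm
  xc0 <- sum(mag2 * xm) / sum(mag2)
  yc0 <- sum(mag2 * ym) / sum(mag2)
  dist <- sqrt((xm - xc0)^2 + (ym - yc0)^2)
  w <- w0 / pmax(dist, 1e-6)
  list(m = as.vector(m), b = as.vector(b), w = as.vector(w))
}

# 3x3 mean filter, zero-padded borders (matches a 'same' convolution).
mean_filter3 <- function(a) {
  ny <- nrow(a); nx <- ncol(a)
  p <- matrix(0, ny + 2, nx + 2)
  p[2:(ny + 1), 2:(nx + 1)] <- a
  out <- matrix(0, ny, nx)
  for (dy in 0:2) for (dx in 0:2)
    out <- out + p[(1 + dy):(ny + dy), (1 + dx):(nx + dx)]
  out / 9
}

#' Sub-pixel spot localization by radial symmetry
#'
#' Gradient-based radial-symmetry center finding: intensity gradients are
#' computed at the midpoints of 2x2 pixel blocks from the two diagonal
#' differences (3x3 mean-smoothed); each gradient defines a line through
#' its midpoint along the gradient direction; the center is the
#' least-squares point minimizing the weighted sum of squared
#' point-to-line distances, with weights proportional to the squared
#' gradient magnitude divided by the midpoint's distance to the
#' gradient-magnitude centroid. For a radially symmetric spot all lines
#' pass through the true center, so the estimate is exact in the noiseless
#' limit and needs no PSF model or iteration.
#'
#' @param patch square numeric matrix (typically `(2h+1) x (2h+1)` around a
#'   candidate).
#' @return `c(x, y)`: the center in the patch's 0-based pixel frame (the
#'   central pixel of a `(2h+1)`-patch is at `(h, h)`).
#' @examples
#' g <- outer(0:8, 0:8, function(y, x) exp(-((x - 4.3)^2 + (y - 3.8)^2) / 4))
#' localize_radial_symmetry(g)
#' @export
localize_radial_symmetry <- function(patch) {
  stopifnot(is.matrix(patch))
  ln <- radial_symmetry_lines(patch)
  wm2p1 <- ln$w / (ln$m^2 + 1)
  sw <- sum(wm2p1)
  smmw <- sum(ln$m^2 * wm2p1)
  smw <- sum(ln$m * wm2p1)
  smbw <- sum(ln$m * ln$b * wm2p1)
  sbw <- sum(ln$b * wm2p1)
  det <- smw * smw - smmw * sw
  if (!is.finite(det) || abs(det) < 1e-300)
    stop("singular normal equations in radial-symmetry fit", call. = FALSE)
  xc <- (smbw * sw - smw * sbw) / det
  yc <- (smbw * smw - smmw * sbw) / det
  c(x = xc, y = yc)
}

#' Link per-slice candidates into 3D spot detections
#'
#' One emitter's PSF spans several consecutive slices, so its candidates
#' must be collapsed into a single detection. Greedy linking by descending
#' filtered intensity (ties broken by `(z, y, x)`): the brightest unused
#' candidate seeds a spot and absorbs unused candidates in neighboring
#' slices within `link_radius_xy` laterally, walking contiguously up and
#' down in z and bridging at most `link_max_gap` missing slices. The spot's
#' sub-pixel `(x, y)` is the radial-symmetry localization at its brightest
#' slice; `z_slice` is that slice.
#'
#' @param stack the [image_stack()] the candidates came from (for
#'   localization patches).
#' @param candidates data frame from [detect_candidates()].
#' @param params a [detection_params()].
#' @return Data frame of spot detections: `x`, `y` (sub-pixel, 0-based),
#'   `z_slice`, `intensity` (band-pass peak amplitude, background-corrected
#'   by construction), `n_slices_spanned`, `aggregate_class` (filled by
#'   [classify_aggregates()], initialized to `"single_or_few"`).
#' @export
link_across_slices <- function(stack, candidates,
                               params = detection_params()) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(params, "detection_params"))
  n <- nrow(candidates)
  empty <- data.frame(x = numeric(0), y = numeric(0), z_slice = integer(0),
                      intensity = numeric(0), n_slices_spanned = integer(0),
                      aggregate_class = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  ord <- order(-candidates$filtered_value, candidates$z, candidates$y,
               candidates$x)
  cand <- candidates[ord, ]
  used <- rep(FALSE, n)
  # per-slice spatial hash for radius queries
  r <- params$link_radius_xy
  nz <- dim(stack$voxels)[3]
  by_slice <- split(seq_len(n), factor(cand$z, levels = 0:(nz - 1)))
  key <- function(i) paste(floor(cand$x[i] / r), floor(cand$y[i] / r))
  grids <- lapply(by_slice, function(idx) split(idx, vapply(idx, key, "")))
  query <- function(z, x0, y0) {
    g <- grids[[z + 1L]]
    if (is.null(g) || !length(g)) return(integer(0))
    kx <- floor(x0 / r); ky <- floor(y0 / r)
    hits <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      cell <- g[[paste(kx + dx, ky + dy)]]
      if (!is.null(cell)) hits <- c(hits, cell)
    }
    hits <- hits[!used[hits]]
    hits[(cand$x[hits] - x0)^2 + (cand$y[hits] - y0)^2 <= r^2]
  }
  spots <- vector("list", n)
  nspots <- 0L
  h <- params$patch_halfwidth
  d <- dim(stack$voxels)
  for (i in seq_len(n)) {
    if (used[i]) next
    used[i] <- TRUE
    members <- i
    x0 <- cand$x[i]; y0 <- cand$y[i]; z0 <- cand$z[i]
    for (direction in c(-1L, 1L)) {
      zc <- z0
      repeat {
        found <- FALSE
        for (gap in 0:params$link_max_gap) {
          znext <- zc + direction * (1L + gap)
          if (znext < 0L || znext > nz - 1L) break
          hits <- query(znext, x0, y0)
          if (length(hits)) {
            # nearest within radius
            dd <- (cand$x[hits] - x0)^2 + (cand$y[hits] - y0)^2
            take <- hits[which.min(dd)]
            used[take] <- TRUE
            members <- c(members, take)
            zc <- znext
            found <- TRUE
            break
          }
        }
        if (!found) break
      }
    }
    # sub-pixel localization at the brightest member's slice
    xi <- cand$x[i]; yi <- cand$y[i]
    xs <- xi; ys <- yi
    if (xi - h >= 0 && xi + h <= d[2] - 1 && yi - h >= 0 && yi + h <= d[1] - 1) {
      patch <- stack$voxels[(yi - h):(yi + h) + 1, (xi - h):(xi + h) + 1,
                            z0 + 1]
      loc <- tryCatch(localize_radial_symmetry(patch), error = function(e) NULL)
      if (!is.null(loc) && all(abs(loc - h) <= h)) {
        xs <- xi - h + loc[["x"]]
        ys <- yi - h + loc[["y"]]
      }
    }
    nspots <- nspots + 1L
    spots[[nspots]] <- data.frame(
      x = xs, y = ys, z_slice = z0, intensity = cand$filtered_value[i],
      n_slices_spanned = length(unique(cand$z[members])),
      aggregate_class = "single_or_few", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, spots[seq_len(nspots)])
  rownames(out) <- NULL
  out
}

#' Classify spots as single complexes or aggregates
#'
#' The modal spot intensity (kernel density peak) estimates the brightness
#' of a single (or few-QD) complex; spots brighter than
#' `aggregate_intensity_factor` times the mode are classed `aggregate`.
#'
#' @param spots data frame from [link_across_slices()].
#' @param params a [detection_params()].
#' @return `spots` with `aggregate_class` filled, and the estimated modal
#'   intensity in attribute `"modal_intensity"`.
#' @export
classify_aggregates <- function(spots, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  if (nrow(spots) == 0L) return(spots)
  if (nrow(spots) < params$min_spots_for_mode) {
    warning(sprintf(
      "only %d spots (< %d needed to estimate the modal intensity); ",
      nrow(spots), params$min_spots_for_mode),
      "all spots classed single_or_few", call. = FALSE)
    spots$aggregate_class <- "single_or_few"
    return(spots)
  }
  if (stats::sd(spots$intensity) == 0) {
    spots$aggregate_class <- "single_or_few"
    attr(spots, "modal_intensity") <- spots$intensity[1]
    return(spots)
  }
  den <- density(spots$intensity)
  mode_int <- den$x[which.max(den$y)]
  spots$aggregate_class <- ifelse(
    spots$intensity > params$aggregate_intensity_factor * mode_int,
    "aggregate", "single_or_few")
  attr(spots, "modal_intensity") <- mode_int
  spots
}

#' Assign spots to cells and count per cell
#'
#' A spot belongs to the retained region whose footprint contains the pixel
#' holding its sub-pixel `(x, y)` (nearest-pixel rule). Spots outside all
#' retained regions are orphans (never counted); aggregates are excluded
#' from counts by default, or counted as one when
#' `params$count_aggregates == "one"`.
#'
#' @param spots data frame from [link_across_slices()] /
#'   [classify_aggregates()].
#' @param regions a `cell_regions` object ([segment_cells()] or
#'   [regions_from_labels()]).
#' @param params a [detection_params()].
#' @return A list: `counts` (data frame `cell`, `qd_count`, one row per
#'   retained region), `n_orphans`, `n_aggregates_excluded`, and `spots`
#'   with an `assigned_cell` column (0 = orphan).
#' @export
count_spots_per_cell <- function(spots, regions,
                                 params = detection_params()) {
  stopifnot(inherits(regions, "cell_regions"),
            inherits(params, "detection_params"))
  labels <- regions$labels
  retained <- regions$regions$cell[regions$regions$retained]
  # retained footprints must be disjoint: label map areas must match
  areas <- tabulate(labels[labels > 0L], max(c(labels, 1L)))
  stated <- regions$regions$area[regions$regions$retained]
  if (length(retained) &&
      !all(areas[retained] == stated))
    stop("retained regions are inconsistent/overlapping upstream",
         call. = FALSE)
  ny <- nrow(labels); nx <- ncol(labels)
  if (nrow(spots)) {
    px <- pmin(pmax(round(spots$x), 0), nx - 1)
    py <- pmin(pmax(round(spots$y), 0), ny - 1)
    spots$assigned_cell <- labels[cbind(py + 1, px + 1)]
  } else {
    spots$assigned_cell <- integer(0)
  }
  countable <- if (params$count_aggregates == "exclude")
    spots$aggregate_class != "aggregate" else rep(TRUE, nrow(spots))
  n_agg_excl <- sum(!countable)
  counted <- spots[countable, , drop = FALSE]
  counts <- data.frame(cell = retained,
                       qd_count = vapply(retained, function(i)
                         sum(counted$assigned_cell == i), 0L))
  list(counts = counts,
       n_orphans = sum(counted$assigned_cell == 0L |
                       !(counted$assigned_cell %in% retained)),
       n_aggregates_excluded = n_agg_excl,
       spots = spots)
}
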