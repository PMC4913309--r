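# Diffuse-fluorescence comparator: per-cell summed intensity with the
# column-minimum global background estimator.

#' Column-minimum global background of a field of view
#'
#' For each column of the field the minimum pixel value over rows is
#' taken; the background is the mean of these column minima. Intended to
#' be applied per slice (see [diffuse_per_cell()]).
#'
#' @param field_image 2D numeric matrix (`[y, x]`).
#' @return Scalar background estimate.
#' @examples
#' global_background(matrix(c(1, 3, 5, 2), 2, 2))  # minima 1, 2 -> 1.5
#' @export
global_background <- function(field_image) {
  stopifnot(is.matrix(field_image))
  if (length(field_image) == 0L) stop("empty image", call. = FALSE)
  mean(apply(field_image, 2, min))
}

#' Per-cell net diffuse fluorescence
#'
#' Sums pixel values over all slices within the cell's 2D footprint and
#' subtracts, per slice, the global background times the footprint area:
#' `diffuse_net = sum_z sum_footprint I - sum_z (background_z * area)`.
#' Negative results are kept (no clipping), preserving linearity.
#'
#' @param stack an [image_stack()].
#' @param footprint logical `ny x nx` matrix (the cell's 2D mask, applied
#'   to every slice).
#' @param backgrounds per-slice background scalars; defaults to
#'   [global_background()] of each slice.
#' @return Scalar `diffuse_net` in camera counts.
#' @export
diffuse_per_cell <- function(stack, footprint, backgrounds = NULL) {
  stopifnot(inherits(stack, "image_stack"), is.logical(footprint))
  area <- sum(footprint)
  if (area == 0L) stop("empty cell footprint", call. = FALSE)
  nz <- dim(stack$voxels)[3]
  if (is.null(backgrounds))
    backgrounds <- vapply(seq_len(nz), function(k)
      global_background(stack$voxels[, , k]), 0)
  if (length(backgrounds) == 1L) backgrounds <- rep(backgrounds, nz)
  stopifnot(length(backgrounds) == nz)
  tot <- vapply(seq_len(nz), function(k) sum(stack$voxels[, , k][footprint]), 0)
  sum(tot) - sum(backgrounds) * area
}

#' Diffuse fluorescence for every retained cell of a field
#'
#' @param stack an [image_stack()].
#' @param regions a `cell_regions` object.
#' @param mode `"per_slice"` (default; one [global_background()] per slice)
#'   or `"projection"` (a single background from the mean projection,
#'   applied to every slice).
#' @return Data frame `cell`, `diffuse_net`.
#' @export
diffuse_table <- function(stack, regions,
                          mode = c("per_slice", "projection")) {
  stopifnot(inherits(stack, "image_stack"), inherits(regions, "cell_regions"))
  mode <- match.arg(mode)
  nz <- dim(stack$voxels)[3]
  backgrounds <- if (mode == "per_slice")
    vapply(seq_len(nz), function(k) global_background(stack$voxels[, , k]), 0)
  else
    rep(global_background(apply(stack$voxels, c(1, 2), mean)), nz)
  retained <- regions$regions$cell[regions$regions$retained]
  data.frame(cell = retained,
             diffuse_net = vapply(retained, function(i)
               diffuse_per_cell(stack, regions$labels == i, backgrounds), 0))
}
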