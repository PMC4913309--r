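# Image-stack, cell-table and outline I/O. Formats: plain multi-page
# grayscale TIFF (one page per slice) with a JSON calibration sidecar, and
# CSV for tables. Coordinates are 0-based, (x, y) = (column, row).

#' Construct an image stack
#'
#' @param voxels numeric array `[y, x, z]` of non-negative intensities; a
#'   matrix is promoted to a single-slice stack.
#' @param pixel_size lateral pixel size, nm.
#' @param slice_spacing inter-slice distance, nm.
#' @param channel_label free-text channel name.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size, slice_spacing,
                        channel_label = "QD") {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a [y, x, z] array or a 2D matrix", call. = FALSE)
  if (any(voxels < 0)) stop("intensities must be non-negative", call. = FALSE)
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar(slice_spacing, "slice_spacing", positive = TRUE)
  structure(list(voxels = voxels, pixel_size = pixel_size,
                 slice_spacing = slice_spacing,
                 channel_label = as.character(channel_label)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "Image stack '%s': %d x %d px, %d slices; %.0f nm/px, %.0f nm/slice\n",
    x$channel_label, d[1], d[2], d[3], x$pixel_size, x$slice_spacing))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a z-stack as multi-page 16-bit TIFF
#'
#' `write_stack()` stores one page per slice (values clipped to
#' `[0, 65535]` and rounded) plus a JSON sidecar (`<path>.json`) carrying
#' the calibration and channel label. `read_stack()` restores the stack;
#' calibration comes from the sidecar, or from the `pixel_size` /
#' `slice_spacing` arguments, or — with a warning — from defaults
#' (160 nm / 300 nm).
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path.
#' @return `read_stack()` returns an [image_stack()]; `write_stack()`
#'   returns `path` invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  v[v > 65535] <- 65535
  pages <- lapply(seq_len(dim(v)[3]), function(k) round(v[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(pixel_size = stack$pixel_size, slice_spacing = stack$slice_spacing,
         channel_label = stack$channel_label),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @param pixel_size,slice_spacing optional calibration overrides (nm).
#' @param channel_label optional channel label override.
#' @export
read_stack <- function(path, pixel_size = NULL, slice_spacing = NULL,
                       channel_label = NULL) {
  if (!file.exists(path)) stop("no such TIFF file: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("unreadable TIFF '", path, "': ",
                                             conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("inconsistent page shapes in '", path, "': ",
         paste(unique(shapes), collapse = ", "), call. = FALSE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate gray stored with channels
    round(p * 65535)
  })
  voxels <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  meta <- list()
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  px <- pixel_size %||% meta$pixel_size
  sp <- slice_spacing %||% meta$slice_spacing
  if (is.null(px) || is.null(sp)) {
    warning("no calibration in sidecar or arguments for '", path,
            "'; falling back to 160 nm pixels / 300 nm slices", call. = FALSE)
    px <- px %||% 160
    sp <- sp %||% 300
  }
  image_stack(voxels, pixel_size = px, slice_spacing = sp,
              channel_label = channel_label %||% meta$channel_label %||% "QD")
}

cell_table_columns <- c("field", "cell", "condition", "qd_count",
                        "diffuse_net")

#' Write / read the per-cell measurement table
#'
#' One row per cell with stable column order: `field`, `cell`, `condition`,
#' `qd_count`, `diffuse_net`, then any extra columns (e.g.
#' `marker_intensity`, QC flags). Numeric values round-trip losslessly
#' through the paired reader.
#'
#' @param records data frame of per-cell records; must contain the five
#'   core columns and have unique `(field, cell)` keys.
#' @param path CSV path.
#' @export
write_cell_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(cell_table_columns, names(records))
  if (length(missing_cols))
    stop("cell table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(records) && anyDuplicated(records[, c("field", "cell")]))
    stop("duplicate (field, cell) keys in cell table", call. = FALSE)
  ord <- c(cell_table_columns, setdiff(names(records), cell_table_columns))
  write.csv(format_numeric_full(records[, ord, drop = FALSE]), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

# Full-precision numeric formatting so CSV round-trips are lossless.
format_numeric_full <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

#' Write / read / rasterize cell outlines
#'
#' Outline tables hold one row per polygon vertex: `cell`, `x`, `y`
#' (0-based pixel coordinates, vertex order preserved). Each cell must form
#' a simple (non-self-intersecting) closed polygon with at least three
#' vertices; the closing edge back to the first vertex is implicit.
#'
#' @param outlines data frame with columns `cell`, `x`, `y`.
#' @param path CSV path.
#' @export
write_outlines <- function(outlines, path) {
  validate_outlines(outlines)
  write.csv(format_numeric_full(outlines[, c("cell", "x", "y")]), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_outlines
#' @export
read_outlines <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  validate_outlines(out)
  out
}

validate_outlines <- function(outlines) {
  stopifnot(is.data.frame(outlines))
  if (!all(c("cell", "x", "y") %in% names(outlines)))
    stop("outlines need columns cell, x, y", call. = FALSE)
  for (id in unique(outlines$cell)) {
    v <- outlines[outlines$cell == id, ]
    if (nrow(v) < 3L)
      stop("cell ", id, " outline has fewer than 3 vertices", call. = FALSE)
    if (polygon_self_intersects(v$x, v$y))
      stop("cell ", id, " outline is self-intersecting", call. = FALSE)
  }
  invisible(outlines)
}

# Proper-crossing test between non-adjacent edges of the closed polygon.
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]  # skip edges sharing a vertex
    for (j in js)
      if (segments_cross(x[i], y[i], x2[i], y2[i], x[j], y[j], x2[j], y2[j]))
        return(TRUE)
  }
  FALSE
}

segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' @rdname write_outlines
#' @param ny,nx label-map dimensions in pixels.
#' @return `outlines_to_mask()` returns an integer `ny x nx` label matrix:
#'   a pixel belongs to a cell iff its center (integer `(x, y)`) lies
#'   inside or on the boundary of that cell's polygon (even-odd rule).
#' @export
outlines_to_mask <- function(outlines, ny, nx) {
  validate_outlines(outlines)
  labels <- matrix(0L, ny, nx)
  px <- rep(0:(nx - 1), each = ny)
  py <- rep(0:(ny - 1), nx)
  for (id in unique(outlines$cell)) {
    v <- outlines[outlines$cell == id, ]
    inside <- points_in_polygon(px, py, v$x, v$y)
    labels[inside] <- as.integer(id)
  }
  labels
}

# Even-odd (crossing number) point-in-polygon, boundary counted as inside.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # boundary: point on segment (i, j)
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    within <- pmin(xi, xj) - 1e-9 <= px & px <= pmax(xi, xj) + 1e-9 &
              pmin(yi, yj) - 1e-9 <= py & py <= pmax(yi, yj) + 1e-9
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    crosses <- ((yi > py) != (yj > py)) &
      (px < xi + (xj - xi) * (py - yi) / (yj - yi))
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}
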