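# Threshold-based single-cell segmentation with debris/aggregate removal.

#' Collapse a z-stack to a 2D reference image
#'
#' @param stack an [image_stack()].
#' @param mode `"sum_projection"` (pixel-wise sum over z; default — noise
#'   averages out, so dim cells keep contrast) or `"max_projection"`
#'   (pixel-wise maximum; favors sparse bright structures but compresses
#'   contrast under deep stacks of noise).
#' @return A numeric `ny x nx` matrix.
#' @export
make_reference <- function(stack, mode = c("sum_projection",
                                           "max_projection")) {
  stopifnot(inherits(stack, "image_stack"))
  mode <- match.arg(mode)
  if (mode == "max_projection") apply(stack$voxels, c(1, 2), max)
  else apply(stack$voxels, c(1, 2), sum)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge any label
# pairs that touch diagonally (union-find), then relabel 1..K in raster
# order of each component's first pixel for determinism.
label_components8 <- function(binary) {
  l4 <- EBImage::bwlabel(EBImage::Image(binary * 1))
  l4 <- matrix(as.integer(round(as.matrix(l4))), nrow(binary), ncol(binary))
  k <- max(l4)
  if (k == 0L) return(l4)
  parent <- seq_len(k)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  ny <- nrow(l4); nx <- ncol(l4)
  # diagonal neighbor label pairs
  pairs <- rbind(
    cbind(as.vector(l4[-ny, -nx]), as.vector(l4[-1, -1])),   # down-right
    cbind(as.vector(l4[-1, -nx]), as.vector(l4[-ny, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(k), find, 1L)
  merged <- l4
  merged[l4 > 0L] <- roots[l4[l4 > 0L]]
  # deterministic relabeling by first occurrence in column-major order
  ids <- unique(merged[merged > 0L])
  relab <- integer(max(roots))
  relab[ids] <- seq_along(ids)
  out <- merged
  out[merged > 0L] <- relab[merged[merged > 0L]]
  out
}

#' Segment single cells from a reference image
#'
#' Global threshold (Otsu by default) followed by 8-connected component
#' labeling. Components below `min_area` are flagged as debris
#' (`too_small`), above `max_area` as aggregates (`too_large`), and
#' components touching the field border are excluded by default (partial
#' cells bias counts). Aggregates are removed, never split.
#'
#' @param reference 2D numeric matrix (e.g. from [make_reference()]) or a
#'   supplied mask channel.
#' @param min_area,max_area retained-component area bounds, pixels.
#' @param threshold_method `"otsu"` or `"absolute"`.
#' @param threshold absolute intensity threshold (required when
#'   `threshold_method = "absolute"`).
#' @param exclude_border drop border-touching components (default TRUE).
#' @return An object of class `cell_regions`: a list with
#'   \describe{
#'     \item{labels}{integer label map of \emph{retained} regions
#'       (pairwise disjoint by construction),}
#'     \item{all_labels}{label map of every detected component,}
#'     \item{regions}{data frame `cell`, `area`, `cx`, `cy`,
#'       `touches_border`, `excluded_reason` (`""`, `"too_small"`,
#'       `"too_large"` or `"border"`), `retained`.}
#'   }
#' @examples
#' img <- matrix(0, 64, 64)
#' img[20:30, 10:20] <- 50   # one 11 x 11 block
#' r <- segment_cells(img, min_area = 20, max_area = 500,
#'                    threshold_method = "absolute", threshold = 10)
#' r$regions
#' @export
segment_cells <- function(reference, min_area = 300, max_area = 8000,
                          threshold_method = c("otsu", "absolute"),
                          threshold = NULL, exclude_border = TRUE) {
  stopifnot(is.matrix(reference))
  threshold_method <- match.arg(threshold_method)
  if (min_area >= max_area)
    stop("'min_area' must be < 'max_area'", call. = FALSE)
  rng <- range(reference)
  if (threshold_method == "otsu") {
    if (diff(rng) == 0) {
      thr <- rng[1]  # flat image: nothing exceeds the threshold
    } else {
      scaled <- (reference - rng[1]) / diff(rng)
      thr <- rng[1] + EBImage::otsu(EBImage::Image(scaled)) * diff(rng)
    }
  } else {
    if (is.null(threshold))
      stop("'threshold' is required with threshold_method = 'absolute'",
           call. = FALSE)
    thr <- threshold
  }
  binary <- reference > thr
  all_labels <- label_components8(binary)
  k <- max(all_labels)
  regions <- data.frame(cell = integer(0), area = integer(0),
                        cx = numeric(0), cy = numeric(0),
                        touches_border = logical(0),
                        excluded_reason = character(0),
                        retained = logical(0))
  ny <- nrow(reference); nx <- ncol(reference)
  if (k > 0) {
    idx <- which(all_labels > 0L)
    lab <- all_labels[idx]
    row0 <- (idx - 1L) %% ny          # 0-based y
    col0 <- (idx - 1L) %/% ny         # 0-based x
    area <- tabulate(lab, k)
    cx <- vapply(seq_len(k), function(i) mean(col0[lab == i]), 0)
    cy <- vapply(seq_len(k), function(i) mean(row0[lab == i]), 0)
    border <- vapply(seq_len(k), function(i)
      any(row0[lab == i] == 0L | row0[lab == i] == ny - 1L |
          col0[lab == i] == 0L | col0[lab == i] == nx - 1L), NA)
    reason <- ifelse(area < min_area, "too_small",
              ifelse(area > max_area, "too_large",
              ifelse(border & exclude_border, "border", "")))
    regions <- data.frame(cell = seq_len(k), area = area, cx = cx, cy = cy,
                          touches_border = border, excluded_reason = reason,
                          retained = reason == "",
                          stringsAsFactors = FALSE)
  }
  labels <- all_labels
  if (k > 0) {
    drop <- regions$cell[!regions$retained]
    labels[labels %in% drop] <- 0L
  }
  structure(list(labels = labels, all_labels = all_labels, regions = regions,
                 threshold = thr),
            class = "cell_regions")
}

#' @export
print.cell_regions <- function(x, ...) {
  r <- x$regions
  cat(sprintf(
    "Segmentation: %d components, %d retained (threshold %.3g)\n",
    nrow(r), sum(r$retained), x$threshold))
  if (any(!r$retained)) {
    tab <- table(r$excluded_reason[!r$retained])
    cat("  excluded:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build a `cell_regions` object from a known label map
#'
#' Wraps an existing labeled mask (e.g. synthetic ground truth or
#' rasterized outlines) so it can be used wherever [segment_cells()] output
#' is expected. All regions are retained.
#'
#' @param labels integer label matrix (0 = background).
#' @return A `cell_regions` object.
#' @export
regions_from_labels <- function(labels) {
  stopifnot(is.matrix(labels))
  ids <- sort(unique(labels[labels > 0]))
  ny <- nrow(labels)
  rows <- lapply(ids, function(i) {
    idx <- which(labels == i)
    row0 <- (idx - 1L) %% ny
    col0 <- (idx - 1L) %/% ny
    data.frame(cell = i, area = length(idx), cx = mean(col0),
               cy = mean(row0), touches_border = FALSE,
               excluded_reason = "", retained = TRUE,
               stringsAsFactors = FALSE)
  })
  regions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = integer(0), area = integer(0), cx = numeric(0),
               cy = numeric(0), touches_border = logical(0),
               excluded_reason = character(0), retained = logical(0))
  structure(list(labels = labels, all_labels = labels, regions = regions,
                 threshold = NA_real_),
            class = "cell_regions")
}
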