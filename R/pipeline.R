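# End-to-end orchestration: simulate -> count -> compare, with YAML
# configs and reproducible outputs. These functions are also what the
# command-line wrapper (inst/cli/qdcount) calls.

#' Read / write a pipeline configuration
#'
#' The YAML config has optional blocks `scene`, `population`, `detection`,
#' `segmentation` and `stats`, each holding the arguments of the matching
#' constructor ([scene_spec()], [population_spec()], [detection_params()],
#' [segment_cells()], [compare_conditions()]). Round-trips exactly:
#' `read_config(write_config(cfg, path))` reproduces the same specs.
#'
#' @param config a named list (or the objects themselves under the block
#'   names).
#' @param path YAML file path.
#' @return `read_config()` returns a named list with instantiated
#'   `scene`/`population`/`detection` objects where the blocks are present.
#' @export
write_config <- function(config, path) {
  strip <- function(b) {
    if (is.null(b)) return(NULL)
    b <- unclass(b)
    b[!vapply(b, is.null, NA)]
  }
  yaml::write_yaml(lapply(config, strip), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- raw
  if (!is.null(raw$scene)) out$scene <- do.call(scene_spec, raw$scene)
  if (!is.null(raw$population))
    out$population <- do.call(population_spec, raw$population)
  if (!is.null(raw$detection))
    out$detection <- do.call(detection_params, raw$detection)
  out
}

#' Simulate a scene and write it to disk
#'
#' Writes `scene.tif` (+ JSON calibration sidecar), `cells.csv`,
#' `emitters.csv` and `scene_spec.json` (a config echo that re-feeds into
#' [scene_spec()]) into `out_dir`. Deterministic per seed: repeated runs
#' produce byte-identical CSVs.
#'
#' @param spec a [scene_spec()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the [simulate_scene()] result.
#' @export
run_simulate <- function(spec, out_dir) {
  stopifnot(inherits(spec, "scene_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  sim <- simulate_scene(spec)
  write_stack(sim$stack, file.path(out_dir, "scene.tif"))
  write.csv(format_numeric_full(sim$truth$cells),
            file.path(out_dir, "cells.csv"), row.names = FALSE, quote = FALSE)
  write.csv(format_numeric_full(sim$truth$emitters),
            file.path(out_dir, "emitters.csv"), row.names = FALSE,
            quote = FALSE)
  jsonlite::write_json(unclass(spec)[!vapply(unclass(spec), is.null, NA)],
                       file.path(out_dir, "scene_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

#' Count spots and quantify diffuse fluorescence for one or more fields
#'
#' For each image stack: segments cells on a reference projection, detects
#' and links spot candidates, classifies aggregates, counts spots per
#' cell, and computes per-cell net diffuse fluorescence. Results are
#' merged into one per-cell table (one `field` id per stack).
#'
#' @param stacks a list of [image_stack()] objects, or a character vector
#'   of TIFF paths for [read_stack()].
#' @param condition condition label recorded for every cell.
#' @param params a [detection_params()].
#' @param min_area,max_area,threshold_method,threshold segmentation
#'   settings (see [segment_cells()]).
#' @param regions optional list of precomputed `cell_regions` (one per
#'   stack), bypassing segmentation (e.g. ground-truth masks).
#' @param reference_mode projection mode for [make_reference()].
#' @param out optional CSV path; when given, the table is written with
#'   [write_cell_table()].
#' @param verbose log per-field retention/exclusion tallies via `message()`.
#' @return The per-cell data frame (`field`, `cell`, `condition`,
#'   `qd_count`, `diffuse_net`, `n_orphans` per field attribute columns).
#' @export
run_count <- function(stacks, condition = "untreated",
                      params = detection_params(),
                      min_area = 300, max_area = 8000,
                      threshold_method = "otsu", threshold = NULL,
                      regions = NULL,
                      reference_mode = "sum_projection",
                      out = NULL, verbose = TRUE) {
  if (is.character(stacks)) stacks <- lapply(stacks, read_stack)
  if (inherits(stacks, "image_stack")) stacks <- list(stacks)
  if (inherits(regions, "cell_regions")) regions <- list(regions)
  tabs <- vector("list", length(stacks))
  for (fi in seq_along(stacks)) {
    stack <- stacks[[fi]]
    reg <- if (!is.null(regions)) regions[[fi]] else
      segment_cells(make_reference(stack, reference_mode),
                    min_area = min_area, max_area = max_area,
                    threshold_method = threshold_method,
                    threshold = threshold)
    cand <- detect_candidates(stack, params)
    spots <- link_across_slices(stack, cand, params)
    spots <- classify_aggregates(spots, params)
    counted <- count_spots_per_cell(spots, reg, params)
    dt <- diffuse_table(stack, reg)
    tab <- merge(counted$counts, dt, by = "cell")
    if (verbose) {
      r <- reg$regions
      message(sprintf(
        "field %d: %d components, %d retained (%s); %d spots, %d orphans, %d aggregates excluded",
        fi, nrow(r), sum(r$retained),
        if (any(!r$retained))
          paste(names(table(r$excluded_reason[!r$retained])),
                table(r$excluded_reason[!r$retained]), sep = "=",
                collapse = ", ")
        else "none excluded",
        nrow(spots), counted$n_orphans, counted$n_aggregates_excluded))
    }
    tabs[[fi]] <- data.frame(field = fi, cell = tab$cell,
                             condition = condition, qd_count = tab$qd_count,
                             diffuse_net = tab$diffuse_net,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, tabs)
  if (!is.null(out)) write_cell_table(res, out)
  res
}

#' Compare per-cell tables across conditions and write the results
#'
#' @param cells a per-cell data frame (or CSV path readable by
#'   [read_cell_table()]) containing all conditions.
#' @param out optional path prefix; writes `<out>_comparisons.csv` and the
#'   bee-swarm-ready `<out>_cells_long.csv`.
#' @param ... passed to [compare_conditions()].
#' @return The [compare_conditions()] object.
#' @export
run_compare <- function(cells, out = NULL, ...) {
  if (is.character(cells)) cells <- read_cell_table(cells)
  cmp <- compare_conditions(cells, ...)
  if (!is.null(out)) {
    write.csv(format_numeric_full(cmp$table),
              paste0(out, "_comparisons.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(format_numeric_full(cmp$cells),
              paste0(out, "_cells_long.csv"), row.names = FALSE,
              quote = FALSE)
  }
  cmp
}
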