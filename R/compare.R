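# Condition-level comparison of per-cell measurements against an
# untreated reference.

#' Score every treated condition against the untreated reference
#'
#' For each non-reference condition in a per-cell table this computes the
#' index of drug insensitivity, the rank-sum U statistic and p-value, the
#' mean phosphoresponse in untreated-SD units, and p-values adjusted over
#' the set of conditions (the drug panel) by step-down Holm-Sidak. Each
#' treated cell is additionally flagged as an outlier when its value is at
#' least the untreated mean (the cells that look untreated despite the
#' drug).
#'
#' @param cells data frame with at least a condition column and a value
#'   column (e.g. the table from [write_cell_table()]).
#' @param value name of the measurement column (default `"qd_count"`).
#' @param condition name of the condition column.
#' @param reference label of the untreated reference condition.
#' @param alternative passed to [ranksum_test()].
#' @param adjust_method passed to [adjust_pvalues()].
#' @return An object of class `qdp_comparison`: a list with
#'   \describe{
#'     \item{table}{one row per treated condition: `condition`, `M`, `N`,
#'       `index`, `U`, `p_value`, `p_adjusted`, `mean_phosphoresponse`,}
#'     \item{cells}{long-format per-cell data (`condition`, `cell`,
#'       `value`, `outlier`) ready for bee-swarm plotting,}
#'     \item{reference, value, alternative, adjust_method}{the settings.}
#'   }
#' @examples
#' cells <- data.frame(
#'   condition = rep(c("untreated", "drugA"), each = 50),
#'   qd_count = c(rnbinom(50, size = 5, mu = 100),
#'                rnbinom(50, size = 5, mu = 20)))
#' compare_conditions(cells)
#' @export
compare_conditions <- function(cells, value = "qd_count",
                               condition = "condition",
                               reference = "untreated",
                               alternative = c("two_sided", "treated_lower"),
                               adjust_method = "holm_sidak") {
  alternative <- match.arg(alternative)
  stopifnot(is.data.frame(cells))
  if (!condition %in% names(cells) || !value %in% names(cells))
    stop("'cells' must contain columns '", condition, "' and '", value, "'",
         call. = FALSE)
  conds <- unique(cells[[condition]])
  if (!reference %in% conds)
    stop("reference condition '", reference, "' not present in the table",
         call. = FALSE)
  x <- cells[[value]][cells[[condition]] == reference]
  treated_conds <- setdiff(conds, reference)
  rows <- lapply(treated_conds, function(cc) {
    y <- cells[[value]][cells[[condition]] == cc]
    rs <- ranksum_test(x, y, alternative = alternative)
    data.frame(condition = cc, M = rs$M, N = rs$N, index = rs$index,
               U = rs$U, p_value = rs$p_value,
               mean_phosphoresponse = mean_phosphoresponse(x, y),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(
    data.frame(condition = character(0), M = integer(0), N = integer(0),
               index = numeric(0), U = numeric(0), p_value = numeric(0),
               mean_phosphoresponse = numeric(0)))))
  tab$p_adjusted <- adjust_pvalues(tab$p_value, method = adjust_method)
  tab <- tab[, c("condition", "M", "N", "index", "U", "p_value",
                 "p_adjusted", "mean_phosphoresponse")]
  long <- data.frame(condition = cells[[condition]],
                     cell = if ("cell" %in% names(cells)) cells$cell
                            else seq_len(nrow(cells)),
                     value = cells[[value]], stringsAsFactors = FALSE)
  long$outlier <- long$condition != reference & long$value >= mean(x)
  structure(list(table = tab, cells = long, reference = reference,
                 value = value, alternative = alternative,
                 adjust_method = adjust_method),
            class = "qdp_comparison")
}

#' @export
print.qdp_comparison <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Drug-insensitivity scoring of '%s' vs reference '%s' (%d condition%s)\n",
    x$value, x$reference, nrow(x$table), if (nrow(x$table) == 1) "" else "s"))
  tab <- x$table
  tab$index <- sprintf("%.3f (%2.0f%%)", tab$index, 100 * tab$index)
  print(format(tab, digits = digits), row.names = FALSE)
  cat("index 0.5 = treated indistinguishable from untreated;",
      "-> 0 = complete inhibition\n")
  invisible(x)
}

#' @export
summary.qdp_comparison <- function(object, ...) {
  out <- object$table
  out$n_outliers <- vapply(out$condition, function(cc)
    sum(object$cells$outlier[object$cells$condition == cc]), 0L)
  out
}
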