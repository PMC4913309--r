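# Population-level scoring: index of drug insensitivity, rank-sum test,
# multiple-comparison adjustment, phosphoresponse and S/N summaries.

check_sample <- function(v, name) {
  if (!is.numeric(v) || length(v) < 1L)
    stop(sprintf("'%s' must be a non-empty numeric sample", name),
         call. = FALSE)
  if (any(!is.finite(v)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  invisible(v)
}

#' Index of drug insensitivity
#'
#' The probability that a randomly chosen treated cell has a higher
#' measurement than a randomly chosen untreated cell, with ties split
#' evenly:
#' \deqn{\frac{1}{MN}\sum_{i=1}^{M}\sum_{j=1}^{N}
#'   \left[\delta(x_i < y_j) + 0.5\,\delta(x_i = y_j)\right]}
#' where \eqn{\delta} is 1 when its argument holds and 0 otherwise. An
#' index of 0.5 means the treated and untreated populations are
#' indistinguishable (maximal insensitivity); values approaching 0 mean
#' complete inhibition. Computed via midranks in
#' `O((M+N) log(M+N))`, exactly equal to the double sum.
#'
#' @param x untreated per-cell measurements (size M).
#' @param y treated per-cell measurements (size N).
#' @return The index, a probability in `[0, 1]`. The complement identity
#'   `index(x, y) + index(y, x) == 1` holds for all inputs.
#' @examples
#' index_of_insensitivity(c(1, 2), c(1, 2))  # 0.5: identical samples
#' index_of_insensitivity(c(5, 3), c(1, 2))  # 0: complete separation
#' @export
index_of_insensitivity <- function(x, y) {
  check_sample(x, "x"); check_sample(y, "y")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))  # midranks handle the 0.5 tie term exactly
  u <- sum(r[(m + 1):(m + n)]) - n * (n + 1) / 2
  u / (m * n)
}

#' Wilcoxon rank-sum comparison of untreated vs treated populations
#'
#' The statistic is `U = M * N * index_of_insensitivity(x, y)` (the number
#' of (untreated, treated) pairs with the treated value higher, ties
#' counting one half). The null hypothesis is that the two populations
#' share one distribution. For `M * N <= 64` with no ties the p-value is
#' exact (full enumeration of the U distribution); otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. Distribution-free: no normality or threshold assumptions.
#'
#' @param x,y untreated / treated samples.
#' @param alternative `"two_sided"` (populations differ) or
#'   `"treated_lower"` (treated values are stochastically lower, i.e. the
#'   drug works).
#' @return A list of class `ranksum_test`: `U`, `p_value`, `index`, `M`,
#'   `N`, `alternative`, `method` (`"exact"` or `"normal_approx"`).
#' @export
ranksum_test <- function(x, y, alternative = c("two_sided",
                                               "treated_lower")) {
  alternative <- match.arg(alternative)
  check_sample(x, "x"); check_sample(y, "y")
  m <- length(x); n <- length(y)
  idx <- index_of_insensitivity(x, y)
  u <- idx * m * n
  pooled <- c(x, y)
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  if (length(unique(pooled)) == 1L) {
    warning("all values tied across both samples; p = 1", call. = FALSE)
    p <- 1
    method <- "degenerate"
  } else if (m * n <= 64 && !has_ties) {
    method <- "exact"
    # pwilcox is the CDF of the #(x > y) pair count for sample sizes (m, n);
    # our U counts y-higher pairs, so U_lower-tail = P(W >= mn - u).
    p_lower <- 1 - pwilcox(m * n - u - 1, m, n)
    p_upper <- pwilcox(u, n, m)  # P(U <= u) by symmetry of roles
    p <- switch(alternative,
                treated_lower = p_lower,
                two_sided = min(1, 2 * min(p_lower, 1 - p_lower +
                                             dwilcox_at(u, m, n))))
  } else {
    method <- "normal_approx"
    mu <- m * n / 2
    tie_term <- sum(ties^3 - ties)
    v <- m * n / 12 * ((m + n + 1) - tie_term / ((m + n) * (m + n - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      # continuity-corrected z toward the null
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(v)
      if (abs(u - mu) <= 0.5) z <- 0
      p <- switch(alternative,
                  two_sided = 2 * pnorm(-abs(z)),
                  treated_lower = pnorm((u - mu + 0.5) / sqrt(v)))
      p <- min(1, p)
    }
  }
  structure(list(U = u, p_value = p, index = idx, M = m, N = n,
                 alternative = alternative, method = method),
            class = "ranksum_test")
}

# point mass of the no-tie U distribution at integer u (0 elsewhere)
dwilcox_at <- function(u, m, n) {
  if (abs(u - round(u)) > 1e-9) return(0)
  stats::dwilcox(round(u), m, n)
}

#' @export
print.ranksum_test <- function(x, ...) {
  cat(sprintf(paste0(
    "Rank-sum comparison (M = %d untreated, N = %d treated)\n",
    "  index of insensitivity = %.4f (%.1f%%), U = %.1f\n",
    "  p = %.4g (%s, %s)\n"),
    x$M, x$N, x$index, 100 * x$index, x$U, x$p_value, x$alternative,
    x$method))
  invisible(x)
}

#' Multiple-comparison adjustment of p-values
#'
#' Step-down Holm-Sidak by default: with the p-values sorted ascending,
#' `adjusted_(i) = max_{j <= i} [1 - (1 - p_(j))^(m - j + 1)]`, clipped to
#' `[0, 1]` and mapped back to input order. `"holm"` and `"bonferroni"`
#' delegate to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"holm_sidak"`, `"holm"` or `"bonferroni"`.
#' @return Adjusted p-values in input order.
#' @export
adjust_pvalues <- function(p, method = c("holm_sidak", "holm",
                                         "bonferroni")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (method != "holm_sidak")
    return(p.adjust(p, method = method))
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- cummax(pmin(1, 1 - (1 - ps)^(m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Mean phosphoresponse in units of untreated SD
#'
#' `(mean(y) - mean(x)) / sd(x)`: the shift of the treated mean from the
#' untreated mean, in units of the untreated population's standard
#' deviation (sample SD, denominator M - 1). Negative values mean
#' inhibition.
#'
#' @param x untreated sample (M >= 2, non-constant).
#' @param y treated sample.
#' @return The response in sigma-units.
#' @export
mean_phosphoresponse <- function(x, y) {
  check_sample(x, "x"); check_sample(y, "y")
  if (length(x) < 2L) stop("need M >= 2 untreated cells", call. = FALSE)
  s <- sd(x)
  if (s == 0) stop("untreated sample has zero standard deviation",
                   call. = FALSE)
  (mean(y) - mean(x)) / s
}

#' Signal-to-noise versus an isotype control
#'
#' Ratio of the mean signal measurement to the mean isotype-control
#' measurement. The isotype control (labeling without the specific primary
#' antibody) defines the assay noise floor.
#'
#' @param signal per-cell measurements under specific labeling.
#' @param isotype_control per-cell measurements of the isotype control;
#'   mean must be positive.
#' @return `mean(signal) / mean(isotype_control)`.
#' @export
signal_to_noise <- function(signal, isotype_control) {
  check_sample(signal, "signal"); check_sample(isotype_control,
                                               "isotype_control")
  mc <- mean(isotype_control)
  if (mc <= 0) stop("isotype control mean must be > 0", call. = FALSE)
  mean(signal) / mc
}
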