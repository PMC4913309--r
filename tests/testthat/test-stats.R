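test_that("index matches its defining examples", {
  expect_identical(index_of_insensitivity(c(1, 2), c(1, 2)), 0.5)
  expect_identical(index_of_insensitivity(c(5, 3), c(1, 2)), 0)
  expect_identical(index_of_insensitivity(c(1, 2), c(5, 3)), 1)
  expect_error(index_of_insensitivity(numeric(0), 1), "non-empty")
  expect_error(index_of_insensitivity(c(1, NA), 1), "non-finite")
})

test_that("fast index equals the brute-force double sum exactly", {
  set.seed(99)
  for (i in 1:200) {
    m <- sample(1:12, 1); n <- sample(1:12, 1)
    x <- sample(0:8, m, replace = TRUE)   # heavy ties on purpose
    y <- sample(0:8, n, replace = TRUE)
    expect_identical(index_of_insensitivity(x, y), bf_index(x, y))
    expect_identical(suppressWarnings(ranksum_test(x, y))$U,
                     bf_index(x, y) * m * n)
  }
})

test_that("index complement and permutation-null identities hold", {
  set.seed(3)
  for (i in 1:50) {
    x <- rnbinom(sample(5:60, 1), size = 5, mu = 50)
    y <- rnbinom(sample(5:60, 1), size = 5, mu = 20)
    expect_equal(index_of_insensitivity(x, y) +
                 index_of_insensitivity(y, x), 1)
    expect_identical(index_of_insensitivity(x, sample(x)), 0.5)
  }
})

test_that("rank-sum test handles its stated cases", {
  rs <- ranksum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(rs$U, 4.5)
  expect_equal(rs$p_value, 1)

  # complete separation at M = N = 10, one-sided
  x <- 101:110; y <- 1:10
  rs2 <- ranksum_test(x, y, alternative = "treated_lower")
  expect_lt(rs2$p_value, 0.001)
  # independent exact oracle
  oracle <- wilcox.test(y, x, alternative = "less", exact = TRUE)$p.value
  expect_lt(oracle, 0.001)

  expect_warning(rs3 <- ranksum_test(rep(4, 5), rep(4, 7)), "tied")
  expect_equal(rs3$p_value, 1)
})

test_that("exact small-sample p-values match wilcox.test enumeration", {
  set.seed(12)
  for (i in 1:40) {
    m <- sample(2:8, 1); n <- sample(2:8, 1)
    if (m * n > 64) next
    repeat {  # unique values so the exact path is taken
      x <- round(rnorm(m, 50, 20), 6); y <- round(rnorm(n, 40, 20), 6)
      if (!anyDuplicated(c(x, y))) break
    }
    rs <- ranksum_test(x, y)
    expect_equal(rs$method, "exact")
    w <- wilcox.test(y, x, exact = TRUE)
    expect_equal(rs$p_value, w$p.value, tolerance = 1e-12)
    w1 <- wilcox.test(y, x, alternative = "less", exact = TRUE)
    expect_equal(ranksum_test(x, y, "treated_lower")$p_value, w1$p.value,
                 tolerance = 1e-12)
  }
})

test_that("normal-approximation p-values match wilcox.test with ties", {
  set.seed(21)
  for (i in 1:25) {
    x <- rnbinom(40, size = 4, mu = 30)
    y <- rnbinom(35, size = 4, mu = 22)
    rs <- ranksum_test(x, y)
    expect_equal(rs$method, "normal_approx")
    w <- wilcox.test(y, x, exact = FALSE, correct = TRUE)
    expect_equal(rs$p_value, w$p.value, tolerance = 1e-9)
  }
})

test_that("Holm-Sidak adjustment matches the step-down closed form", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  p <- c(0.01, 0.04, 0.03)
  # sorted: 0.01, 0.03, 0.04 with multipliers 3, 2, 1 and running max
  exp_sorted <- cummax(c(1 - (1 - 0.01)^3, 1 - (1 - 0.03)^2, 0.04))
  expect_equal(adjust_pvalues(p), exp_sorted[c(1, 3, 2)])
  expect_equal(adjust_pvalues(rep(1, 4)), rep(1, 4))
  expect_equal(adjust_pvalues(p, "holm"), p.adjust(p, "holm"))
  expect_equal(adjust_pvalues(p, "bonferroni"), p.adjust(p, "bonferroni"))
  expect_error(adjust_pvalues(c(0.2, 1.4)), "\\[0, 1\\]")
  # adjusted never below raw, monotone in the raw ordering (ties allowed)
  set.seed(6)
  q <- runif(10)
  a <- adjust_pvalues(q)
  expect_true(all(a >= q))
  expect_true(all(diff(a[order(q)]) >= 0))
})

test_that("mean phosphoresponse is the sigma-unit mean shift", {
  x <- c(90, 100, 110); y <- x
  expect_equal(mean_phosphoresponse(x, y), 0)
  set.seed(8)
  x <- rnorm(200, 100, 10)
  y <- rnorm(150, 80, 12)
  expect_equal(mean_phosphoresponse(x, y),
               (mean(y) - mean(x)) / sd(x))
  # shifting y by +c moves the response by c / sd(x)
  expect_equal(mean_phosphoresponse(x, y + 7) - mean_phosphoresponse(x, y),
               7 / sd(x))
  expect_error(mean_phosphoresponse(c(5), y), "M >= 2")
  expect_error(mean_phosphoresponse(rep(3, 10), y), "zero standard")
})

test_that("signal-to-noise is a scale-invariant mean ratio", {
  expect_equal(signal_to_noise(c(5, 7), c(5, 7)), 1)
  expect_equal(signal_to_noise(rep(60, 9), rep(6, 4)), 10)
  set.seed(4)
  s <- rpois(50, 40) + 1; c0 <- rpois(50, 5) + 1
  expect_equal(signal_to_noise(s * 3.7, c0 * 3.7), signal_to_noise(s, c0))
  expect_error(signal_to_noise(s, rep(0, 5)), "> 0")
})

test_that("compare_conditions scores a drug panel coherently", {
  set.seed(14)
  ut <- rnbinom(120, size = 5, mu = 100)
  cells <- data.frame(
    condition = c(rep("untreated", 120), rep("drugA", 100),
                  rep("drugB", 100), rep("drugC", 100)),
    qd_count = c(ut, ut[1:100],                        # identical copy
                 rnbinom(100, size = 5, mu = 25),
                 rnbinom(100, size = 5, mu = 60)))
  cmp <- compare_conditions(cells)
  tab <- cmp$table
  expect_equal(tab$condition, c("drugA", "drugB", "drugC"))
  expect_equal(tab$index[1], 0.5, tolerance = 0.06)
  expect_lt(tab$index[2], tab$index[3])
  expect_equal(tab$p_adjusted, adjust_pvalues(tab$p_value))
  # outlier flag: treated cells at/above the untreated mean
  longA <- cmp$cells[cmp$cells$condition == "drugA", ]
  expect_equal(longA$outlier, longA$value >= mean(ut))
  expect_error(compare_conditions(cells, reference = "missing"),
               "not present")
  s <- summary(cmp)
  expect_true(all(c("condition", "n_outliers") %in% names(s)))
})

test_that("complete separation drives the index to zero", {
  cells <- data.frame(condition = rep(c("untreated", "drug"), each = 30),
                      qd_count = c(101:130, 1:30))
  cmp <- compare_conditions(cells)
  expect_equal(cmp$table$index, 0)
  expect_lt(cmp$table$p_value, 1e-6)
})
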