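test_that("metrics reproduce hand arithmetic from confusion counts", {
  m <- metrics_from_counts(tp = 227, fp = 2, tn = 217, fn = 11)
  expect_equal(m$recall, 227 / 238)
  expect_equal(m$specificity, 217 / 219)
  expect_equal(m$accuracy, 444 / 457)
  expect_equal(m$missed_lesion_rate, 11 / 238)
  expect_equal(m$mislabeled_healthy_rate, 2 / 219)

  perfect <- metrics(c(0, 1, 1, 0), c(0, 1, 1, 0), c(0.1, 0.9, 0.8, 0.2))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)

  ## zero denominators surface as NaN, never silent zeros
  deg <- metrics(c(0, 0), c(0, 0))
  expect_true(is.nan(deg$precision))
  expect_true(attr(deg, "degenerate"))
  expect_error(metrics(c(0, 1), c(0)), class = "radfuse_config_error")
})

test_that("AUC uses the tie-half Mann-Whitney convention and matches oracles", {
  y <- c(0, 0, 1, 1)
  expect_equal(auc_mann_whitney(y, c(0.5, 0.5, 0.5, 0.5)), 0.5)

  set.seed(61)
  for (i in 1:10) {
    yy <- rep(0:1, each = 20)
    sc <- round(rnorm(40, mean = yy), 1)   # rounding induces ties
    expect_equal(auc_mann_whitney(yy, sc), oracle_auc_trapezoid(yy, sc),
                 tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  yy <- rep(0:1, each = 25); sc <- rnorm(50, mean = yy)
  expect_equal(auc_mann_whitney(yy, sc),
               as.numeric(pROC::auc(pROC::roc(yy, sc, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("paired t-test matches the closed form and flags degeneracy", {
  a <- c(0.91, 0.93, 0.92, 0.95, 0.94)
  b <- c(0.90, 0.91, 0.90, 0.93, 0.92)
  res <- paired_t(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)

  same <- paired_t(a, a)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)

  tiny <- paired_t(b + 1 + rnorm(5, sd = 1e-6), b)
  expect_lt(tiny$p_value, 0.01)
})

test_that("Wilcoxon signed-rank exact p matches enumeration", {
  ## n = 5, all differences one sign: two-sided p = 2/32
  res5 <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(res5$p_value, 0.0625)
  expect_equal(res5$statistic, 0)

  res4 <- wilcoxon_signed_rank(c(2, 3, 4, 5), c(1, 1, 1, 1))
  expect_equal(res4$p_value, 0.125)

  ## one positive and one negative of equal magnitude: p = 1
  expect_equal(wilcoxon_signed_rank(c(1, -1), c(0, 0))$p_value, 1)

  ## all-zero differences flag degeneracy
  expect_true(wilcoxon_signed_rank(c(1, 2), c(1, 2))$degenerate)

  ## tie-free cases agree with the base-R exact distribution
  set.seed(62)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    ours <- wilcoxon_signed_rank(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  ## tied absolute differences still yield a valid exact p
  tied <- wilcoxon_signed_rank(c(2, 3, 1, 5), c(1, 2, 2, 1))
  expect_gte(tied$p_value, 0)
  expect_lte(tied$p_value, 1)
})

test_that("permutation test handles constant, signal and null regimes", {
  y <- rep(0:1, each = 10)
  folds <- rep(1:2, 10)
  const <- permutation_test(function(yy) 0.5, y, folds, n_perm = 20, seed = 1)
  expect_equal(const$p_value, 1)

  ## a statistic that perfectly tracks the labels: no permutation ties it
  score_fn <- function(yy) abs(cor(yy, y))
  strong <- permutation_test(score_fn, y, folds, n_perm = 20, seed = 2)
  expect_equal(strong$p_value, 0)

  ## add-one variant never returns exactly 0
  a1 <- permutation_test(score_fn, y, folds, n_perm = 20, seed = 2, add_one = TRUE)
  expect_equal(a1$p_value, 1 / 21)

  ## calibration: for a null statistic, p is rarely small
  set.seed(63)
  x <- rnorm(20)
  small <- 0
  for (r in 1:40) {
    y_obs <- sample(y)
    stat <- function(yy) abs(mean(x[yy == 1]) - mean(x[yy == 0]))
    p <- permutation_test(stat, y_obs, folds, n_perm = 40, seed = r)$p_value
    small <- small + (p <= 0.05)
  }
  expect_lte(small, 8)  # ~5% expected, allow generous binomial slack

  expect_error(permutation_test(function(yy) 1, y, folds, n_perm = 0),
               class = "radfuse_config_error")
})

test_that("McNemar exact and chi-square branches match hand calculations", {
  y <- rep(1, 10)
  ## b = 0, c = 10: exact p = 2 * (1/2)^10
  pa <- rep(1, 10)                  # a always right
  pb <- rep(0, 10)                  # b always wrong
  res <- mcnemar_test(pb, pa, y)    # b discordant = 0, c = 10
  expect_equal(res$p_value, 2 * (0.5)^10)

  ## b = 2, c = 8: two-sided exact p = 2 * P(X <= 2), X ~ Bin(10, 1/2)
  pa2 <- c(rep(1, 8), rep(0, 2))
  pb2 <- c(rep(0, 8), rep(1, 2))
  res2 <- mcnemar_test(pa2, pb2, y)
  expect_equal(res2$p_value, 2 * pbinom(2, 10, 0.5))
  expect_equal(res2$p_value, 0.109375)

  ## b = c: symmetric, p = 1
  res3 <- mcnemar_test(c(1, 0), c(0, 1), c(1, 1))
  expect_equal(res3$p_value, 1)

  ## large discordance uses the continuity-corrected chi-square
  y2 <- rep(1, 40)
  pa4 <- c(rep(1, 30), rep(0, 10))
  pb4 <- c(rep(0, 30), rep(1, 10))
  res4 <- mcnemar_test(pa4, pb4, y2)
  ref <- mcnemar.test(matrix(c(0, 30, 10, 0), 2, 2), correct = TRUE)
  expect_equal(res4$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("the paired comparison table combines tests with family-wise correction", {
  scores <- list(
    pca_vs_plain = list(variant = c(0.66, 0.65, 0.67, 0.64, 0.66),
                        baseline = c(0.62, 0.62, 0.63, 0.61, 0.62)),
    skb_vs_plain = list(variant = c(0.63, 0.61, 0.64, 0.62, 0.61),
                        baseline = c(0.62, 0.62, 0.63, 0.61, 0.62))
  )
  tab <- paired_comparison_table(scores)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$wilcoxon_p[1], 0.0625)  # five same-sign differences
  expect_equal(tab$t_p_adjusted, p.adjust(tab$t_p, "holm"))
  expect_gt(tab$mean_gain[1], tab$mean_gain[2])
  ## table round-trips through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$t_p, tab$t_p)
})

test_that("Holm-Bonferroni reproduces the step-down rule and dominates Bonferroni", {
  hb <- holm_bonferroni(c(0.01, 0.03, 0.04), alpha = 0.05)
  expect_equal(hb$reject, c(TRUE, FALSE, FALSE))
  expect_equal(hb$adjusted, c(0.03, 0.06, 0.06))

  all1 <- holm_bonferroni(rep(1, 4))
  expect_false(any(all1$reject))
  expect_true(all(all1$adjusted == 1))

  single <- holm_bonferroni(0.049)
  expect_true(single$reject)
  expect_equal(single$adjusted, 0.049)

  set.seed(64)
  for (i in 1:20) {
    p <- runif(6)^2
    hb <- holm_bonferroni(p)
    bonf <- p.adjust(p, method = "bonferroni") <= 0.05
    expect_true(all(hb$reject[bonf]))  # Bonferroni-rejected implies Holm-rejected
  }
  expect_error(holm_bonferroni(c(0.1, 1.2)), class = "radfuse_config_error")
})
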