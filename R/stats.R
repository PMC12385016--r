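## Evaluation metrics and the statistical validation protocol.

#' Classification metrics from confusion counts
#'
#' Positive class is "lesion" (label 1). Ratios with a zero denominator are
#' reported as `NaN` (never silently 0) and flagged in the `degenerate`
#' attribute. Rates are on the 0-1 scale.
#'
#' @param tp,fp,tn,fn non-negative integer confusion counts.
#' @return A one-row tibble (class `metric_set`) with accuracy, precision,
#'   recall (sensitivity), specificity, f1, auc (`NA` here — needs scores),
#'   the counts, and the two error rates `missed_lesion_rate`
#'   (`FN / (TP + FN)`) and `mislabeled_healthy_rate` (`FP / (TN + FP)`).
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  ratio <- function(num, den) if (den > 0) num / den else NaN
  acc <- ratio(tp + tn, tp + tn + fp + fn)
  prec <- ratio(tp, tp + fp)
  rec <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  f1 <- if (is.finite(prec) && is.finite(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NaN
  out <- tibble::tibble(
    accuracy = acc, precision = prec, recall = rec, specificity = spec,
    f1 = f1, auc = NA_real_,
    tp = as.integer(tp), fp = as.integer(fp),
    tn = as.integer(tn), fn = as.integer(fn),
    missed_lesion_rate = ratio(fn, tp + fn),
    mislabeled_healthy_rate = ratio(fp, tn + fp)
  )
  structure(out, class = c("metric_set", class(out)),
            degenerate = !all(is.finite(c(acc, prec, rec, spec, f1))))
}

#' Classification metrics from predictions
#'
#' @param y_true true labels (0/1).
#' @param y_pred predicted hard labels (0/1).
#' @param y_prob optional lesion probabilities for AUC (Mann-Whitney with
#'   ties counted half).
#' @return A `metric_set` tibble, see [metrics_from_counts()].
#' @export
metrics <- function(y_true, y_pred, y_prob = NULL) {
  if (length(y_true) != length(y_pred))
    abort_config("y_true and y_pred lengths differ")
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fn <- sum(y_true == 1 & y_pred == 0)
  out <- metrics_from_counts(tp, fp, tn, fn)
  if (!is.null(y_prob)) {
    if (length(y_prob) != length(y_true)) abort_config("y_prob length differs")
    out$auc <- auc_mann_whitney(y_true, y_prob)
  }
  out
}

#' Area under the ROC curve via the Mann-Whitney statistic
#'
#' `AUC = U / (n_pos * n_neg)` with tied scores counted half. Requires both
#' classes present.
#'
#' @param y_true labels (0/1).
#' @param scores continuous scores, higher = more lesion-like.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(y_true, scores) {
  pos <- y_true == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort_config("AUC needs both classes present")
  r <- rank(scores)                      # average ranks handle ties half-count
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

paired_result <- function(kind, statistic, p_value, n_pairs, degenerate = FALSE) {
  structure(list(kind = kind, statistic = statistic, p_value = p_value,
                 n_pairs = n_pairs, degenerate = degenerate),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic=%.4g p=%.4g n=%d%s\n", x$kind, x$statistic,
              x$p_value, x$n_pairs, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Paired t-test on fold scores
#'
#' Two-sided classical paired t on the per-fold differences. Zero
#' difference variance (e.g. identical score vectors) yields a degenerate
#' result with p = 1 by convention.
#'
#' @param a,b equal-length numeric score vectors (length >= 2).
#' @return A `paired_test_result` (`statistic`, `p_value`, `n_pairs`).
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    abort_config("paired_t needs equal-length vectors of length >= 2")
  d <- a - b
  if (stats::var(d) == 0)
    return(paired_result("paired_t", 0, 1, length(a), degenerate = TRUE))
  tt <- stats::t.test(a, b, paired = TRUE)
  paired_result("paired_t", unname(tt$statistic), tt$p.value, length(a))
}

#' Wilcoxon signed-rank test with an exact small-sample null
#'
#' Zero differences are dropped; tied absolute differences receive average
#' ranks. For n <= 25 remaining pairs the two-sided p-value is computed
#' from the exact signed-rank distribution (dynamic programming over the
#' 2^n sign assignments, supporting the half-integer ranks that ties
#' produce); larger n uses the normal approximation with tie correction.
#' The reported statistic is `min(W+, W-)`.
#'
#' @param a,b equal-length numeric vectors.
#' @return A `paired_test_result`; all-zero differences give a degenerate
#'   result with p = 1.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) abort_config("length mismatch")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(paired_result("wilcoxon_signed_rank", 0, 1, 0L, degenerate = TRUE))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  if (n <= 25L) {
    p <- wilcoxon_exact_p(r, w_pos)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  paired_result("wilcoxon_signed_rank", w, p, n)
}

## Exact two-sided p for the signed-rank sum: distribution of W+ over all
## 2^n equiprobable sign patterns, via DP on doubled ranks (integers even
## with average ranks). p = 2 * min tail, capped at 1.
wilcoxon_exact_p <- function(ranks, w_pos) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1L)   # index = doubled rank sum + 1
  dist[1] <- 1
  for (rk in r2) {
    shifted <- c(numeric(rk), dist[seq_len(total + 1L - rk)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  w2 <- as.integer(round(2 * w_pos))
  lower <- sum(dist[seq_len(w2 + 1L)])
  upper <- sum(dist[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(lower, upper))
}

#' Within-fold label-permutation test of a training procedure
#'
#' Class labels are shuffled independently inside each fold and the entire
#' training-evaluation procedure is repeated; the empirical p-value is the
#' plain proportion of permutations whose score matches or exceeds the
#' observed score (so p = 0 is representable; set `add_one = TRUE` for the
#' (b+1)/(n+1) variant).
#'
#' @param run_fn function(labels) -> scalar score; must be deterministic
#'   given the labels.
#' @param y integer labels.
#' @param folds integer fold assignment, same length as `y`.
#' @param n_perm number of permutations (default 200).
#' @param seed integer seed for the shuffles.
#' @param observed optional precomputed observed score (else `run_fn(y)`).
#' @param add_one use the add-one correction.
#' @return List with `p_value`, `observed`, `null_scores`.
#' @export
permutation_test <- function(run_fn, y, folds, n_perm = 200L, seed = 1L,
                             observed = NULL, add_one = FALSE) {
  if (n_perm < 1L) abort_config("n_perm must be >= 1")
  if (length(folds) != length(y)) abort_config("folds and y lengths differ")
  if (is.null(observed)) observed <- run_fn(y)
  null_scores <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    yp <- y
    for (f in unique(folds)) {
      idx <- which(folds == f)
      yp[idx] <- sample(y[idx])
    }
    run_fn(yp)
  }, numeric(1)))
  b <- sum(null_scores >= observed)
  p <- if (add_one) (b + 1) / (n_perm + 1) else b / n_perm
  list(p_value = p, observed = observed, null_scores = null_scores)
}

#' McNemar test of prediction disagreement between two classifiers
#'
#' Discordant counts: `b` = samples classifier A gets right and B wrong,
#' `c` = the reverse. Exact binomial two-sided p when `b + c < 25`,
#' otherwise the continuity-corrected chi-square.
#'
#' @param pred_a,pred_b hard predictions from the two classifiers.
#' @param y_true true labels.
#' @return A `paired_test_result`; `statistic` is `min(b, c)` in the exact
#'   branch and the chi-square value otherwise.
#' @export
mcnemar_test <- function(pred_a, pred_b, y_true) {
  if (length(pred_a) != length(y_true) || length(pred_b) != length(y_true))
    abort_config("length mismatch")
  ra <- pred_a == y_true
  rb <- pred_b == y_true
  b <- sum(ra & !rb)
  cc <- sum(!ra & rb)
  n <- b + cc
  if (n == 0L)
    return(paired_result("mcnemar", 0, 1, 0L, degenerate = TRUE))
  if (n < 25L) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
    paired_result("mcnemar", min(b, cc), p, n)
  } else {
    chi <- (abs(b - cc) - 1)^2 / n
    paired_result("mcnemar", chi, stats::pchisq(chi, 1, lower.tail = FALSE), n)
  }
}

#' Paired comparison table across model variants
#'
#' Runs the paired t-test and the exact Wilcoxon signed-rank test on each
#' variant's fold scores against its baseline, then applies the
#' Holm-Bonferroni correction across the whole family of contrasts —
#' the layout used to report whether feature-selection variants deliver a
#' reproducible gain over a plain baseline.
#'
#' @param scores named list; each element is a list with numeric vectors
#'   `variant` and `baseline` (paired fold scores).
#' @param alpha family-wise error rate (default 0.05).
#' @return A tibble with one row per contrast: mean gain, t and Wilcoxon
#'   statistics/p-values, Holm-adjusted p-values and rejection flags.
#' @export
paired_comparison_table <- function(scores, alpha = 0.05) {
  rows <- lapply(names(scores), function(nm) {
    a <- scores[[nm]]$variant; b <- scores[[nm]]$baseline
    tt <- paired_t(a, b)
    wt <- wilcoxon_signed_rank(a, b)
    tibble::tibble(contrast = nm, n_folds = length(a),
                   mean_gain = mean(a - b),
                   t_statistic = tt$statistic, t_p = tt$p_value,
                   wilcoxon_w = wt$statistic, wilcoxon_p = wt$p_value)
  })
  out <- dplyr::bind_rows(rows)
  hb_t <- holm_bonferroni(out$t_p, alpha)
  hb_w <- holm_bonferroni(out$wilcoxon_p, alpha)
  out$t_p_adjusted <- hb_t$adjusted
  out$t_reject <- hb_t$reject
  out$wilcoxon_p_adjusted <- hb_w$adjusted
  out$wilcoxon_reject <- hb_w$reject
  out
}

#' Holm-Bonferroni step-down multiple-testing correction
#'
#' Step-down procedure controlling the family-wise error rate: p-values are
#' sorted ascending, `p_(i)` is compared with `alpha / (m - i + 1)` and the
#' procedure stops at the first failure. Adjusted p-values are the
#' max-monotone of `(m - i + 1) * p_(i)` capped at 1.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param alpha family-wise error rate (default 0.05).
#' @return A tibble with `p`, `adjusted`, `reject`, in the input order.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    abort_config("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "holm")
  tibble::tibble(p = p_values, adjusted = adj, reject = adj <= alpha)
}
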