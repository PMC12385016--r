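## Dimensionality reduction: ANOVA-F SelectKBest and PCA at a variance target.

F_SENTINEL <- 1e12   # stands in for an infinite F (zero within-class variance)

#' Per-feature ANOVA F statistics for a binary outcome
#'
#' Classic one-way ANOVA per column: between-class mean square over
#' within-class mean square (df 1 and n - 2 for two classes). Constant
#' features score 0 by convention; features with zero within-class variance
#' but non-zero separation receive a large finite sentinel (1e12) so they
#' rank first without producing infinities.
#'
#' @param X numeric matrix (samples x features).
#' @param y binary labels (0/1), length `nrow(X)`.
#' @return Numeric vector of F scores, one per feature.
#' @export
anova_f_scores <- function(X, y) {
  X <- as.matrix(X)
  cls <- sort(unique(y))
  if (length(cls) < 2L) abort_config("anova_f_scores needs two classes")
  if (any(table(y) < 2L)) abort_config("each class needs at least 2 samples")
  n <- nrow(X)
  k <- length(cls)
  gmean <- colMeans(X)
  ssb <- 0; ssw <- 0
  for (cl in cls) {
    Xi <- X[y == cl, , drop = FALSE]
    mi <- colMeans(Xi)
    ssb <- ssb + nrow(Xi) * (mi - gmean)^2
    ssw <- ssw + colSums(sweep(Xi, 2, mi)^2)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, F_SENTINEL, 0))
  unname(f)
}

#' Reduction specification
#'
#' @param kind `"none"`, `"select_k_best"` (ANOVA F filter) or `"pca"`.
#' @param k number of features kept by SelectKBest (default 100).
#' @param variance cumulative explained-variance target for PCA
#'   (default 0.95).
#' @return A `reduction_spec` list.
#' @export
reduction_spec <- function(kind = c("none", "select_k_best", "pca"),
                           k = 100L, variance = 0.95) {
  kind <- match.arg(kind)
  structure(list(kind = kind, k = as.integer(k), variance = variance),
            class = "reduction_spec")
}

#' Fit a dimensionality reduction on training data
#'
#' SelectKBest keeps exactly `min(k, n_features)` columns, ordered by
#' descending F score (with a warning if `k` exceeds the feature count).
#' PCA centers by the training mean and keeps the minimal number of leading
#' components whose cumulative explained variance reaches the target;
#' component signs are fixed so the largest-magnitude loading is positive.
#'
#' @param X training feature matrix.
#' @param y training labels (needed for SelectKBest; ignored by PCA).
#' @param spec a [reduction_spec()].
#' @return A `reduction_model`.
#' @export
fit_reduction <- function(X, y = NULL, spec = reduction_spec()) {
  X <- as.matrix(X)
  out <- list(kind = spec$kind, in_names = colnames(X))
  if (spec$kind == "select_k_best") {
    if (is.null(y)) abort_config("SelectKBest needs labels")
    f <- anova_f_scores(X, y)
    k <- spec$k
    if (k > ncol(X)) {
      warning(sprintf("k = %d exceeds %d features; clamping", k, ncol(X)))
      k <- ncol(X)
    }
    ord <- order(f, decreasing = TRUE)
    out$indices <- ord[seq_len(k)]
    out$scores <- f
  } else if (spec$kind == "pca") {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    varratio <- pc$sdev^2 / sum(pc$sdev^2)
    m <- which(cumsum(varratio) >= spec$variance - 1e-12)[1]
    if (is.na(m)) m <- length(varratio)
    rot <- pc$rotation[, seq_len(m), drop = FALSE]
    for (j in seq_len(ncol(rot))) {
      if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
    }
    out$center <- pc$center
    out$rotation <- rot
    out$explained <- varratio[seq_len(m)]
  }
  structure(out, class = "reduction_model")
}

#' Apply a fitted reduction to new data
#'
#' @param model a `reduction_model` from [fit_reduction()].
#' @param X feature matrix with the training columns.
#' @return Reduced numeric matrix.
#' @export
apply_reduction <- function(model, X) {
  X <- as.matrix(X)
  switch(model$kind,
    none = X,
    select_k_best = X[, model$indices, drop = FALSE],
    pca = {
      Z <- sweep(X, 2, model$center) %*% model$rotation
      colnames(Z) <- paste0("PC", seq_len(ncol(Z)))
      Z
    })
}

## names of the reduced feature space (for attribution labeling)
reduced_feature_names <- function(model) {
  switch(model$kind,
    none = model$in_names,
    select_k_best = model$in_names[model$indices],
    pca = paste0("PC", seq_len(ncol(model$rotation))))
}
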