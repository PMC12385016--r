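## Tree-ensemble classification with grid search and stratified k-fold CV.

#' Classifier specification with a hyperparameter grid
#'
#' Default grids cover the tuned hyperparameters of each learner: the
#' forest's number of trees and maximum depth, and the boosted model's
#' learning rate, maximum depth and minimum child weight. A depth of 0
#' means unlimited.
#'
#' @param kind `"random_forest"` or `"gradient_boosted_trees"`.
#' @param grid data frame of hyperparameter combinations; `NULL` uses the
#'   default grid.
#' @param nrounds boosting rounds (fixed, not tuned; default 100).
#' @param seed integer seed for tree growing.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("random_forest", "gradient_boosted_trees"),
                            grid = NULL, nrounds = 100L, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(grid)) {
    grid <- if (kind == "random_forest") {
      expand.grid(n_estimators = c(100L, 300L, 500L), max_depth = c(0L, 10L, 20L))
    } else {
      expand.grid(learning_rate = c(0.05, 0.1, 0.3), max_depth = c(3L, 6L),
                  min_child_weight = c(1, 5))
    }
  }
  if (nrow(grid) < 1L) abort_config("hyperparameter grid must be non-empty")
  structure(list(kind = kind, grid = grid, nrounds = as.integer(nrounds),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

## stratified fold ids, deterministic given seed
stratified_folds <- function(y, k = 5L, seed = 1L) {
  if (any(table(y) < k)) abort_config(sprintf("each class needs >= %d samples for %d folds", k, k))
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  folds
}

## Fit one reduction + classifier on training rows.
fit_pipeline <- function(X, y, spec, params, reduction = reduction_spec("none")) {
  X <- as.matrix(X)
  red <- fit_reduction(X, y, reduction)
  Z <- apply_reduction(red, X)
  colnames(Z) <- sanitize_names(reduced_feature_names(red))
  model <- if (spec$kind == "random_forest") {
    ranger::ranger(
      x = as.data.frame(Z), y = factor(y, levels = c(0, 1)),
      num.trees = params$n_estimators,
      max.depth = params$max_depth,
      probability = TRUE, seed = spec$seed, num.threads = 1
    )
  } else {
    dtrain <- xgboost::xgb.DMatrix(Z, label = y)
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = params$learning_rate,
                    max_depth = params$max_depth,
                    min_child_weight = params$min_child_weight,
                    base_score = 0.5, nthread = 1, seed = spec$seed),
      data = dtrain, nrounds = spec$nrounds, verbose = 0
    )
  }
  structure(list(reduction = red, model = model, kind = spec$kind,
                 params = params, nrounds = spec$nrounds,
                 feature_names = colnames(Z), seed = spec$seed,
                 train_X = Z, train_y = y),
            class = "fusion_pipeline")
}

sanitize_names <- function(nm) make.names(nm, unique = TRUE)

#' @rdname predict_proba
#' @param X feature matrix in the original (pre-reduction) space
#'   (pipeline method).
#' @export
predict_proba.fusion_pipeline <- function(object, X, ...) {
  Z <- apply_reduction(object$reduction, as.matrix(X))
  colnames(Z) <- object$feature_names
  if (object$kind == "random_forest") {
    pr <- predict(object$model, data = as.data.frame(Z), num.threads = 1)$predictions
    if ("1" %in% colnames(pr)) unname(pr[, "1"]) else rep(0, nrow(pr))
  } else {
    unname(predict(object$model, xgboost::xgb.DMatrix(Z)))
  }
}

#' Grid-search hyperparameters under stratified k-fold cross-validation
#'
#' The reduction is refit inside every training fold (no leakage into held
#' out folds). The best hyperparameter combination maximizes the mean fold
#' score; ties are broken toward the simpler model (fewer trees / smaller
#' learning budget, then shallower), then by grid order. The winning
#' configuration is refit on all rows to produce the returned pipeline.
#'
#' For test-time-augmentation protocols pass `X_infer`: training folds are
#' always taken from `X`, while held-out rows are scored from `X_infer`
#' (e.g. TTA-averaged features).
#'
#' @param X feature matrix (samples x features).
#' @param y binary labels (0/1).
#' @param spec a [classifier_spec()].
#' @param reduction a [reduction_spec()].
#' @param folds number of folds (default 5) or a precomputed integer fold
#'   assignment.
#' @param seed integer seed controlling fold assignment.
#' @param metric model-selection metric, `"accuracy"` (default) or `"auc"`.
#' @param X_infer optional matrix like `X` used for scoring held-out rows.
#' @return A `cv_result`: per-fold metrics for the best configuration, the
#'   grid summary, chosen hyperparameters, fold assignment and the fitted
#'   `fusion_pipeline`.
#' @export
grid_search_cv <- function(X, y, spec = classifier_spec(),
                           reduction = reduction_spec("none"),
                           folds = 5L, seed = 1L,
                           metric = c("accuracy", "auc"), X_infer = NULL) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) abort_config("labels must contain both classes")
  fold_id <- if (length(folds) == length(y)) as.integer(folds)
             else stratified_folds(y, folds, seed)
  k <- max(fold_id)
  if (is.null(X_infer)) X_infer <- X
  grid <- spec$grid
  mean_scores <- numeric(nrow(grid))
  fold_cache <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    per_fold <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- fold_id != f
      pipe <- fit_pipeline(X[tr, , drop = FALSE], y[tr], spec, params, reduction)
      prob <- predict_proba(pipe, X_infer[!tr, , drop = FALSE])
      per_fold[[f]] <- metrics(y[!tr], as.integer(prob >= 0.5), prob)
    }
    fm <- dplyr::bind_rows(per_fold)
    fold_cache[[g]] <- fm
    mean_scores[g] <- mean(fm[[metric]])
  }
  best_score <- max(mean_scores)
  cand <- which(abs(mean_scores - best_score) < 1e-12)
  if (length(cand) > 1L) cand <- cand[order(complexity_key(spec, grid[cand, , drop = FALSE]))]
  best <- cand[1]
  best_params <- as.list(grid[best, , drop = FALSE])
  fold_metrics <- dplyr::mutate(fold_cache[[best]], fold = dplyr::row_number(),
                                .before = 1)
  pipeline <- fit_pipeline(X, y, spec, best_params, reduction)
  structure(
    list(fold_metrics = fold_metrics,
         grid_summary = dplyr::mutate(tibble::as_tibble(grid), mean_score = mean_scores),
         best_params = best_params, metric = metric,
         fold_assignment = fold_id, seed = seed,
         reduction = reduction, spec = spec, pipeline = pipeline),
    class = "cv_result"
  )
}

## lexicographic simplicity: fewer/slower trees first, then shallower
## (depth 0 = unlimited counts as deepest)
complexity_key <- function(spec, grid_rows) {
  if (spec$kind == "random_forest") {
    depth <- ifelse(grid_rows$max_depth == 0L, .Machine$integer.max, grid_rows$max_depth)
    order(grid_rows$n_estimators, depth)
  } else {
    order(grid_rows$learning_rate, grid_rows$max_depth, grid_rows$min_child_weight)
  }
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, best by %s = %.4f\n",
              nrow(x$fold_metrics), x$metric,
              mean(x$fold_metrics[[x$metric]])))
  cat("  params:", paste(names(x$best_params), unlist(x$best_params),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}
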