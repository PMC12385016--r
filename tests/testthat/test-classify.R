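rf_spec_small <- function(seed = 1L)
  classifier_spec("random_forest",
                  grid = data.frame(n_estimators = 60L, max_depth = 0L),
                  seed = seed)

test_that("stratified folds are disjoint, exhaustive and balanced", {
  y <- rep(c(0L, 1L), c(23, 27))
  f <- radfuse:::stratified_folds(y, k = 5, seed = 2)
  expect_setequal(unique(f), 1:5)
  for (k in 1:5) {
    expect_true(abs(sum(y[f == k] == 1) - 27 / 5) <= 1)
  }
  expect_identical(f, radfuse:::stratified_folds(y, 5, seed = 2))
})

test_that("cross-validated accuracy is chance on null data and perfect with leakage", {
  set.seed(51)
  n <- 80
  y <- rep(0:1, each = n / 2)
  Xnull <- matrix(rnorm(n * 10), n, 10)
  cv <- grid_search_cv(Xnull, y, rf_spec_small(), seed = 3)
  ci <- 1.96 * sqrt(0.25 / n)
  expect_lte(abs(mean(cv$fold_metrics$accuracy) - 0.5), ci + 0.06)

  Xleak <- cbind(Xnull, leak = y + rnorm(n, sd = 1e-4))
  cv2 <- grid_search_cv(Xleak, y, rf_spec_small(), seed = 3)
  expect_gte(mean(cv2$fold_metrics$accuracy), 0.99)
})

test_that("grid search is deterministic and refits reductions inside folds", {
  d <- fix_feature_data(n = 60, p = 12, effect = 1.5, seed = 15)
  run <- function() grid_search_cv(d$X, d$y, rf_spec_small(),
                                   reduction = reduction_spec("select_k_best", k = 5),
                                   seed = 7)
  a <- run(); b <- run()
  expect_identical(a$fold_metrics, b$fold_metrics)
  expect_identical(a$fold_assignment, b$fold_assignment)
  expect_identical(a$best_params, b$best_params)
})

test_that("fitted reduction and model depend only on training folds (no leakage)", {
  d <- fix_feature_data(n = 60, p = 12, effect = 1.5, seed = 16)
  folds <- radfuse:::stratified_folds(d$y, 5, seed = 1)
  tr <- folds != 1
  spec <- rf_spec_small()
  params <- list(n_estimators = 60L, max_depth = 0L)
  p1 <- radfuse:::fit_pipeline(d$X[tr, ], d$y[tr], spec, params,
                               reduction_spec("select_k_best", k = 5))
  y_shuffled <- d$y
  y_shuffled[!tr] <- rev(d$y[!tr])
  p2 <- radfuse:::fit_pipeline(d$X[tr, ], y_shuffled[tr], spec, params,
                               reduction_spec("select_k_best", k = 5))
  expect_identical(p1$reduction$indices, p2$reduction$indices)
  expect_identical(predict_proba(p1, d$X), predict_proba(p2, d$X))
})

test_that("predicted probabilities are valid and stable under duplication", {
  d <- fix_feature_data(n = 60, p = 8, effect = 1.5, seed = 17)
  cv <- grid_search_cv(d$X, d$y, rf_spec_small(), seed = 5)
  p <- predict_proba(cv$pipeline, d$X)
  expect_true(all(p >= 0 & p <= 1))
  pdup <- predict_proba(cv$pipeline, d$X[c(1, 1, 2), ])
  expect_equal(pdup[1], pdup[2])
  expect_equal(pdup[1], p[1])
})

test_that("gradient-boosted pipelines train, predict and cross-validate", {
  d <- fix_feature_data(n = 60, p = 8, effect = 2, seed = 18)
  spec <- classifier_spec("gradient_boosted_trees",
                          grid = data.frame(learning_rate = 0.3, max_depth = 3L,
                                            min_child_weight = 1),
                          nrounds = 30L, seed = 2)
  cv <- grid_search_cv(d$X, d$y, spec, seed = 9)
  expect_gte(mean(cv$fold_metrics$accuracy), 0.8)
  expect_true(all(predict_proba(cv$pipeline, d$X) >= 0))
})

test_that("hyperparameter ties break toward the simpler model", {
  d <- fix_feature_data(n = 40, p = 4, effect = 4, seed = 19)
  ## easy data: every config scores 1.0; the smaller forest must win
  spec <- classifier_spec("random_forest",
                          grid = data.frame(n_estimators = c(500L, 50L),
                                            max_depth = c(0L, 5L)),
                          seed = 1)
  cv <- grid_search_cv(d$X, d$y, spec, seed = 4)
  if (abs(diff(cv$grid_summary$mean_score)) < 1e-12) {
    expect_equal(cv$best_params$n_estimators, 50L)
  }
  ## tidy/glance round out the result surface
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(nrow(glance(cv)), 1)
})
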