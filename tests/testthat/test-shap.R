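## hand-built unified trees for the exact cases
stump_tree <- function() list(
  feature = c(2L, NA, NA), split = c(0.5, NA, NA),
  yes = c(2L, NA, NA), no = c(3L, NA, NA),
  cover = c(10, 4, 6), value = c(NA, 1, 5), rule = "lt")

and_tree <- function() list(
  ## symmetric AND of features 1 and 2, uniform cover
  feature = c(1L, NA, 2L, NA, NA), split = c(0.5, NA, 0.5, NA, NA),
  yes = c(2L, NA, 4L, NA, NA), no = c(3L, NA, 5L, NA, NA),
  cover = c(4, 2, 2, 1, 1), value = c(NA, 0, NA, 0, 1), rule = "lt")

test_that("a single-split stump puts all attribution on its feature", {
  tree <- stump_tree()
  phi <- radfuse:::treeshap_one(tree, c(9, 0.9, -1), 3)
  expect_equal(phi[c(1, 3)], c(0, 0))
  ## v(empty) = 0.4*1 + 0.6*5 = 3.4; f(x) = 5
  expect_equal(phi[2], 5 - 3.4)
  expect_equal(phi, shapley_brute_force(tree, c(9, 0.9, -1), 3))
})

test_that("a symmetric AND tree attributes equally by the symmetry axiom", {
  tree <- and_tree()
  phi <- radfuse:::treeshap_one(tree, c(0.9, 0.9), 2)
  expect_equal(phi[1], phi[2])
  expect_equal(sum(phi), 1 - radfuse:::tree_expectation(tree))
})

test_that("polynomial TreeSHAP equals subset-enumeration Shapley on small trees", {
  ## the spec's depth-2, 3-feature case plus randomized fuzz
  set.seed(71)
  for (i in 1:50) {
    l4 <- runif(4, 0.5, 4)
    tree <- list(
      feature = c(sample(3L, 3, replace = TRUE), NA, NA, NA, NA),
      split = c(rnorm(3), NA, NA, NA, NA),
      yes = c(2L, 4L, 6L, NA, NA, NA, NA),
      no = c(3L, 5L, 7L, NA, NA, NA, NA),
      cover = c(sum(l4), l4[1] + l4[2], l4[3] + l4[4], l4),
      value = c(NA, NA, NA, rnorm(4)), rule = "lt")
    x <- rnorm(3)
    expect_equal(radfuse:::treeshap_one(tree, x, 3),
                 shapley_brute_force(tree, x, 3), tolerance = 1e-9)
  }
})

test_that("random forest attributions satisfy local accuracy and missingness", {
  d <- fix_feature_data(n = 80, p = 6, effect = 1.5, seed = 23)
  X <- cbind(d$X, dead = rnorm(80) * 0)   # constant feature: never split on
  spec <- classifier_spec("random_forest",
                          grid = data.frame(n_estimators = 40L, max_depth = 4L),
                          seed = 5)
  pipe <- radfuse:::fit_pipeline(X, d$y, spec,
                                 list(n_estimators = 40L, max_depth = 4L))
  at <- tree_shapley(pipe, X[1:20, ])
  expect_equal(at$scale, "probability")
  gap <- abs(at$base_value + rowSums(at$values) - at$output)
  expect_lt(max(gap), 1e-6)
  expect_true(all(at$values[, "dead"] == 0))

  ## additivity: attribution sums track output differences between samples
  diffs <- outer(at$output, at$output, "-")
  sums <- outer(rowSums(at$values), rowSums(at$values), "-")
  expect_equal(diffs, sums, tolerance = 1e-9)
})

test_that("boosted-tree attributions match xgboost's own TreeSHAP", {
  d <- fix_feature_data(n = 80, p = 6, effect = 1.5, seed = 24)
  spec <- classifier_spec("gradient_boosted_trees",
                          grid = data.frame(learning_rate = 0.3, max_depth = 3L,
                                            min_child_weight = 1),
                          nrounds = 25L, seed = 5)
  pipe <- radfuse:::fit_pipeline(d$X, d$y, spec,
                                 list(learning_rate = 0.3, max_depth = 3L,
                                      min_child_weight = 1))
  at <- tree_shapley(pipe, d$X)
  expect_equal(at$scale, "margin")
  expect_lt(max(abs(at$base_value + rowSums(at$values) - at$output)), 1e-6)

  Z <- d$X; colnames(Z) <- pipe$feature_names
  pc <- predict(pipe$model, xgboost::xgb.DMatrix(Z), predcontrib = TRUE)
  expect_lt(max(abs(pc[, 1:6] - at$values)), 1e-5)
  expect_lt(abs(pc[1, 7] - at$base_value), 1e-5)
})

test_that("attribution requires a tree-ensemble pipeline", {
  fake <- structure(list(kind = "svm"), class = "fusion_pipeline")
  expect_error(tree_shapley(fake, matrix(0, 1, 1)),
               class = "radfuse_unsupported_model_error")
})

test_that("explanation bundles expose probability, QC and sorted attributions", {
  d <- fix_feature_data(n = 60, p = 5, effect = 1.5, seed = 25)
  spec <- classifier_spec("random_forest",
                          grid = data.frame(n_estimators = 30L, max_depth = 4L),
                          seed = 2)
  pipe <- radfuse:::fit_pipeline(d$X, d$y, spec,
                                 list(n_estimators = 30L, max_depth = 4L))
  at <- tree_shapley(pipe, d$X[1:3, ], ids = c("a", "b", "c"))
  msk <- matrix(0L, 16, 16); msk[4:12, 4:12] <- 1L
  bundle <- explanation_bundle(fix_sample(16, 1, id = "a"), fix_saliency(msk),
                               at, index = 1, top_k = 3)
  expect_gte(bundle$probability, 0)
  expect_lte(bundle$probability, 1)
  v <- abs(bundle$top_attributions$value)
  expect_true(all(diff(v) <= 1e-12))
  expect_equal(nrow(bundle$top_attributions), 3)

  ## lossless JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  bundle_to_json(bundle, path)
  back <- bundle_from_json(path)
  expect_equal(back$probability, bundle$probability)
  expect_equal(back$top_attributions$value, bundle$top_attributions$value)
  expect_equal(back$qc$reliable, bundle$qc$reliable)
})
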