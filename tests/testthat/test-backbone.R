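test_that("seeded initialization and embedding are deterministic", {
  a <- build_test_backbone(seed = 3, side = 16, conv_channels = 8)
  b <- build_test_backbone(seed = 3, side = 16, conv_channels = 8)
  expect_identical(a$weights, b$weights)
  img <- fix_image(16, 1)
  expect_identical(embed(a, img), embed(a, img))
  ## batches preserve order and length
  imgs <- lapply(1:4, fix_image, side = 16)
  E <- embed(a, imgs)
  expect_equal(dim(E), c(4L, 8L))
  expect_equal(E[2, ], embed(a, imgs[[2]])[1, ])
})

test_that("zero weights force a zero embedding through ReLU", {
  bb <- build_test_backbone(seed = 1, side = 16, conv_channels = 8)
  bb$weights <- lapply(bb$weights, function(w) w * 0)
  expect_true(all(embed(bb, fix_image(16, 2)) == 0))
  tr <- trace_conv(bb, fix_image(16, 2), target_class = 1)
  expect_true(all(tr$gradients == 0))
})

test_that("trace_conv gradients are exact for the GAP-linear head", {
  bb <- build_test_backbone(seed = 5, side = 16, conv_channels = 6)
  img <- fix_image(16, 3)
  tr <- trace_conv(bb, img, target_class = 1)
  h <- dim(tr$activations)[1]; w <- dim(tr$activations)[2]
  ## analytic: d logit_1 / dA[i,j,k] = Wd[k, 2] / (h*w), constant per channel
  for (k in 1:6)
    expect_equal(unique(as.vector(tr$gradients[, , k])),
                 bb$weights$Wd[k, 2] / (h * w))
  ## finite-difference oracle on the head: y = colMeans(A) %*% Wd + bd
  logit_of <- function(A) (apply(A, 3, mean) %*% bb$weights$Wd + bb$weights$bd)[2]
  eps <- 1e-5
  for (cell in list(c(1, 1, 1), c(2, 3, 2), c(4, 4, 6))) {
    Ap <- tr$activations; Ap[cell[1], cell[2], cell[3]] <- Ap[cell[1], cell[2], cell[3]] + eps
    Am <- tr$activations; Am[cell[1], cell[2], cell[3]] <- Am[cell[1], cell[2], cell[3]] - eps
    num <- (logit_of(Ap) - logit_of(Am)) / (2 * eps)
    expect_equal(num, tr$gradients[cell[1], cell[2], cell[3]], tolerance = 1e-4)
  }
})

test_that("full backward pass matches finite differences", {
  bb <- build_test_backbone(seed = 2, side = 8, conv_channels = 4)
  img <- fix_image(8, 4)
  loss_fn <- function(b) {
    p <- radfuse:::softmax2(radfuse:::cnn_forward(b, img)$logits)
    -log(p[2])
  }
  fw <- radfuse:::cnn_forward(bb, img, keep = TRUE)
  p <- radfuse:::softmax2(fw$logits)
  dlog <- p; dlog[2] <- dlog[2] - 1
  g <- radfuse:::cnn_backward(bb, fw, dlog)
  eps <- 1e-6
  set.seed(8)
  for (nm in names(bb$weights)) {
    ii <- sample(length(bb$weights[[nm]]), min(3, length(bb$weights[[nm]])))
    for (i in ii) {
      bp <- bb; bp$weights[[nm]][i] <- bp$weights[[nm]][i] + eps
      bm <- bb; bm$weights[[nm]][i] <- bm$weights[[nm]][i] - eps
      num <- (loss_fn(bp) - loss_fn(bm)) / (2 * eps)
      expect_equal(num, g[[nm]][i], tolerance = 1e-4)
    }
  }
})

test_that("an untrained backbone scores at chance on balanced data", {
  ds <- generate_dataset(synthetic_config(n_images = 40, lesion_fraction = 0.5,
                                          image_size = 32, seed = 7))
  bb <- build_test_backbone(seed = 9, side = 32, conv_channels = 8)
  p <- predict_proba(bb, ds)
  acc <- mean((p >= 0.5) == (sample_labels(ds) == 1))
  ci <- 1.96 * sqrt(0.25 / 40)
  expect_lte(abs(acc - 0.5), ci + 1e-9)
})

test_that("short training on an easy set lifts validation accuracy above 0.8", {
  ds <- generate_dataset(synthetic_config(n_images = 70, image_size = 32,
                                          lesion_fraction = 0.5, seed = 21))
  labs <- sample_labels(ds)
  tr <- ds[c(which(labs == 1)[1:25], which(labs == 0)[1:25])]
  va <- ds[c(which(labs == 1)[26:35], which(labs == 0)[26:35])]
  bb <- build_test_backbone(seed = 1, side = 32, conv_channels = 16)
  ## patience equals the budget: the from-scratch loss plateaus before the
  ## localized signal is found, so stopping early would freeze a chance model
  bb <- train_backbone(bb, tr, val_samples = va, epochs = 60, patience = 60,
                       seed = 13)
  pv <- predict_proba(bb, va)
  acc <- mean((pv >= 0.5) == (sample_labels(va) == 1))
  expect_gt(acc, 0.8)
})

test_that("adapter contract errors are typed", {
  ad <- mock_adapter(side = 16)
  expect_error(trace_conv(ad, fix_image(16, 1)),
               class = "radfuse_capability_error")
  expect_error(embed(ad, fix_image(8, 1)), regexp = "resize")
  ## a custom adapter satisfies embed/predict
  expect_length(predict_proba(ad, fix_image(16, 1)), 1)
  expect_equal(ncol(embed(ad, fix_image(16, 1))), 4)
})
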