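## Shared fixtures, built in code at load time.

## deterministic pixel matrix in [0,1]
fix_image <- function(side = 16L, seed = 1L) {
  set.seed(seed)
  matrix(runif(side * side), side, side)
}

fix_sample <- function(side = 16L, seed = 1L, label = 1L, id = "fix") {
  radiograph_sample(id, fix_image(side, seed), label)
}

## random binary mask with at least `min_fg` foreground pixels
fix_mask <- function(side = 8L, seed = 1L, p = 0.6, min_fg = 2L) {
  set.seed(seed)
  repeat {
    m <- matrix(as.integer(runif(side * side) < p), side, side)
    if (sum(m) >= min_fg) return(m)
  }
}

## mock adapter whose embedding is a fixed linear readout of the pixels,
## with a hand-settable saliency trace
mock_adapter <- function(side = 16L, dim = 4L, seed = 7L,
                         trace_maker = NULL) {
  set.seed(seed)
  W <- matrix(rnorm(side * side * dim), side * side, dim)
  backbone_adapter(
    name = "mock", embedding_dim = dim, input_side = side,
    embed_fn = function(img) as.numeric(crossprod(W, as.vector(img))),
    trace_fn = trace_maker,
    predict_fn = function(img) 1 / (1 + exp(-sum(img - 0.5)))
  )
}

## saliency_result with a given mask (reliable unless forced otherwise)
fix_saliency <- function(mask, reliable = NULL) {
  qc <- mask_qc(mask)
  if (!is.null(reliable)) qc$reliable <- reliable
  hm <- mask * 1.0
  structure(list(heatmap = hm, mask = mask, qc = qc, threshold = 0.5,
                 target_class = 1L), class = "saliency_result")
}

## small labeled feature matrix with a planted informative column
fix_feature_data <- function(n = 60L, p = 10L, effect = 2, seed = 3L) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  X[, 1] <- X[, 1] + effect * y
  list(X = X, y = y)
}
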