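test_that("tta_views are deterministic, identity-first, and distinct on asymmetric input", {
  s <- fix_sample(16, 12)
  expect_length(tta_views(s, tta_policy(1)), 1)
  expect_identical(tta_views(s, tta_policy(1))[[1]], s$pixels)

  v5 <- tta_views(s, tta_policy(5))
  expect_length(v5, 5)
  for (i in 2:5) for (j in seq_len(i - 1))
    expect_false(isTRUE(all.equal(v5[[i]], v5[[j]])))

  ## a symmetric image: flips are exactly invariant, rotations invariant up
  ## to interpolation error on a smooth radial blob over black background
  ctr <- (16 + 1) / 2
  d2 <- outer(1:16, 1:16, function(r, c) (r - ctr)^2 + (c - ctr)^2)
  blob <- radiograph_sample("b", 0.8 * exp(-d2 / 8), 0)
  vb <- tta_views(blob, tta_policy(5))
  expect_equal(vb[[2]], vb[[1]], tolerance = 1e-12)   # hflip
  expect_equal(vb[[3]], vb[[1]], tolerance = 1e-12)   # vflip
  expect_lt(max(abs(vb[[4]] - vb[[1]])), 0.02)        # +10 deg
  expect_lt(max(abs(vb[[5]] - vb[[1]])), 0.02)        # -10 deg

  expect_error(tta_policy(0), class = "radfuse_config_error")
  expect_error(tta_policy(6), class = "radfuse_config_error")
})

test_that("fuse averages embeddings over views and takes radiomics from the original", {
  msk <- matrix(0L, 16, 16); msk[5:12, 5:12] <- 1L
  sal <- fix_saliency(msk)
  s <- fix_sample(16, 13)

  ad <- mock_adapter(side = 16)
  f1 <- fuse(s, ad, sal, tta_policy(1))
  expect_equal(unname(f1[1:4]), as.numeric(embed(ad, s)))
  expect_length(f1, 4 + 87)
  expect_identical(names(f1)[5:91], radiomic_feature_names())

  ## constant-output adapter: TTA mean equals single view
  flat <- backbone_adapter("flat", 3, 16, embed_fn = function(img) c(1, 2, 3),
                           predict_fn = function(img) 0.5)
  expect_equal(unname(fuse(s, flat, sal, tta_policy(5))[1:3]), c(1, 2, 3))

  ## two hand-set embeddings average to (e1 + e2) / 2
  counter <- new.env(); counter$i <- 0
  stub <- backbone_adapter("stub", 2, 16, embed_fn = function(img) {
    counter$i <- counter$i + 1
    if (counter$i == 1) c(1, 10) else c(3, 20)
  })
  f2 <- fuse(s, stub, sal, tta_policy(2))
  expect_equal(unname(f2[1:2]), c(2, 15))

  ## radiomic block identical regardless of TTA (mask from the original)
  expect_equal(unname(f1[5:91]),
               unname(fuse(s, ad, sal, tta_policy(5))[5:91]))

  ## bit-for-bit reproducibility
  expect_identical(fuse(s, ad, sal, tta_policy(5)),
                   fuse(s, ad, sal, tta_policy(5)))
})

test_that("ensemble concatenation preserves blocks, order and identity", {
  msk <- matrix(0L, 16, 16); msk[5:12, 5:12] <- 1L
  sal <- fix_saliency(msk)
  s <- fix_sample(16, 14)
  a <- fuse(s, mock_adapter(16, dim = 4, seed = 1), sal, tta_policy(1))
  b <- fuse(s, mock_adapter(16, dim = 6, seed = 2), sal, tta_policy(1))
  attr(b, "backbone") <- "mock2"
  ab <- ensemble_concat(a, b)
  expect_length(ab, length(a) + length(b))
  expect_equal(unname(ab[seq_along(a)]), unname(as.numeric(a)))
  ba <- ensemble_concat(b, a)
  expect_equal(unname(ba[seq_along(b)]), unname(as.numeric(b)))

  s2 <- fix_sample(16, 15, id = "other")
  b2 <- fuse(s2, mock_adapter(16, dim = 6, seed = 2), sal, tta_policy(1))
  expect_error(ensemble_concat(a, b2), regexp = "mismatch")
  expect_warning(ensemble_concat(a, a), regexp = "itself")
})

test_that("fuse_dataset applies TTA only to the requested ids", {
  msk <- matrix(0L, 16, 16); msk[5:12, 5:12] <- 1L
  trace_maker <- function(img, target_class)
    conv_trace(array(img[seq(1, 16, 4), seq(1, 16, 4)], c(4, 4, 1)),
               array(1, c(4, 4, 1)))
  ad <- mock_adapter(16, trace_maker = trace_maker)
  ds <- list(fix_sample(16, 1, id = "s1"), fix_sample(16, 2, id = "s2"))
  fd_none <- fuse_dataset(ds, ad, policy = tta_policy(5), tta_ids = NULL)
  fd_one <- fuse_dataset(ds, ad, policy = tta_policy(5), tta_ids = "s2")
  emb_cols <- paste0("emb_", 1:4)
  expect_equal(fd_none$features[1, emb_cols], fd_one$features[1, emb_cols])
  expect_false(isTRUE(all.equal(fd_none$features[2, emb_cols],
                                fd_one$features[2, emb_cols])))
})
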