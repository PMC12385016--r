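test_that("discretization follows the fixed-bin-width formula", {
  px <- matrix(c(0.0, 0.1, 0.2, 0.05), 2, 2)
  roi <- discretize(px, matrix(1L, 2, 2), bin_width = 0.1)
  expect_equal(sort(unique(roi$levels[roi$mask])), c(1L, 2L, 3L))
  expect_equal(roi$n_levels, 3)

  const <- discretize(matrix(0.4, 3, 3), matrix(1L, 3, 3), 0.1)
  expect_equal(const$n_levels, 1)
  wide <- discretize(px, matrix(1L, 2, 2), bin_width = 0.5)
  expect_equal(wide$n_levels, 1)

  expect_error(discretize(px, matrix(0L, 2, 2), 0.1),
               class = "radfuse_empty_roi_error")
})

test_that("first-order features match direct formulas and conventions", {
  x <- c(1, 2, 3) / 3
  roi <- discretize(matrix(x, 1, 3), matrix(1L, 1, 3), 0.098)
  fo <- first_order(roi)
  expect_equal(unname(fo["fo_mean"]), mean(x))
  expect_equal(unname(fo["fo_variance"]), mean((x - mean(x))^2))  # population
  expect_equal(unname(fo["fo_range"]), 2 / 3)

  ## symmetric values have zero skewness
  sym <- c(0.1, 0.5, 0.9)
  fos <- first_order(discretize(matrix(sym, 1, 3), matrix(1L, 1, 3), 0.05))
  expect_equal(unname(fos["fo_skewness"]), 0)

  ## constant ROI conventions
  foc <- first_order(discretize(matrix(0.3, 2, 2), matrix(1L, 2, 2), 0.1))
  expect_equal(unname(foc["fo_variance"]), 0)
  expect_equal(unname(foc["fo_entropy"]), 0)
  expect_equal(unname(foc["fo_uniformity"]), 1)

  ## random ROIs agree with direct formulas to 1e-12
  for (seed in 1:10) {
    r <- oracle_random_roi(seed)
    f <- first_order(r$roi)
    v <- r$pixels[r$mask == 1]
    expect_equal(unname(f["fo_mean"]), mean(v), tolerance = 1e-12)
    expect_equal(unname(f["fo_variance"]), mean((v - mean(v))^2), tolerance = 1e-12)
    m2 <- mean((v - mean(v))^2)
    if (m2 > 0)
      expect_equal(unname(f["fo_skewness"]), mean((v - mean(v))^3) / m2^1.5,
                   tolerance = 1e-12)
    expect_equal(unname(f["fo_energy"]), sum(v^2), tolerance = 1e-12)
    expect_equal(unname(f["fo_rms"]), sqrt(mean(v^2)), tolerance = 1e-12)
  }
})

test_that("GLCM counts and features match enumeration on tiny grids", {
  ## [[1,1],[2,2]]: horizontal pairs stay within rows -> zero contrast
  px <- matrix(c(0, 0, 0.15, 0.15), 2, 2, byrow = TRUE)
  roi <- discretize(px, matrix(1L, 2, 2), 0.1)
  g0 <- glcm(roi, angles = 0)
  expect_equal(g0$matrices[[1]],
               matrix(c(2, 0, 0, 2), 2, 2))
  expect_equal(unname(g0$features["glcm_contrast"]), 0)
  expect_equal(unname(g0$features["glcm_maximum_probability"]), 0.5)

  g90 <- glcm(roi, angles = 90)
  expect_equal(unname(g90$features["glcm_contrast"]), 1)

  ## constant grid: single cell with probability 1
  cst <- discretize(matrix(0.5, 3, 3), matrix(1L, 3, 3), 0.1)
  gc <- glcm(cst, angles = c(0, 45, 90, 135))
  expect_equal(unname(gc$features["glcm_maximum_probability"]), 1)
  expect_equal(unname(gc$features["glcm_joint_entropy"]), 0)
  expect_equal(unname(gc$features["glcm_correlation"]), 1)  # degenerate convention
})

test_that("GLRLM runs match hand enumeration", {
  roi <- discretize(matrix(c(0, 0, 0.15), 1, 3), matrix(1L, 1, 3), 0.1)
  r0 <- glrlm(roi, angles = 0)
  R <- r0$matrices[[1]]
  expect_equal(R[1, 2], 1)  # level 1, run length 2
  expect_equal(R[2, 1], 1)  # level 2, run length 1
  expect_equal(unname(r0$features["glrlm_rp"]), 2 / 3)

  const4 <- discretize(matrix(0.5, 1, 4), matrix(1L, 1, 4), 0.1)
  expect_equal(unname(glrlm(const4, angles = 0)$features["glrlm_lre"]), 16)

  distinct <- discretize(matrix(c(0.05, 0.25, 0.45, 0.65), 1, 4),
                         matrix(1L, 1, 4), 0.1)
  expect_equal(unname(glrlm(distinct, angles = 0)$features["glrlm_sre"]), 1)
})

test_that("GLDM dependence counts match the neighbor geometry", {
  cst <- discretize(matrix(0.5, 3, 3), matrix(1L, 3, 3), 0.1)
  P <- gldm(cst, alpha = 0, distance = 1)$matrix
  ## center 8 neighbors, edges 5, corners 3
  expect_equal(P[1, 9], 1)  # dependence 8 -> column 9
  expect_equal(P[1, 6], 4)  # four edge pixels with 5 dependent neighbors
  expect_equal(P[1, 4], 4)  # four corners with 3

  single <- discretize(matrix(0.2, 1, 1), matrix(1L, 1, 1), 0.1)
  Ps <- gldm(single, alpha = 0, distance = 1)$matrix
  expect_equal(Ps[1, 1], 1)  # dependence 0

  ## alpha saturation: every in-mask neighbor counts
  r <- oracle_random_roi(3)
  big_alpha <- gldm(r$roi, alpha = r$roi$n_levels, distance = 1)$matrix
  expect_equal(big_alpha, oracle_gldm(r$roi$levels, alpha = r$roi$n_levels))
})

test_that("NGTDM table matches 3-pixel hand enumeration and degenerate caps", {
  roi <- discretize(matrix(c(0, 0.15, 0), 1, 3), matrix(1L, 1, 3), 0.1)
  out <- ngtdm(roi, distance = 1)
  ## s(level 2) = |2 - mean(1,1)| = 1 ; s(level 1) = |1-2| + |1-2| = 2
  expect_equal(out$table$s, c(2, 1))
  expect_equal(out$table$n, c(2, 1))

  cst <- ngtdm(discretize(matrix(0.5, 3, 3), matrix(1L, 3, 3), 0.1))
  expect_equal(unname(cst$features["ngtdm_contrast"]), 0)
  expect_equal(unname(cst$features["ngtdm_coarseness"]), 1e6)

  single <- ngtdm(discretize(matrix(0.2, 1, 1), matrix(1L, 1, 1), 0.1))
  expect_equal(unname(single$features["ngtdm_coarseness"]), 1e6)
  expect_equal(unname(single$features["ngtdm_busyness"]), 0)
})

test_that("texture matrices equal brute-force enumeration on random masked grids", {
  for (seed in 1:40) {
    r <- oracle_random_roi(seed)
    lev <- r$roi$levels
    for (ang in c(0, 45, 90, 135)) {
      expect_equal(glcm(r$roi, angles = ang)$matrices[[1]],
                   oracle_glcm(lev, ang, ng = r$roi$n_levels))
      expect_equal(glrlm(r$roi, angles = ang)$matrices[[1]],
                   oracle_glrlm(lev, ang))
    }
    expect_equal(gldm(r$roi)$matrix, oracle_gldm(lev))
    o <- oracle_ngtdm(lev)
    tab <- ngtdm(r$roi)$table
    expect_equal(tab$n, o$n)
    expect_equal(tab$s, o$s, tolerance = 1e-12)
  }
})

test_that("features ignore everything outside the mask (fuzz)", {
  set.seed(31)
  for (i in 1:10) {
    px <- matrix(runif(64), 8, 8)
    msk <- fix_mask(8, i + 50, p = 0.5)
    sal <- fix_saliency(msk, reliable = TRUE)
    s1 <- radiograph_sample("a", px, 1)
    v1 <- extract_all(s1, sal)
    px2 <- px; px2[msk == 0] <- runif(sum(msk == 0))
    v2 <- extract_all(radiograph_sample("a", px2, 1), sal)
    expect_identical(as.numeric(v1), as.numeric(v2))
  }
})

test_that("GLCM features are transposition-invariant with the full angle set", {
  for (seed in 1:8) {
    r <- oracle_random_roi(seed + 200)
    f1 <- glcm(r$roi)$features
    roi_t <- discretize(t(r$pixels), t(r$mask), r$roi$bin_width)
    f2 <- glcm(roi_t)$features
    expect_equal(f1, f2, tolerance = 1e-12)
  }
})
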