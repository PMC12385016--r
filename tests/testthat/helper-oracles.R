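## Independent brute-force oracles (naive loops), kept deliberately
## separate from the package's vectorized implementations.

oracle_offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                       `90` = c(-1L, 0L), `135` = c(-1L, -1L))

## GLCM counts by explicit pair enumeration (symmetric accumulation)
oracle_glcm <- function(levels, angle, d = 1L, ng = max(levels, na.rm = TRUE)) {
  off <- oracle_offsets[[as.character(angle)]] * d
  counts <- matrix(0, ng, ng)
  for (i in seq_len(nrow(levels))) for (j in seq_len(ncol(levels))) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 < 1 || i2 > nrow(levels) || j2 < 1 || j2 > ncol(levels)) next
    a <- levels[i, j]; b <- levels[i2, j2]
    if (is.na(a) || is.na(b)) next
    counts[a, b] <- counts[a, b] + 1
    counts[b, a] <- counts[b, a] + 1
  }
  counts
}

## GLRLM counts by walking every line pixel by pixel
oracle_glrlm <- function(levels, angle, max_len = max(dim(levels))) {
  ng <- max(levels, na.rm = TRUE)
  off <- oracle_offsets[[as.character(angle)]]
  step <- -off  # walk in the "forward" direction along the line
  R <- matrix(0, ng, max_len)
  seen <- matrix(FALSE, nrow(levels), ncol(levels))
  for (i in seq_len(nrow(levels))) for (j in seq_len(ncol(levels))) {
    if (seen[i, j] || is.na(levels[i, j])) next
    ## only start from pixels with no same-run predecessor
    pi <- i - step[1]; pj <- j - step[2]
    prev_same <- pi >= 1 && pi <= nrow(levels) && pj >= 1 && pj <= ncol(levels) &&
      !is.na(levels[pi, pj]) && levels[pi, pj] == levels[i, j]
    if (prev_same) next
    len <- 0L; ci <- i; cj <- j
    while (ci >= 1 && ci <= nrow(levels) && cj >= 1 && cj <= ncol(levels) &&
           !is.na(levels[ci, cj]) && levels[ci, cj] == levels[i, j]) {
      seen[ci, cj] <- TRUE
      len <- len + 1L
      ci <- ci + step[1]; cj <- cj + step[2]
    }
    R[levels[i, j], len] <- R[levels[i, j], len] + 1
  }
  R
}

## GLDM counts: per-pixel dependence by explicit neighbor loops
oracle_gldm <- function(levels, alpha = 0, dist = 1L) {
  ng <- max(levels, na.rm = TRUE)
  nmax <- (2 * dist + 1)^2 - 1
  P <- matrix(0, ng, nmax + 1L)
  for (i in seq_len(nrow(levels))) for (j in seq_len(ncol(levels))) {
    if (is.na(levels[i, j])) next
    dep <- 0L
    for (di in -dist:dist) for (dj in -dist:dist) {
      if (di == 0 && dj == 0) next
      i2 <- i + di; j2 <- j + dj
      if (i2 < 1 || i2 > nrow(levels) || j2 < 1 || j2 > ncol(levels)) next
      if (!is.na(levels[i2, j2]) && abs(levels[i2, j2] - levels[i, j]) <= alpha)
        dep <- dep + 1L
    }
    P[levels[i, j], dep + 1L] <- P[levels[i, j], dep + 1L] + 1
  }
  P
}

## NGTDM per-level n_i and s_i by explicit neighbor loops
oracle_ngtdm <- function(levels, dist = 1L) {
  ng <- max(levels, na.rm = TRUE)
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (i in seq_len(nrow(levels))) for (j in seq_len(ncol(levels))) {
    if (is.na(levels[i, j])) next
    nb <- c()
    for (di in -dist:dist) for (dj in -dist:dist) {
      if (di == 0 && dj == 0) next
      i2 <- i + di; j2 <- j + dj
      if (i2 < 1 || i2 > nrow(levels) || j2 < 1 || j2 > ncol(levels)) next
      if (!is.na(levels[i2, j2])) nb <- c(nb, levels[i2, j2])
    }
    if (length(nb)) {
      lv <- levels[i, j]
      n_i[lv] <- n_i[lv] + 1
      s_i[lv] <- s_i[lv] + abs(lv - mean(nb))
    }
  }
  list(n = n_i, s = s_i)
}

## AUC by trapezoidal integration of the empirical ROC curve
oracle_auc_trapezoid <- function(y, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[y == 0] >= t), numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

## mask QC by raw pixel counting
oracle_mask_qc <- function(mask) {
  n <- length(mask)
  area <- sum(mask == 1) / n
  border_idx <- unique(rbind(
    cbind(1, seq_len(ncol(mask))), cbind(nrow(mask), seq_len(ncol(mask))),
    cbind(seq_len(nrow(mask)), 1), cbind(seq_len(nrow(mask)), ncol(mask))))
  border <- mean(mask[border_idx] == 1)
  list(area = area, border = border,
       reliable = area >= 0.01 && border <= 0.30)
}

## random discretized ROI on a <= 8x8 grid
oracle_random_roi <- function(seed, side_max = 8L) {
  set.seed(seed)
  side <- sample(3:side_max, 1)
  px <- matrix(runif(side * side), side, side)
  msk <- fix_mask(side, seed + 1000L, p = runif(1, 0.4, 0.9))
  list(roi = discretize(px, msk, bin_width = runif(1, 0.05, 0.3)),
       pixels = px, mask = msk)
}
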