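## Texture matrices: GLCM, GLRLM, GLDM, NGTDM. All statistics respect the
## mask exactly: a pixel pair, run, or neighborhood only counts if every
## pixel involved lies inside the mask.

## (row, col) offset of an angle at distance d, matching the usual 2D
## radiomics convention (angle measured so that 0 degrees is horizontal).
angle_offset <- function(angle, d = 1L) {
  switch(as.character(angle),
    "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d),
    abort_config("angle must be one of 0, 45, 90, 135"))
}

## levels of the (dr, dc)-offset neighbor at each pixel; NA off the grid
shifted_neighbors <- function(lev, dr, dc) {
  nr <- nrow(lev); nc <- ncol(lev)
  nb <- matrix(NA_integer_, nr, nc)
  if (max(1L, 1L + dr) > min(nr, nr + dr) ||
      max(1L, 1L + dc) > min(nc, nc + dc)) return(nb)
  r_src <- max(1L, 1L + dr):min(nr, nr + dr)
  c_src <- max(1L, 1L + dc):min(nc, nc + dc)
  nb[r_src - dr, c_src - dc] <- lev[r_src, c_src]
  nb
}

## Chebyshev neighborhood offsets within `dist`, excluding the center.
chebyshev_offsets <- function(dist = 1L) {
  g <- expand.grid(dr = -dist:dist, dc = -dist:dist)
  as.matrix(g[!(g$dr == 0 & g$dc == 0), ])
}

## Pair the levels matrix with its shifted copy; returns two aligned level
## vectors (in-mask pairs only).
shift_pairs <- function(levels, off) {
  nr <- nrow(levels); nc <- ncol(levels)
  dr <- off[1]; dc <- off[2]
  if (max(1L, 1L - dr) > min(nr, nr - dr) || max(1L, 1L - dc) > min(nc, nc - dc))
    return(list(a = integer(0), b = integer(0)))
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- levels[r1, c1, drop = FALSE]
  b <- levels[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  list(a = a[ok], b = b[ok])
}

## --- GLCM -------------------------------------------------------------------

#' Gray-level co-occurrence matrix and features
#'
#' Symmetric co-occurrence accumulation per (distance, angle); pairs with
#' either pixel outside the mask are skipped. Features are computed on each
#' normalized matrix and averaged over all (distance, angle) combinations.
#' Degenerate single-level ROIs take analytic values (contrast 0,
#' correlation 1 by convention).
#'
#' @param roi a [discretize()]d ROI (needs >= 2 pixels).
#' @param distances integer pixel distances (default 1).
#' @param angles angles in degrees, subset of 0/45/90/135.
#' @return List with `features` (24 named values, prefix `glcm_`) and
#'   `matrices` (one count matrix per distance/angle).
#' @export
glcm <- function(roi, distances = 1L, angles = c(0, 45, 90, 135)) {
  if (roi$n_pixels < 2L) abort_config("GLCM needs at least 2 in-mask pixels")
  ng <- roi$n_levels
  mats <- list(); feats <- list()
  for (d in distances) for (ang in angles) {
    prs <- shift_pairs(roi$levels, angle_offset(ang, d))
    counts <- matrix(0, ng, ng)
    if (length(prs$a)) {
      tab <- tabulate((prs$a - 1L) * ng + prs$b, nbins = ng * ng)
      counts <- matrix(tab, ng, ng, byrow = TRUE)
      counts <- counts + t(counts)          # symmetric accumulation
    }
    key <- sprintf("d%d_a%d", d, ang)
    mats[[key]] <- counts
    feats[[key]] <- glcm_features(counts)
  }
  list(features = Reduce(`+`, feats) / length(feats), matrices = mats)
}

glcm_features <- function(counts) {
  ng <- nrow(counts)
  tot <- sum(counts)
  p <- if (tot > 0) counts / tot else counts
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)                          # == colSums(p) by symmetry
  mu <- sum(i * p)
  sigma2 <- sum((i - mu)^2 * p)
  ## difference and sum distributions
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), numeric(1))
  da <- sum(k_diff * p_diff)
  hx <- entropy2(px)
  hxy <- entropy2(p)
  pxpy <- outer(px, px)
  hxy1 <- -sum(p[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hxy2 <- entropy2(pxpy)
  corr <- if (sigma2 > 0) (sum(i * j * p) - mu^2) / sigma2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  offd <- i != j
  c(glcm_autocorrelation = sum(i * j * p),
    glcm_cluster_prominence = sum((i + j - 2 * mu)^4 * p),
    glcm_cluster_shade = sum((i + j - 2 * mu)^3 * p),
    glcm_cluster_tendency = sum((i + j - 2 * mu)^2 * p),
    glcm_contrast = sum((i - j)^2 * p),
    glcm_correlation = corr,
    glcm_difference_average = da,
    glcm_difference_entropy = entropy2(p_diff),
    glcm_difference_variance = sum((k_diff - da)^2 * p_diff),
    glcm_dissimilarity = sum(abs(i - j) * p),
    glcm_id = sum(p / (1 + abs(i - j))),
    glcm_idm = sum(p / (1 + (i - j)^2)),
    glcm_idn = sum(p / (1 + abs(i - j) / ng)),
    glcm_idmn = sum(p / (1 + ((i - j) / ng)^2)),
    glcm_imc1 = imc1,
    glcm_imc2 = imc2,
    glcm_inverse_variance = sum(p[offd] / (i[offd] - j[offd])^2),
    glcm_joint_average = mu,
    glcm_joint_energy = sum(p^2),
    glcm_joint_entropy = hxy,
    glcm_maximum_probability = max(p),
    glcm_sum_average = sum(k_sum * p_sum),
    glcm_sum_entropy = entropy2(p_sum),
    glcm_sum_squares = sigma2)
}

entropy2 <- function(p) {
  p <- p[p > 0]
  if (!length(p)) 0 else -sum(p * log2(p))
}

## --- GLRLM ------------------------------------------------------------------

## Lines of the level matrix along one of the four directions; NA (outside
## mask) breaks runs.
direction_lines <- function(levels, angle) {
  nr <- nrow(levels); nc <- ncol(levels)
  switch(as.character(angle),
    "0" = lapply(seq_len(nr), function(r) levels[r, ]),
    "90" = lapply(seq_len(nc), function(cl) levels[, cl]),
    "45" = lapply(2:(nr + nc), function(s) {
      ii <- max(1L, s - nc):min(nr, s - 1L)
      levels[cbind(ii, s - ii)]
    }),
    "135" = lapply((1L - nc):(nr - 1L), function(dd) {
      ii <- max(1L, dd + 1L):min(nr, nc + dd)
      levels[cbind(ii, ii - dd)]
    }),
    abort_config("angle must be one of 0, 45, 90, 135"))
}

#' Gray-level run-length matrix and features
#'
#' Maximal runs of identical gray level along each direction, truncated at
#' the mask boundary; the standard 16-feature set is computed per angle and
#' averaged.
#'
#' @param roi a [discretize()]d ROI.
#' @param angles angles in degrees, subset of 0/45/90/135.
#' @return List with `features` (16 named values, prefix `glrlm_`) and
#'   `matrices` (level x run-length count matrix per angle).
#' @export
glrlm <- function(roi, angles = c(0, 45, 90, 135)) {
  ng <- roi$n_levels
  max_len <- max(dim(roi$levels))
  mats <- list(); feats <- list()
  for (ang in angles) {
    R <- matrix(0, ng, max_len)
    for (line in direction_lines(roi$levels, ang)) {
      if (!length(line)) next
      rl <- rle(as.vector(line))
      keep <- !is.na(rl$values)
      if (any(keep)) {
        lev <- rl$values[keep]; len <- rl$lengths[keep]
        for (q in seq_along(lev)) R[lev[q], len[q]] <- R[lev[q], len[q]] + 1
      }
    }
    key <- sprintf("a%d", ang)
    mats[[key]] <- R
    feats[[key]] <- glrlm_features(R, n_pixels = roi$n_pixels)
  }
  list(features = Reduce(`+`, feats) / length(feats), matrices = mats)
}

glrlm_features <- function(R, n_pixels) {
  nr_runs <- sum(R)
  p <- R / nr_runs
  i <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  j <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
  pg <- rowSums(p); pr <- colSums(p)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(glrlm_sre = sum(p / j^2),
    glrlm_lre = sum(p * j^2),
    glrlm_gln = sum(rowSums(R)^2) / nr_runs,
    glrlm_glnn = sum(pg^2),
    glrlm_rln = sum(colSums(R)^2) / nr_runs,
    glrlm_rlnn = sum(pr^2),
    glrlm_rp = nr_runs / n_pixels,
    glrlm_glv = sum(p * (i - mu_i)^2),
    glrlm_rv = sum(p * (j - mu_j)^2),
    glrlm_re = entropy2(p),
    glrlm_lglre = sum(p / i^2),
    glrlm_hglre = sum(p * i^2),
    glrlm_srlgle = sum(p / (i^2 * j^2)),
    glrlm_srhgle = sum(p * i^2 / j^2),
    glrlm_lrlgle = sum(p * j^2 / i^2),
    glrlm_lrhgle = sum(p * i^2 * j^2))
}

## --- GLDM -------------------------------------------------------------------

#' Gray-level dependence matrix and features
#'
#' For every in-mask pixel, the dependence count is the number of in-mask
#' neighbors within Chebyshev distance `distance` whose gray level differs
#' by at most `alpha`. The matrix is indexed by (level, dependence + 1) so
#' that the dependence-size index `j` starts at 1; the standard 14-feature
#' set follows.
#'
#' @param roi a [discretize()]d ROI.
#' @param alpha gray-level tolerance (default 0).
#' @param distance Chebyshev neighborhood radius (default 1).
#' @return List with `features` (14 named values, prefix `gldm_`) and
#'   `matrix` (level x dependence-size counts).
#' @export
gldm <- function(roi, alpha = 0, distance = 1L) {
  lev <- roi$levels
  offs <- chebyshev_offsets(distance)
  nr <- nrow(lev); nc <- ncol(lev)
  dep <- matrix(0L, nr, nc)
  for (k in seq_len(nrow(offs))) {
    nb <- shifted_neighbors(lev, offs[k, 1], offs[k, 2])
    ok <- !is.na(lev) & !is.na(nb) & abs(lev - nb) <= alpha
    dep <- dep + ok
  }
  dmax <- nrow(offs)
  P <- matrix(0, roi$n_levels, dmax + 1L)
  inm <- which(roi$mask)
  for (q in inm) P[lev[q], dep[q] + 1L] <- P[lev[q], dep[q] + 1L] + 1
  list(features = gldm_features(P), matrix = P)
}

gldm_features <- function(P) {
  nz <- sum(P)
  p <- P / nz
  i <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  j <- matrix(seq_len(ncol(P)), nrow(P), ncol(P), byrow = TRUE)
  pg <- rowSums(p); pd <- colSums(p)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(gldm_sde = sum(p / j^2),
    gldm_lde = sum(p * j^2),
    gldm_gln = sum(rowSums(P)^2) / nz,
    gldm_dn = sum(colSums(P)^2) / nz,
    gldm_dnn = sum(pd^2),
    gldm_glv = sum(p * (i - mu_i)^2),
    gldm_dv = sum(p * (j - mu_j)^2),
    gldm_de = entropy2(p),
    gldm_lgle = sum(p / i^2),
    gldm_hgle = sum(p * i^2),
    gldm_sdlgle = sum(p / (i^2 * j^2)),
    gldm_sdhgle = sum(p * i^2 / j^2),
    gldm_ldlgle = sum(p * j^2 / i^2),
    gldm_ldhgle = sum(p * i^2 * j^2))
}

## --- NGTDM ------------------------------------------------------------------

NGTDM_COARSENESS_CAP <- 1e6

#' Neighborhood gray-tone difference features
#'
#' For each in-mask pixel that has at least one in-mask neighbor within
#' Chebyshev distance `distance`, the absolute difference between its level
#' and the mean level of those neighbors is accumulated per gray level
#' (`s_i`). Coarseness, contrast, busyness, complexity and strength follow
#' the standard formulas; coarseness is capped at `1e6` when its
#' denominator vanishes (e.g. a constant or single-pixel ROI).
#'
#' @param roi a [discretize()]d ROI.
#' @param distance Chebyshev neighborhood radius (default 1).
#' @return List with `features` (5 named values, prefix `ngtdm_`) and the
#'   per-level table (`n_i`, `p_i`, `s_i`).
#' @export
ngtdm <- function(roi, distance = 1L) {
  lev <- roi$levels
  offs <- chebyshev_offsets(distance)
  nr <- nrow(lev); nc <- ncol(lev)
  nb_sum <- matrix(0, nr, nc)
  nb_cnt <- matrix(0L, nr, nc)
  for (k in seq_len(nrow(offs))) {
    nb <- shifted_neighbors(lev, offs[k, 1], offs[k, 2])
    ok <- !is.na(nb)
    nb_sum[ok] <- nb_sum[ok] + nb[ok]
    nb_cnt <- nb_cnt + ok
  }
  valid <- roi$mask & nb_cnt > 0
  ng <- roi$n_levels
  n_i <- numeric(ng); s_i <- numeric(ng)
  if (any(valid)) {
    lv <- lev[valid]
    dif <- abs(lv - nb_sum[valid] / nb_cnt[valid])
    n_i <- tabulate(lv, nbins = ng)
    s_acc <- rowsum(dif, lv)
    s_i[as.integer(rownames(s_acc))] <- s_acc[, 1]
  }
  nvp <- sum(n_i)
  p_i <- if (nvp > 0) n_i / nvp else n_i
  list(features = ngtdm_features(p_i, s_i, nvp),
       table = tibble::tibble(level = seq_len(ng), n = n_i, p = p_i, s = s_i))
}

ngtdm_features <- function(p_i, s_i, nvp) {
  act <- which(p_i > 0)
  ngp <- length(act)
  denom_coarse <- sum(p_i * s_i)
  coarseness <- if (denom_coarse > 0) 1 / denom_coarse else NGTDM_COARSENESS_CAP
  contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  if (ngp >= 1 && nvp > 0) {
    ii <- act
    if (ngp > 1) {
      pij <- outer(p_i[ii], p_i[ii])
      d2 <- outer(ii, ii, function(a, b) (a - b)^2)
      contrast <- sum(pij * d2) / (ngp * (ngp - 1)) * sum(s_i) / nvp
      bden <- sum(abs(outer(ii * p_i[ii], ii * p_i[ii], "-")))
      busyness <- if (bden > 0) sum(p_i * s_i) / bden else 0
      psi <- p_i[ii] * s_i[ii]
      num <- outer(psi, psi, "+")
      den <- outer(p_i[ii], p_i[ii], "+")
      complexity <- sum(abs(outer(ii, ii, "-")) * num / den) / nvp
      sden <- sum(s_i)
      strength <- if (sden > 0) sum(den * d2) / sden else 0
    }
  }
  c(ngtdm_coarseness = min(coarseness, NGTDM_COARSENESS_CAP),
    ngtdm_contrast = contrast,
    ngtdm_busyness = busyness,
    ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}
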