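## ROI discretization and radiomics configuration.

#' Radiomics settings
#'
#' Defaults follow common 2D radiomics conventions: fixed bin width 0.098
#' on the `[0, 1]` intensity scale (the equivalent of 25 gray levels on
#' 8-bit data), co-occurrence and run-length accumulation over the four
#' 2D angles at distance 1 with symmetric GLCM and angle-averaged
#' features, dependence tolerance `alpha = 0` and all neighborhoods at
#' Chebyshev distance 1. All settings are echoed into exported metadata.
#'
#' @param bin_width fixed intensity bin width on the `[0, 1]` scale.
#' @param distances GLCM pixel distances.
#' @param angles GLCM/GLRLM angles in degrees (subset of 0, 45, 90, 135).
#' @param gldm_alpha gray-level tolerance for dependence counting.
#' @param gldm_distance Chebyshev neighborhood radius for GLDM.
#' @param ngtdm_distance Chebyshev neighborhood radius for NGTDM.
#' @param pixel_spacing physical pixel size (arbitrary units) for shape
#'   and total-energy scaling.
#' @return A `radiomics_config` list.
#' @export
radiomics_config <- function(bin_width = 0.098, distances = 1L,
                             angles = c(0, 45, 90, 135),
                             gldm_alpha = 0, gldm_distance = 1L,
                             ngtdm_distance = 1L, pixel_spacing = 1) {
  assert_number(bin_width, "bin_width", min = 1e-6)
  if (!all(angles %in% c(0, 45, 90, 135)))
    abort_config("`angles` must be a subset of {0, 45, 90, 135}")
  structure(
    list(bin_width = bin_width, distances = as.integer(distances),
         angles = angles, gldm_alpha = gldm_alpha,
         gldm_distance = as.integer(gldm_distance),
         ngtdm_distance = as.integer(ngtdm_distance),
         pixel_spacing = pixel_spacing),
    class = "radiomics_config"
  )
}

#' Discretize the masked region of an image into gray levels
#'
#' Fixed-bin-width discretization:
#' `level(p) = floor((x_p - min_roi) / bin_width) + 1`, so levels run from
#' 1 to `N_g`. Pixels outside the mask are excluded from every downstream
#' statistic.
#'
#' @param sample a [radiograph_sample()] or pixel matrix.
#' @param mask binary matrix of the same shape; must be non-empty.
#' @param bin_width intensity bin width (same scale as the pixels).
#' @return A `discretized_roi`: `levels` (integer matrix, `NA` outside the
#'   mask), `values` (raw in-mask intensities, column-major order),
#'   `n_levels`, `n_pixels`, `bin_width`, `mask`.
#' @export
discretize <- function(sample, mask, bin_width = 0.098) {
  px <- if (inherits(sample, "radiograph_sample")) sample$pixels else sample
  if (!all(dim(px) == dim(mask))) abort_config("mask and image shapes differ")
  msk <- mask != 0
  if (!any(msk))
    stop(structure(class = c("radfuse_empty_roi_error", "error", "condition"),
                   list(message = "empty ROI: apply the mask-QC zero-padding rule before feature extraction",
                        call = NULL)))
  vals <- px[msk]
  lev <- floor((vals - min(vals)) / bin_width) + 1
  levels <- matrix(NA_integer_, nrow(px), ncol(px))
  levels[msk] <- as.integer(lev)
  structure(
    list(levels = levels, values = vals, n_levels = max(lev),
         n_pixels = sum(msk), bin_width = bin_width, mask = msk),
    class = "discretized_roi"
  )
}
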