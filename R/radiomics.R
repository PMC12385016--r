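## Assembly of the full radiomic vector with the zero-padding rule.

#' Names of the full radiomic feature census
#'
#' The package computes a fixed, ordered census of 87 features:
#' 18 first-order + 24 GLCM + 16 GLRLM + 14 GLDM + 5 NGTDM + 10 Shape2D.
#' The census (names and order) is a package constant so that feature
#' matrices are column-stable across runs and configurations.
#'
#' @return Character vector of length 87.
#' @export
radiomic_feature_names <- function() {
  fo <- paste0("fo_", c("energy", "total_energy", "entropy", "minimum", "p10",
                        "p90", "maximum", "mean", "median", "iqr", "range",
                        "mad", "rmad", "rms", "skewness", "kurtosis",
                        "variance", "uniformity"))
  gl <- paste0("glcm_", c("autocorrelation", "cluster_prominence",
                          "cluster_shade", "cluster_tendency", "contrast",
                          "correlation", "difference_average",
                          "difference_entropy", "difference_variance",
                          "dissimilarity", "id", "idm", "idn", "idmn",
                          "imc1", "imc2", "inverse_variance", "joint_average",
                          "joint_energy", "joint_entropy",
                          "maximum_probability", "sum_average", "sum_entropy",
                          "sum_squares"))
  rl <- paste0("glrlm_", c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp",
                           "glv", "rv", "re", "lglre", "hglre", "srlgle",
                           "srhgle", "lrlgle", "lrhgle"))
  gd <- paste0("gldm_", c("sde", "lde", "gln", "dn", "dnn", "glv", "dv", "de",
                          "lgle", "hgle", "sdlgle", "sdhgle", "ldlgle",
                          "ldhgle"))
  ng <- paste0("ngtdm_", c("coarseness", "contrast", "busyness", "complexity",
                           "strength"))
  sh <- paste0("shape_", c("mesh_surface", "pixel_surface", "perimeter",
                           "perimeter_surface_ratio", "sphericity",
                           "compactness", "maximum_diameter",
                           "major_axis_length", "minor_axis_length",
                           "elongation"))
  c(fo, gl, rl, gd, ng, sh)
}

#' Extract the full radiomic vector from a masked sample
#'
#' If the saliency mask failed quality control, the vector is zero-padded:
#' all 87 features are exactly 0 and the `reliable` attribute is `FALSE`
#' (the sample is still usable in the CNN channel). Otherwise all six
#' feature families are computed inside the mask.
#'
#' @param sample a [radiograph_sample()].
#' @param saliency a `saliency_result` from [compute_saliency()], or any
#'   list with fields `mask` and `qc`.
#' @param config a [radiomics_config()].
#' @return A named numeric vector of length 87 (class `radiomic_vector`)
#'   with attribute `reliable`.
#' @export
extract_all <- function(sample, saliency, config = radiomics_config()) {
  nm <- radiomic_feature_names()
  if (!isTRUE(saliency$qc$reliable)) {
    out <- stats::setNames(numeric(length(nm)), nm)
    return(structure(out, reliable = FALSE, class = "radiomic_vector"))
  }
  roi <- discretize(sample, saliency$mask, bin_width = config$bin_width)
  fo <- first_order(roi)
  fo["fo_total_energy"] <- fo["fo_energy"] * config$pixel_spacing^2
  out <- c(fo,
           glcm(roi, distances = config$distances, angles = config$angles)$features,
           glrlm(roi, angles = config$angles)$features,
           gldm(roi, alpha = config$gldm_alpha, distance = config$gldm_distance)$features,
           ngtdm(roi, distance = config$ngtdm_distance)$features,
           shape2d(saliency$mask, pixel_spacing = config$pixel_spacing))
  stopifnot(identical(names(out), nm))
  structure(out, reliable = TRUE, class = "radiomic_vector")
}

#' Radiomic feature matrix for a dataset
#'
#' @param samples list of [radiograph_sample()] objects.
#' @param saliencies list of saliency results, one per sample.
#' @param config a [radiomics_config()].
#' @return A tibble: `id`, `label`, `reliable_mask`, `area_fraction`,
#'   `border_fraction`, then the 87 feature columns.
#' @export
radiomics_matrix <- function(samples, saliencies, config = radiomics_config()) {
  stopifnot(length(samples) == length(saliencies))
  rows <- lapply(seq_along(samples), function(i) {
    v <- extract_all(samples[[i]], saliencies[[i]], config)
    tibble::tibble(
      id = samples[[i]]$id, label = samples[[i]]$label,
      reliable_mask = attr(v, "reliable"),
      area_fraction = saliencies[[i]]$qc$area_fraction,
      border_fraction = saliencies[[i]]$qc$border_fraction,
      !!!as.list(v)
    )
  })
  dplyr::bind_rows(rows)
}
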