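## Grad-CAM heatmaps, binary saliency masks and the mask quality-control rule.

#' Grad-CAM heatmap from a conv trace
#'
#' Standard Grad-CAM: channel weights are the spatial means of the
#' target-class gradients, the raw map is the ReLU of the weighted sum of
#' feature maps, which is then bilinearly upsampled to `out_side` and
#' min-max normalized so that the heatmap peaks at 1 (unless the raw map is
#' identically zero, in which case the heatmap is all zeros). A constant
#' positive raw map normalizes to a constant 1.
#'
#' @param trace a [conv_trace()].
#' @param out_side output resolution in pixels.
#' @return An `out_side` x `out_side` matrix in `[0, 1]`.
#' @export
gradcam <- function(trace, out_side) {
  if (!inherits(trace, "conv_trace")) abort_config("`trace` must be a conv_trace")
  A <- trace$activations; G <- trace$gradients
  if (!all(is.finite(A)) || !all(is.finite(G)))
    stop("non-finite conv trace", call. = FALSE)
  alpha <- apply(G, 3, mean)
  raw <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_along(alpha)) raw <- raw + alpha[k] * A[, , k]
  raw <- pmax(raw, 0)
  up <- resize_matrix(raw, out_side, out_side)
  mx <- max(up); mn <- min(up)
  if (mx <= 0) return(matrix(0, out_side, out_side))
  if (mx > mn) (up - mn) / (mx - mn) else up / mx
}

#' Threshold a heatmap into a binary mask
#'
#' `mask(i, j) = 1` iff `heatmap(i, j) >= threshold` (inclusive
#' comparison).
#'
#' @param heatmap matrix in `[0, 1]`.
#' @param threshold cutoff on the normalized scale, default 0.5.
#' @return An integer 0/1 matrix of the same shape.
#' @export
binarize <- function(heatmap, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    abort_config("`threshold` must lie in [0, 1]")
  m <- (heatmap >= threshold) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Mask quality control
#'
#' A saliency mask is deemed unreliable when it covers less than
#' `min_area` of the image or activates more than `max_border` of the
#' 1-pixel outer border (border fraction = active border pixels / total
#' border pixels, which makes the rule scale-free).
#'
#' @param mask binary matrix (side >= 3).
#' @param min_area minimum area fraction (default 0.01).
#' @param max_border maximum border fraction (default 0.30).
#' @return A `mask_qc` list with `area_fraction`, `border_fraction`,
#'   `reliable`.
#' @export
mask_qc <- function(mask, min_area = 0.01, max_border = 0.30) {
  if (nrow(mask) < 3L || ncol(mask) < 3L) abort_config("mask side must be >= 3")
  area_fraction <- sum(mask != 0) / length(mask)
  border <- c(mask[1, ], mask[nrow(mask), ],
              mask[2:(nrow(mask) - 1L), 1], mask[2:(nrow(mask) - 1L), ncol(mask)])
  border_fraction <- sum(border != 0) / length(border)
  structure(list(area_fraction = area_fraction,
                 border_fraction = border_fraction,
                 reliable = area_fraction >= min_area && border_fraction <= max_border),
            class = "mask_qc")
}

#' Compute the full saliency result for one sample
#'
#' Runs Grad-CAM on the original (non-augmented) image, thresholds the
#' normalized heatmap, and applies mask quality control.
#'
#' @param adapter a backbone adapter supporting conv tracing.
#' @param sample a [radiograph_sample()] at the adapter's input side.
#' @param threshold heatmap cutoff, default 0.5.
#' @param target `"predicted"` (default) differentiates the model's
#'   predicted class; `"lesion"` always uses the lesion class.
#' @param qc_min_area,qc_max_border QC thresholds, see [mask_qc()].
#' @return A `saliency_result`: `heatmap`, `mask`, `qc`, `threshold`,
#'   `target_class`.
#' @export
compute_saliency <- function(adapter, sample, threshold = 0.5,
                             target = c("predicted", "lesion"),
                             qc_min_area = 0.01, qc_max_border = 0.30) {
  target <- match.arg(target)
  tcl <- if (target == "lesion") 1L else NULL
  tr <- trace_conv(adapter, sample, target_class = tcl)
  side <- nrow(if (inherits(sample, "radiograph_sample")) sample$pixels else sample)
  hm <- gradcam(tr, side)
  mk <- binarize(hm, threshold)
  structure(list(heatmap = hm, mask = mk,
                 qc = mask_qc(mk, qc_min_area, qc_max_border),
                 threshold = threshold, target_class = tr$target_class),
            class = "saliency_result")
}

#' @export
print.saliency_result <- function(x, ...) {
  cat(sprintf("<saliency_result> %dx%d  area=%.4f border=%.3f  %s\n",
              nrow(x$heatmap), ncol(x$heatmap), x$qc$area_fraction,
              x$qc$border_fraction,
              if (x$qc$reliable) "reliable" else "UNRELIABLE"))
  invisible(x)
}

#' Export a heatmap or mask as an 8-bit PNG
#'
#' @param x matrix in `[0, 1]` (heatmap) or binary (mask).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_heatmap_png <- function(x, path) {
  png::writePNG(clip01(x), path)
  invisible(path)
}
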