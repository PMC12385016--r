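#' Radiograph sample container
#'
#' A single grayscale radiograph: pixel matrix in `[0, 1]`, a binary label
#' (0 = healthy, 1 = lesion) and an identifier. The pixel matrix uses
#' (row, col) indexing with the origin at the top-left corner.
#'
#' @param id character identifier, unique within a dataset.
#' @param pixels numeric matrix with finite values in `[0, 1]`.
#' @param label 0 (healthy) or 1 (lesion).
#' @param source_path originating file path, or `""` for in-memory samples.
#'
#' @return An object of class `radiograph_sample`: a list with fields
#'   `id`, `pixels`, `label` and `source_path`.
#' @export
radiograph_sample <- function(id, pixels, label, source_path = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    abort_config("`id` must be a non-empty string")
  if (!is.matrix(pixels) || !is.numeric(pixels) || !all(is.finite(pixels)))
    abort_config("`pixels` must be a finite numeric matrix")
  if (min(pixels) < 0 || max(pixels) > 1)
    abort_config("`pixels` must lie in [0, 1]; normalize before construction")
  if (!label %in% c(0, 1)) abort_config("`label` must be 0 (healthy) or 1 (lesion)")
  structure(
    list(id = id, pixels = pixels, label = as.integer(label),
         source_path = source_path),
    class = "radiograph_sample"
  )
}

#' @export
print.radiograph_sample <- function(x, ...) {
  cat(sprintf("<radiograph_sample> id=%s  %dx%d  label=%d (%s)\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$label,
              if (x$label == 1L) "lesion" else "healthy"))
  invisible(x)
}

#' Manifest of a sample list
#'
#' @param samples list of [radiograph_sample()] objects.
#' @return A tibble with columns `id`, `label`, `rows`, `cols`, `source_path`.
#' @export
sample_manifest <- function(samples) {
  tibble::tibble(
    id = vapply(samples, function(s) s$id, character(1)),
    label = vapply(samples, function(s) s$label, integer(1)),
    rows = vapply(samples, function(s) nrow(s$pixels), integer(1)),
    cols = vapply(samples, function(s) ncol(s$pixels), integer(1)),
    source_path = vapply(samples, function(s) s$source_path, character(1))
  )
}

#' Named label vector of a sample list
#'
#' @param samples list of [radiograph_sample()] objects.
#' @return Integer vector of labels named by sample id.
#' @export
sample_labels <- function(samples) {
  stats::setNames(vapply(samples, function(s) s$label, integer(1)),
                  vapply(samples, function(s) s$id, character(1)))
}
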