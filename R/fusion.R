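## Multimodal fusion: TTA-averaged embeddings concatenated with masked
## radiomics; two-model ensemble concatenation.

#' Test-time augmentation policy
#'
#' A deterministic view list — identity, horizontal flip, vertical flip,
#' rotate +10 degrees, rotate -10 degrees — truncated to `count`. The first
#' view is always the identity. Deterministic views are preferred over
#' random draws so that fused vectors are bit-reproducible.
#'
#' @param count number of views, 1..5 (default 5).
#' @return A `tta_policy` list.
#' @export
tta_policy <- function(count = 5L) {
  count <- assert_count(count, "count", min = 1L)
  if (count > 5L) abort_config("`count` must be at most 5")
  structure(list(count = count), class = "tta_policy")
}

#' Deterministic TTA views of a sample
#'
#' @param sample a [radiograph_sample()] or pixel matrix.
#' @param policy a [tta_policy()].
#' @return List of `count` pixel matrices; the first is the original image.
#' @export
tta_views <- function(sample, policy = tta_policy()) {
  px <- if (inherits(sample, "radiograph_sample")) sample$pixels else sample
  makers <- list(
    function(x) x,
    function(x) affine_transform(x, hflip = TRUE),
    function(x) affine_transform(x, vflip = TRUE),
    function(x) affine_transform(x, angle = 10),
    function(x) affine_transform(x, angle = -10)
  )
  lapply(makers[seq_len(policy$count)], function(f) f(px))
}

#' Fuse deep embedding and masked radiomics for one sample
#'
#' The embedding part is the arithmetic mean of the backbone embedding over
#' the TTA views; the radiomic part is extracted once, from the original
#' (untransformed) image under the saliency mask. Concatenation order is
#' `[embedding | radiomics]`.
#'
#' @param sample a [radiograph_sample()] at the adapter's input side.
#' @param adapter a backbone adapter.
#' @param saliency a `saliency_result` for the original image.
#' @param policy a [tta_policy()]; `tta_policy(1)` disables augmentation.
#' @param config a [radiomics_config()].
#' @return A named numeric vector (class `fused_vector`) of length
#'   `embedding_dim + 87`, with provenance attributes `backbone`,
#'   `tta_count`, `sample_id`, `reliable`.
#' @export
fuse <- function(sample, adapter, saliency, policy = tta_policy(),
                 config = radiomics_config()) {
  views <- tta_views(sample, policy)
  emb <- colMeans(embed(adapter, views))
  rad <- extract_all(sample, saliency, config)
  out <- c(emb, as.numeric(rad))
  names(out) <- c(paste0("emb_", seq_along(emb)), names(rad))
  structure(out, class = "fused_vector",
            backbone = adapter$name, tta_count = policy$count,
            sample_id = sample$id, reliable = attr(rad, "reliable"))
}

#' Concatenate the fused vectors of two backbones (two-model ensemble)
#'
#' @param a,b `fused_vector`s of the same sample from two backbones. Block
#'   order in the output follows the argument order; feature names are
#'   prefixed with the backbone name.
#' @return A plain named numeric vector of length `length(a) + length(b)`.
#' @export
ensemble_concat <- function(a, b) {
  ida <- attr(a, "sample_id"); idb <- attr(b, "sample_id")
  if (!is.null(ida) && !is.null(idb) && !identical(ida, idb))
    stop(sprintf("sample-id mismatch in ensemble_concat: '%s' vs '%s'", ida, idb),
         call. = FALSE)
  if (identical(attr(a, "backbone"), attr(b, "backbone")))
    warning("ensembling a backbone with itself duplicates its feature block")
  nm <- c(paste0(attr(a, "backbone") %||% "a", ".", names(a)),
          paste0(attr(b, "backbone") %||% "b", ".", names(b)))
  stats::setNames(c(as.numeric(a), as.numeric(b)), nm)
}

#' Fused feature matrix for a dataset
#'
#' Computes saliency, masked radiomics and (optionally TTA-averaged)
#' embeddings for every sample. TTA is applied only to the ids in
#' `tta_ids` (typically the inference samples); all other samples use the
#' identity view, matching test-time semantics. Use `tta_ids = "all"` to
#' average every sample.
#'
#' @param samples list of [radiograph_sample()] at the adapter input side.
#' @param adapter a backbone adapter.
#' @param policy a [tta_policy()].
#' @param tta_ids character vector of ids to TTA-average, or `"all"`, or
#'   `NULL` (no TTA anywhere).
#' @param threshold Grad-CAM mask threshold.
#' @param config a [radiomics_config()].
#' @param target saliency target class rule, see [compute_saliency()].
#' @return List with `features` (tibble: id, label, reliable_mask, columns
#'   `emb_*` then radiomic names) and `saliencies` (list of saliency
#'   results).
#' @export
fuse_dataset <- function(samples, adapter, policy = tta_policy(),
                         tta_ids = NULL, threshold = 0.5,
                         config = radiomics_config(),
                         target = c("predicted", "lesion")) {
  target <- match.arg(target)
  sal <- lapply(samples, function(s)
    compute_saliency(adapter, s, threshold = threshold, target = target))
  id1 <- tta_policy(1)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    use_tta <- !is.null(tta_ids) &&
      (identical(tta_ids, "all") || s$id %in% tta_ids)
    v <- fuse(s, adapter, sal[[i]], policy = if (use_tta) policy else id1,
              config = config)
    tibble::tibble(id = s$id, label = s$label,
                   reliable_mask = attr(v, "reliable"), !!!as.list(v))
  })
  list(features = dplyr::bind_rows(rows), saliencies = sal)
}
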