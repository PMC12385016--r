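## End-to-end orchestration: data -> backbone -> saliency -> radiomics ->
## fusion (+TTA) -> reduction/classification -> evaluation -> explanation.

#' Pipeline configuration
#'
#' Collects every stage's settings with the package defaults: saliency
#' threshold 0.5, QC thresholds (1% area, 30% border), five TTA views,
#' SelectKBest k = 100, 5-fold stratified CV.
#'
#' @param data a [synthetic_config()] (synthetic run) or a manifest CSV
#'   path (ingest run).
#' @param seed master seed; all stage seeds are derived substreams.
#' @param backbone_side,conv_channels test-backbone geometry.
#' @param epochs,lr backbone training epochs and learning rate.
#' @param patience early-stopping patience; defaults to `epochs`
#'   (disabled) because the from-scratch test backbone plateaus before
#'   finding the lesion signal.
#' @param saliency_threshold Grad-CAM mask cutoff in `[0, 1]`.
#' @param qc_min_area,qc_max_border mask QC thresholds in `[0, 1]`.
#' @param tta_count TTA views at inference (1 disables).
#' @param radiomics a [radiomics_config()].
#' @param reduction a [reduction_spec()].
#' @param classifier a [classifier_spec()].
#' @param protocol `"cv5"`, `"holdout80_20"` or `"split70_15_15"`.
#' @param ablations also evaluate embedding-only and radiomics-only blocks.
#' @param shap_samples rows to attribute with TreeSHAP (0 disables).
#' @param out_dir artifact directory, or `NULL` for in-memory results only.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(data = synthetic_config(n_images = 120, image_size = 32),
                            seed = 1L,
                            backbone_side = 32L, conv_channels = 32L,
                            epochs = 40L, lr = 1e-2, patience = NULL,
                            saliency_threshold = 0.5,
                            qc_min_area = 0.01, qc_max_border = 0.30,
                            tta_count = 5L,
                            radiomics = radiomics_config(),
                            reduction = reduction_spec("select_k_best"),
                            classifier = classifier_spec("random_forest"),
                            protocol = c("cv5", "holdout80_20", "split70_15_15"),
                            ablations = FALSE, shap_samples = 0L,
                            out_dir = NULL) {
  protocol <- match.arg(protocol)
  assert_number(saliency_threshold, "saliency_threshold", 0, 1)
  assert_number(qc_min_area, "qc_min_area", 0, 1)
  assert_number(qc_max_border, "qc_max_border", 0, 1)
  structure(list(
    data = data, seed = as.integer(seed), backbone_side = as.integer(backbone_side),
    conv_channels = as.integer(conv_channels), epochs = as.integer(epochs),
    lr = lr, patience = as.integer(patience %||% epochs),
    saliency_threshold = saliency_threshold,
    qc_min_area = qc_min_area, qc_max_border = qc_max_border,
    tta_count = as.integer(tta_count), radiomics = radiomics,
    reduction = reduction, classifier = classifier, protocol = protocol,
    ablations = ablations, shap_samples = as.integer(shap_samples),
    out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Deterministic given the config seed. Stages: load or synthesize the
#' dataset, stratified 70/15/15 split, train the test backbone on the
#' training portion (validation portion for early stopping), compute
#' Grad-CAM saliency and masked radiomics on every original image, build
#' identity-view and TTA-averaged fused matrices, then evaluate under the
#' configured protocol. Training folds always use identity-view features;
#' held-out samples use TTA-averaged features (test-time semantics).
#'
#' @param config a [pipeline_config()].
#' @param backbone optional pre-trained backbone adapter (skips training).
#' @return An `evaluation_report`: fused/ablation results, feature tibble,
#'   split, attribution, explanation bundles and provenance.
#' @export
run_pipeline <- function(config, backbone = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  samples <- if (inherits(config$data, "synthetic_config")) {
    generate_dataset(config$data)
  } else if (is.character(config$data)) {
    load_dataset(config$data)
  } else abort_config("`data` must be a synthetic_config or a manifest path")
  samples <- lapply(samples, resize_sample, side = config$backbone_side)

  split <- stratified_split(sample_labels(samples),
                            seed = substream_seed(config$seed, 11))
  by_id <- stats::setNames(seq_along(samples), vapply(samples, `[[`, "", "id"))

  if (is.null(backbone)) {
    backbone <- build_test_backbone(seed = substream_seed(config$seed, 23),
                                    side = config$backbone_side,
                                    conv_channels = config$conv_channels)
    backbone <- train_backbone(
      backbone,
      samples[by_id[split_ids(split, "train")]],
      val_samples = samples[by_id[split_ids(split, "val")]],
      epochs = config$epochs, lr = config$lr, patience = config$patience,
      seed = substream_seed(config$seed, 37))
  }

  sal <- lapply(samples, function(s)
    compute_saliency(backbone, s, threshold = config$saliency_threshold,
                     qc_min_area = config$qc_min_area,
                     qc_max_border = config$qc_max_border))
  rad <- radiomics_matrix(samples, sal, config$radiomics)
  emb_id <- embed(backbone, samples)
  emb_tta <- if (config$tta_count > 1L) {
    pol <- tta_policy(config$tta_count)
    t(vapply(samples, function(s) colMeans(embed(backbone, tta_views(s, pol))),
             numeric(backbone$embedding_dim)))
  } else emb_id
  colnames(emb_tta) <- colnames(emb_id)

  rad_mat <- as.matrix(rad[, radiomic_feature_names()])
  y <- rad$label
  X <- cbind(emb_id, rad_mat)
  X_tta <- cbind(emb_tta, rad_mat)
  features <- dplyr::bind_cols(
    tibble::tibble(id = rad$id, label = y, reliable_mask = rad$reliable_mask),
    tibble::as_tibble(X))

  eval_seed <- substream_seed(config$seed, 53)
  evaluate_block <- function(Xb, Xb_infer) {
    switch(config$protocol,
      cv5 = grid_search_cv(Xb, y, spec = config$classifier,
                           reduction = config$reduction, folds = 5L,
                           seed = eval_seed, X_infer = Xb_infer),
      holdout80_20 = holdout_eval(Xb, Xb_infer, y, config, frac = 0.8,
                                  seed = eval_seed),
      split70_15_15 = {
        tr <- split$split != "test"
        pipe <- fit_pipeline(Xb[tr, , drop = FALSE], y[tr], config$classifier,
                             as.list(config$classifier$grid[1, , drop = FALSE]),
                             config$reduction)
        prob <- predict_proba(pipe, Xb_infer[!tr, , drop = FALSE])
        list(metrics = metrics(y[!tr], as.integer(prob >= 0.5), prob),
             pipeline = pipe)
      })
  }
  fused <- evaluate_block(X, X_tta)
  ablation <- NULL
  if (isTRUE(config$ablations)) {
    emb_cols <- seq_len(ncol(emb_id))
    ablation <- list(
      embedding_only = evaluate_block(X[, emb_cols, drop = FALSE],
                                      X_tta[, emb_cols, drop = FALSE]),
      radiomics_only = evaluate_block(rad_mat, rad_mat))
  }

  pipeline <- if (inherits(fused, "cv_result")) fused$pipeline else fused$pipeline
  attribution <- NULL; bundles <- NULL
  if (config$shap_samples > 0L) {
    take <- seq_len(min(config$shap_samples, nrow(X_tta)))
    attribution <- tree_shapley(pipeline, X_tta[take, , drop = FALSE],
                                ids = rad$id[take])
    bundles <- lapply(head(take, 3L), function(i)
      explanation_bundle(samples[[i]], sal[[i]], attribution, i))
  }

  report <- structure(list(
    fused = fused, ablation = ablation, features = features, split = split,
    backbone = backbone, saliencies = sal, attribution = attribution,
    bundles = bundles, config = config,
    provenance = list(seed = config$seed,
                      config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
                      n_samples = length(samples),
                      package_version = as.character(utils::packageVersion("radfuse")))
  ), class = "evaluation_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

holdout_eval <- function(X, X_infer, y, config, frac = 0.8, seed = 1L) {
  ids <- as.character(seq_along(y))
  sp <- stratified_split(stats::setNames(y, ids),
                         fractions = c(frac, 0, 1 - frac), seed = seed)
  tr <- sp$split == "train"
  pipe <- fit_pipeline(X[tr, , drop = FALSE], y[tr], config$classifier,
                       as.list(config$classifier$grid[1, , drop = FALSE]),
                       config$reduction)
  prob <- predict_proba(pipe, X_infer[!tr, , drop = FALSE])
  list(metrics = metrics(y[!tr], as.integer(prob >= 0.5), prob),
       pipeline = pipe, holdout_idx = which(!tr))
}

report_metrics <- function(block) {
  if (inherits(block, "cv_result")) {
    dplyr::summarise(block$fold_metrics,
                     dplyr::across(c("accuracy", "precision", "recall",
                                     "specificity", "f1", "auc"),
                                   mean))
  } else block$metrics[, c("accuracy", "precision", "recall", "specificity",
                           "f1", "auc")]
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", x$config$protocol, "protocol\n")
  m <- report_metrics(x$fused)
  cat(sprintf("  fused: accuracy=%.3f auc=%.3f\n", m$accuracy, m$auc))
  if (!is.null(x$ablation)) {
    me <- report_metrics(x$ablation$embedding_only)
    mr <- report_metrics(x$ablation$radiomics_only)
    cat(sprintf("  embedding-only: accuracy=%.3f | radiomics-only: accuracy=%.3f\n",
                me$accuracy, mr$accuracy))
  }
  invisible(x)
}

## Persist run artifacts: feature matrix, metrics, provenance manifest.
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$features, file.path(dir, "features.csv"))
  readr::write_csv(tibble::as_tibble(report$split), file.path(dir, "split.csv"))
  out <- list(
    protocol = report$config$protocol,
    fused = as.list(report_metrics(report$fused)),
    settings = list(
      saliency_threshold = report$config$saliency_threshold,
      qc = c(report$config$qc_min_area, report$config$qc_max_border),
      tta_count = report$config$tta_count,
      radiomics = unclass(report$config$radiomics)
    ),
    provenance = report$provenance
  )
  if (!is.null(report$ablation)) {
    out$embedding_only <- as.list(report_metrics(report$ablation$embedding_only))
    out$radiomics_only <- as.list(report_metrics(report$ablation$radiomics_only))
  }
  jsonlite::write_json(out, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$bundles)) {
    for (i in seq_along(report$bundles))
      bundle_to_json(report$bundles[[i]],
                     file.path(dir, sprintf("bundle_%02d.json", i)))
  }
  invisible(dir)
}
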