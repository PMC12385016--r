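## broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-fold metrics of a cross-validation result
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return Long tibble: `fold`, `metric`, `value`.
#' @export
tidy.cv_result <- function(x, ...) {
  tidyr::pivot_longer(x$fold_metrics,
                      cols = c("accuracy", "precision", "recall",
                               "specificity", "f1", "auc"),
                      names_to = "metric", values_to = "value")[
    , c("fold", "metric", "value")]
}

#' One-row summary of a cross-validation result
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return Tibble with mean and SD of accuracy and AUC plus the chosen
#'   hyperparameters.
#' @export
glance.cv_result <- function(x, ...) {
  fm <- x$fold_metrics
  dplyr::bind_cols(
    tibble::tibble(
      n_folds = nrow(fm),
      accuracy = mean(fm$accuracy), accuracy_sd = stats::sd(fm$accuracy),
      auc = mean(fm$auc), auc_sd = stats::sd(fm$auc),
      metric = x$metric),
    tibble::as_tibble(x$best_params))
}

#' Tidy an attribution object into long format
#'
#' Beeswarm-ready: one row per (sample, feature) with the contribution and
#' the feature value is left to the caller's data.
#'
#' @param x an `attribution`.
#' @param ... unused.
#' @return Tibble: `sample`, `feature`, `value`.
#' @export
tidy.attribution <- function(x, ...) {
  v <- x$values
  tibble::tibble(
    sample = rep(x$ids %||% seq_len(nrow(v)), times = ncol(v)),
    feature = rep(colnames(v), each = nrow(v)),
    value = as.vector(v))
}

#' @export
glance.attribution <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$values), n_features = ncol(x$values),
                 base_value = x$base_value, scale = x$scale,
                 local_accuracy_gap = max(abs(x$base_value +
                                              rowSums(x$values) - x$output)))
}

#' Plot a Grad-CAM saliency result
#'
#' Raster heatmap with the binary mask outlined by its in-mask pixels.
#'
#' @param object a `saliency_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.saliency_result <- function(object, ...) {
  hm <- object$heatmap
  df <- tidyr::expand_grid(row = seq_len(nrow(hm)), col = seq_len(ncol(hm)))
  df$heat <- as.vector(hm[as.matrix(df[, c("row", "col")])])
  df$masked <- as.vector(object$mask[as.matrix(df[, c("row", "col")])] == 1L)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$heat)) +
    ggplot2::geom_point(data = df[df$masked, ], size = 0.1, alpha = 0.15) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "Grad-CAM", x = NULL, y = NULL,
                  title = sprintf("Saliency (%s mask)",
                                  if (object$qc$reliable) "reliable" else "unreliable"))
}

#' Plot per-fold cross-validation metrics
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "fold", y = NULL)
}

#' Plot mean absolute Shapley contributions
#'
#' @param object an `attribution`.
#' @param top_k number of features shown.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.attribution <- function(object, top_k = 15L, ...) {
  imp <- colMeans(abs(object$values))
  ord <- order(imp, decreasing = TRUE)[seq_len(min(top_k, length(imp)))]
  df <- tibble::tibble(feature = factor(names(imp)[ord],
                                        levels = rev(names(imp)[ord])),
                       importance = imp[ord])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = sprintf("mean |SHAP| (%s scale)", object$scale), y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
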