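## Shapley attributions for the fitted tree ensembles. The polynomial-time
## path-dependent TreeSHAP recursion is implemented here over a unified
## tree table extracted from ranger or xgboost models; an exponential-time
## subset-enumeration oracle is provided for verification on small trees.

## A unified tree is a list of aligned vectors over 1-based node ids:
##   feature (NA at leaves), split, yes, no (children), cover (training
##   weight), value (leaf value), plus rule: "le" (x <= split goes to
##   `yes`, ranger) or "lt" (x < split, xgboost).

## round a double to float32 precision (xgboost stores and compares
## feature values and thresholds in single precision)
as_float32 <- function(v) readBin(writeBin(as.numeric(v), raw(), size = 4L),
                                  "numeric", size = 4L, n = length(v))

goes_yes <- function(tree, node, x) {
  xv <- x[tree$feature[node]]
  if (tree$rule == "lt") as_float32(xv) < tree$split[node]
  else xv <= tree$split[node]
}

## expected leaf value of a subtree under cover weighting
tree_expectation <- function(tree, node = 1L) {
  if (is.na(tree$feature[node])) return(tree$value[node])
  yl <- tree$yes[node]; nr <- tree$no[node]
  (tree$cover[yl] * tree_expectation(tree, yl) +
   tree$cover[nr] * tree_expectation(tree, nr)) / tree$cover[node]
}

## Path-dependent TreeSHAP for one tree and one sample; returns phi over
## n_features. Translation of the standard EXTEND/UNWIND recursion; path
## state is carried in plain vectors (copy-on-write gives each branch its
## own path).
treeshap_one <- function(tree, x, n_features) {
  phi <- numeric(n_features)

  extend <- function(feat, z, o, w, pz, po, pf) {
    l <- length(w)
    feat <- c(feat, pf); z <- c(z, pz); o <- c(o, po)
    w <- c(w, if (l == 0L) 1 else 0)
    if (l > 0L) for (j in l:1) {
      w[j + 1L] <- w[j + 1L] + po * w[j] * j / (l + 1)
      w[j] <- pz * w[j] * (l - j + 1) / (l + 1)
    }
    list(feat = feat, z = z, o = o, w = w)
  }

  unwind <- function(feat, z, o, w, i1) {
    l <- length(w); ud <- l - 1L
    of <- o[i1]; zf <- z[i1]
    n <- w[l]
    for (j in (l - 1L):1) {
      if (of != 0) {
        t0 <- w[j]
        w[j] <- n * (ud + 1) / (j * of)
        n <- t0 - w[j] * zf * (ud - j + 1) / (ud + 1)
      } else {
        w[j] <- w[j] * (ud + 1) / (zf * (ud - j + 1))
      }
    }
    keep <- seq_len(l - 1L)
    if (i1 <= l - 1L) for (j in i1:(l - 1L)) {
      feat[j] <- feat[j + 1L]; z[j] <- z[j + 1L]; o[j] <- o[j + 1L]
    }
    list(feat = feat[keep], z = z[keep], o = o[keep], w = w[keep])
  }

  unwound_sum <- function(z, o, w, i1) {
    l <- length(w); ud <- l - 1L
    of <- o[i1]; zf <- z[i1]
    n <- w[l]; total <- 0
    for (j in (l - 1L):1) {
      if (of != 0) {
        t0 <- n * (ud + 1) / (j * of)
        total <- total + t0
        n <- w[j] - t0 * zf * (ud - j + 1) / (ud + 1)
      } else {
        total <- total + w[j] * (ud + 1) / (zf * (ud - j + 1))
      }
    }
    total
  }

  recurse <- function(node, pz, po, pf, feat, z, o, w) {
    ext <- extend(feat, z, o, w, pz, po, pf)
    feat <- ext$feat; z <- ext$z; o <- ext$o; w <- ext$w
    if (is.na(tree$feature[node])) {
      l <- length(w)
      if (l >= 2L) for (i1 in 2:l) {
        ws <- unwound_sum(z, o, w, i1)
        phi[feat[i1]] <<- phi[feat[i1]] + ws * (o[i1] - z[i1]) * tree$value[node]
      }
      return(invisible(NULL))
    }
    f <- tree$feature[node]
    hot <- if (goes_yes(tree, node, x)) tree$yes[node] else tree$no[node]
    cold <- if (hot == tree$yes[node]) tree$no[node] else tree$yes[node]
    iz <- 1; io <- 1
    k <- which(feat == f & seq_along(feat) >= 2L)
    if (length(k)) {
      k <- k[1]
      iz <- z[k]; io <- o[k]
      uw <- unwind(feat, z, o, w, k)
      feat <- uw$feat; z <- uw$z; o <- uw$o; w <- uw$w
    }
    rc <- tree$cover[node]
    recurse(hot, iz * tree$cover[hot] / rc, io, f, feat, z, o, w)
    recurse(cold, iz * tree$cover[cold] / rc, 0, f, feat, z, o, w)
    invisible(NULL)
  }

  recurse(1L, 1, 1, 0L, integer(0), numeric(0), numeric(0), numeric(0))
  phi
}

#' Exact Shapley values for one tree by subset enumeration
#'
#' Exponential-time oracle: enumerates all subsets of the features the tree
#' actually splits on, evaluating the cover-weighted conditional
#' expectation for each subset. Intended for verifying the polynomial
#' TreeSHAP recursion on small trees.
#'
#' @param tree a unified tree list (`feature`, `split`, `yes`, `no`,
#'   `cover`, `value`, `rule`).
#' @param x one sample (numeric vector in the tree's feature space).
#' @param n_features length of the output attribution vector.
#' @return Numeric vector of Shapley values (features absent from the tree
#'   get exactly 0).
#' @export
shapley_brute_force <- function(tree, x, n_features) {
  used <- sort(unique(tree$feature[!is.na(tree$feature)]))
  m <- length(used)
  if (m > 20L) abort_config("brute-force Shapley is limited to <= 20 used features")
  expect_s <- function(node, inset) {
    if (is.na(tree$feature[node])) return(tree$value[node])
    if (tree$feature[node] %in% inset) {
      nxt <- if (goes_yes(tree, node, x)) tree$yes[node] else tree$no[node]
      return(expect_s(nxt, inset))
    }
    yl <- tree$yes[node]; nr <- tree$no[node]
    (tree$cover[yl] * expect_s(yl, inset) +
     tree$cover[nr] * expect_s(nr, inset)) / tree$cover[node]
  }
  phi <- numeric(n_features)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  vcache <- apply(subsets, 1, function(sel) expect_s(1L, used[sel]))
  key <- function(sel) sum(2^(seq_len(m) - 1) * sel) + 1
  for (fi in seq_len(m)) {
    f <- used[fi]
    for (r in seq_len(nrow(subsets))) {
      sel <- as.logical(subsets[r, ])
      if (sel[fi]) next
      s_size <- sum(sel)
      wgt <- factorial(s_size) * factorial(m - s_size - 1) / factorial(m)
      with_f <- sel; with_f[fi] <- TRUE
      phi[f] <- phi[f] + wgt * (vcache[key(with_f)] - vcache[key(sel)])
    }
  }
  phi
}

## --- model extraction -------------------------------------------------------

extract_trees <- function(pipeline) {
  if (pipeline$kind == "random_forest") extract_trees_ranger(pipeline)
  else extract_trees_xgb(pipeline)
}

extract_trees_ranger <- function(pipeline) {
  rf <- pipeline$model
  Z <- pipeline$train_X
  lapply(seq_len(rf$num.trees), function(t) {
    ti <- ranger::treeInfo(rf, tree = t)
    pred_cols <- grep("^pred", names(ti), value = TRUE)
    value <- if (length(pred_cols) >= 2L) ti[[pred_cols[2]]] else ti[[pred_cols[1]]]
    tree <- list(
      feature = ifelse(ti$terminal, NA_integer_, ti$splitvarID + 1L),
      split = ti$splitval,
      yes = ti$leftChild + 1L,
      no = ti$rightChild + 1L,
      value = ifelse(ti$terminal, value, NA_real_),
      rule = "le"
    )
    tree$cover <- tree_covers(tree, Z)
    tree
  })
}

## route the full training matrix down the tree to get node weights
tree_covers <- function(tree, Z) {
  n_nodes <- length(tree$feature)
  cover <- numeric(n_nodes)
  assign_rows <- function(node, rows) {
    cover[node] <<- length(rows)
    if (is.na(tree$feature[node]) || length(rows) == 0L) return(invisible(NULL))
    xv <- Z[rows, tree$feature[node]]
    left <- if (tree$rule == "lt") as_float32(xv) < tree$split[node]
            else xv <= tree$split[node]
    assign_rows(tree$yes[node], rows[left])
    assign_rows(tree$no[node], rows[!left])
  }
  assign_rows(1L, seq_len(nrow(Z)))
  if (any(cover == 0))
    warning("tree has nodes unreached by training data; their branches get zero weight")
  cover
}

## Parse trees from the JSON model payload: unlike the text dump, the JSON
## serialization round-trips the float32 split thresholds and leaf weights
## exactly, so traversal reproduces xgboost's own comparisons bit for bit.
extract_trees_xgb <- function(pipeline) {
  js <- rawToChar(xgboost::xgb.save.raw(pipeline$model, raw_format = "json"))
  mod <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  lapply(mod$learner$gradient_booster$model$trees, function(tt) {
    lc <- unlist(tt$left_children)
    rc <- unlist(tt$right_children)
    leaf <- lc == -1L
    list(
      feature = ifelse(leaf, NA_integer_, unlist(tt$split_indices) + 1L),
      split = ifelse(leaf, NA_real_, as_float32(unlist(tt$split_conditions))),
      yes = ifelse(leaf, NA_integer_, lc + 1L),
      no = ifelse(leaf, NA_integer_, rc + 1L),
      cover = unlist(tt$sum_hessian),
      value = ifelse(leaf, unlist(tt$base_weights), NA_real_),
      rule = "lt"
    )
  })
}

## --- public attribution API -------------------------------------------------

#' TreeSHAP attributions for a fitted pipeline
#'
#' Computes per-sample, per-feature Shapley contributions in the reduced
#' feature space actually fed to the trees (attributions on PCA components
#' are labeled as components, not mapped back to fabricated single-feature
#' names; the reduction model is attached so the loadings remain
#' inspectable). Satisfies local accuracy: `base_value + sum(contributions)`
#' equals the model output for every sample — the class-1 probability for
#' random forests, the log-odds margin for gradient-boosted trees.
#'
#' @param pipeline a fitted `fusion_pipeline` from [grid_search_cv()] or
#'   `fit_pipeline`; must be a tree ensemble.
#' @param X feature matrix in the original (pre-reduction) space.
#' @param ids optional row identifiers.
#' @return An `attribution` object: `values` (n x p matrix), `base_value`,
#'   `output` (model output per sample), `scale` (`"probability"` or
#'   `"margin"`), `feature_names`, `reduction`.
#' @export
tree_shapley <- function(pipeline, X, ids = NULL) {
  if (!inherits(pipeline, "fusion_pipeline") ||
      !pipeline$kind %in% c("random_forest", "gradient_boosted_trees"))
    stop(structure(class = c("radfuse_unsupported_model_error", "error", "condition"),
                   list(message = "Shapley attribution requires a fitted tree-ensemble pipeline",
                        call = NULL)))
  Z <- apply_reduction(pipeline$reduction, as.matrix(X))
  colnames(Z) <- pipeline$feature_names
  trees <- extract_trees(pipeline)
  p <- ncol(Z); n <- nrow(Z)
  phi <- matrix(0, n, p, dimnames = list(ids, pipeline$feature_names))
  for (tree in trees) {
    for (r in seq_len(n)) phi[r, ] <- phi[r, ] + treeshap_one(tree, Z[r, ], p)
  }
  expectations <- vapply(trees, tree_expectation, numeric(1))
  if (pipeline$kind == "random_forest") {
    phi <- phi / length(trees)
    base <- mean(expectations)
    output <- predict_proba(pipeline, X)
    scale <- "probability"
  } else {
    base <- sum(expectations)
    ## margin summed in double precision over the extracted trees; agrees
    ## with predict(..., outputmargin = TRUE) up to float32 accumulation
    output <- vapply(seq_len(n), function(r) {
      sum(vapply(trees, function(tree) {
        nd <- 1L
        while (!is.na(tree$feature[nd]))
          nd <- if (goes_yes(tree, nd, Z[r, ])) tree$yes[nd] else tree$no[nd]
        tree$value[nd]
      }, numeric(1)))
    }, numeric(1))
    scale <- "margin"
  }
  structure(list(values = phi, base_value = base, output = output,
                 scale = scale, feature_names = pipeline$feature_names,
                 ids = ids, reduction = pipeline$reduction),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("<attribution> %d samples x %d features (%s scale), base=%.4f\n",
              nrow(x$values), ncol(x$values), x$scale, x$base_value))
  invisible(x)
}

#' Assemble the dual-layer explanation bundle for one sample
#'
#' The record a clinician-facing report layer consumes: the lesion
#' probability, the saliency heatmap and QC verdict (pixel level), and the
#' top-k signed feature attributions sorted by absolute value (feature
#' level).
#'
#' @param sample a [radiograph_sample()].
#' @param saliency its `saliency_result`.
#' @param attribution an [tree_shapley()] result containing this sample.
#' @param index row of `attribution` corresponding to the sample.
#' @param top_k number of attribution rows to keep (default 10).
#' @return An `explanation_bundle` list; serializes losslessly with
#'   [bundle_to_json()].
#' @export
explanation_bundle <- function(sample, saliency, attribution, index, top_k = 10L) {
  contrib <- attribution$values[index, ]
  ord <- order(abs(contrib), decreasing = TRUE)[seq_len(min(top_k, length(contrib)))]
  out <- attribution$output[index]
  prob <- if (attribution$scale == "margin") 1 / (1 + exp(-out)) else out
  structure(list(
    id = sample$id,
    probability = unname(prob),
    label = sample$label,
    qc = list(area_fraction = saliency$qc$area_fraction,
              border_fraction = saliency$qc$border_fraction,
              reliable = saliency$qc$reliable),
    heatmap_side = nrow(saliency$heatmap),
    base_value = attribution$base_value,
    scale = attribution$scale,
    top_attributions = tibble::tibble(
      feature = attribution$feature_names[ord],
      value = unname(contrib[ord]))
  ), class = "explanation_bundle")
}

#' Serialize / restore an explanation bundle
#'
#' @param bundle an [explanation_bundle()].
#' @param path optional file path; `NULL` returns the JSON string.
#' @return JSON string (or path); `bundle_from_json` returns the bundle.
#' @export
bundle_to_json <- function(bundle, path = NULL) {
  js <- jsonlite::toJSON(unclass(bundle), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(path)) }
  js
}

#' @rdname bundle_to_json
#' @param json JSON string or file path.
#' @export
bundle_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$top_attributions <- tibble::as_tibble(x$top_attributions)
  structure(x, class = "explanation_bundle")
}
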