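## Backbone adapter contract + a small, seeded, trainable CNN implemented
## with plain matrix algebra (im2col convolutions, Adam optimizer). The
## adapter contract is what the rest of the pipeline sees: any model that
## can produce a penultimate embedding and last-conv activations/gradients
## can stand behind it.

#' Construct a custom backbone adapter
#'
#' The adapter contract used throughout the pipeline: a backbone must
#' expose a fixed-length penultimate embedding ([embed()]), last
#' convolutional activations with target-class gradients ([trace_conv()]),
#' and a lesion probability ([predict_proba()]). This constructor wraps
#' user-supplied functions (e.g. bindings to an external framework, or
#' mocks in tests); the in-package CNN from [build_test_backbone()]
#' satisfies the same contract.
#'
#' @param name backbone name (recorded in fused-vector provenance).
#' @param embedding_dim length of the embedding vector.
#' @param input_side expected square input side in pixels.
#' @param embed_fn function(image_matrix) -> numeric(embedding_dim).
#' @param trace_fn function(image_matrix, target_class) -> [conv_trace()],
#'   or `NULL` if the backbone cannot expose conv gradients.
#' @param predict_fn function(image_matrix) -> probability of class lesion.
#' @return A `backbone_adapter` object.
#' @export
backbone_adapter <- function(name, embedding_dim, input_side,
                             embed_fn, trace_fn = NULL, predict_fn = NULL) {
  structure(
    list(name = name, embedding_dim = as.integer(embedding_dim),
         input_side = as.integer(input_side),
         embed_fn = embed_fn, trace_fn = trace_fn, predict_fn = predict_fn),
    class = "backbone_adapter"
  )
}

#' Last-convolution trace: activations and target-class gradients
#'
#' @param activations h x w x k array of last-conv feature maps.
#' @param gradients array of the same shape: gradient of the target-class
#'   score with respect to each activation.
#' @param target_class the class (0/1) whose score was differentiated.
#' @return A `conv_trace` object.
#' @export
conv_trace <- function(activations, gradients, target_class = 1L) {
  if (!identical(dim(activations), dim(gradients)))
    abort_config("activations and gradients must share shape")
  if (!all(is.finite(activations)) || !all(is.finite(gradients)))
    stop("non-finite values in conv trace", call. = FALSE)
  structure(list(activations = activations, gradients = gradients,
                 target_class = as.integer(target_class)),
            class = "conv_trace")
}

#' @rdname embed
#' @export
embed <- function(adapter, images, ...) UseMethod("embed")

#' Penultimate-layer embeddings
#'
#' Runs the backbone as a fixed feature extractor and returns the
#' post-pooling, pre-classification-head vector for each image.
#'
#' @param adapter a backbone adapter.
#' @param images a single pixel matrix, a list of matrices, or a list of
#'   [radiograph_sample()] objects, already at the adapter's input side.
#' @param ... unused.
#' @return A numeric matrix, one row per image, `embedding_dim` columns.
#' @export
embed.backbone_adapter <- function(adapter, images, ...) {
  imgs <- as_image_list(images, adapter$input_side)
  out <- t(vapply(imgs, adapter$embed_fn, numeric(adapter$embedding_dim)))
  dimnames(out) <- list(NULL, paste0("emb_", seq_len(adapter$embedding_dim)))
  out
}

#' @rdname trace_conv
#' @export
trace_conv <- function(adapter, image, target_class = NULL, ...) UseMethod("trace_conv")

#' Gradients of the class score at the last convolutional layer
#'
#' @param adapter a backbone adapter supporting conv tracing.
#' @param image one pixel matrix or [radiograph_sample()].
#' @param target_class 0 or 1; `NULL` uses the model's predicted class.
#' @param ... unused.
#' @return A [conv_trace()].
#' @export
trace_conv.backbone_adapter <- function(adapter, image, target_class = NULL, ...) {
  if (is.null(adapter$trace_fn))
    stop(structure(class = c("radfuse_capability_error", "error", "condition"),
                   list(message = sprintf("backbone '%s' does not support conv tracing", adapter$name),
                        call = NULL)))
  img <- as_image_list(image, adapter$input_side)[[1]]
  adapter$trace_fn(img, target_class)
}

#' @rdname predict_proba
#' @export
predict_proba <- function(object, ...) UseMethod("predict_proba")

#' Lesion probability
#'
#' @param object a backbone adapter or fitted classification pipeline.
#' @param images images as in [embed()] (backbone method).
#' @param ... unused.
#' @return Numeric vector of probabilities of the lesion class (index 1).
#' @export
predict_proba.backbone_adapter <- function(object, images, ...) {
  imgs <- as_image_list(images, object$input_side)
  vapply(imgs, object$predict_fn, numeric(1))
}

## Normalize image input to a list of matrices; enforce the adapter side.
as_image_list <- function(images, side = NULL) {
  if (is.matrix(images)) images <- list(images)
  if (inherits(images, "radiograph_sample")) images <- list(images$pixels)
  imgs <- lapply(images, function(x) if (inherits(x, "radiograph_sample")) x$pixels else x)
  if (!is.null(side)) {
    ok <- vapply(imgs, function(m) all(dim(m) == side), logical(1))
    if (!all(ok))
      stop(sprintf("adapter expects %dx%d input; resize samples first", side, side),
           call. = FALSE)
  }
  imgs
}

## ---------------------------------------------------------------------------
## The test backbone: conv(3x3, c1) -> ReLU -> pool2 -> conv(3x3, c2) -> ReLU
## -> pool2 -> conv(3x3, C) -> ReLU -> GAP -> dropout(0.30) -> dense(2).
## "Penultimate layer" is the post-GAP vector; the last conv layer feeds
## Grad-CAM. Lesion is class index 1 (second logit) everywhere.
## ---------------------------------------------------------------------------

#' Build the small seeded test CNN
#'
#' A three-block CNN suitable for desk-scale training on synthetic
#' radiographs. Initial weights are drawn with He scaling from a seeded
#' stream, so the same seed reproduces identical weights.
#'
#' @param seed integer seed for weight initialization.
#' @param side square input side in pixels (must be divisible by 4).
#' @param conv_channels channels of the last conv block = embedding length.
#' @return A `cnn_backbone` (also a `backbone_adapter`).
#' @export
build_test_backbone <- function(seed = 1L, side = 32L, conv_channels = 32L) {
  side <- assert_count(side, "side", min = 8L)
  if (side %% 4L != 0L) abort_config("`side` must be divisible by 4")
  conv_channels <- assert_count(conv_channels, "conv_channels", min = 2L)
  ch <- c(8L, 16L, conv_channels)
  w <- with_seed(seed, list(
    W1 = matrix(rnorm(9 * 1 * ch[1], sd = sqrt(2 / 9)), 9, ch[1]),
    b1 = numeric(ch[1]),
    W2 = matrix(rnorm(9 * ch[1] * ch[2], sd = sqrt(2 / (9 * ch[1]))), 9 * ch[1], ch[2]),
    b2 = numeric(ch[2]),
    W3 = matrix(rnorm(9 * ch[2] * ch[3], sd = sqrt(2 / (9 * ch[2]))), 9 * ch[2], ch[3]),
    b3 = numeric(ch[3]),
    Wd = matrix(rnorm(ch[3] * 2, sd = sqrt(1 / ch[3])), ch[3], 2),
    bd = numeric(2)
  ))
  structure(
    list(name = sprintf("test_cnn_s%d_c%d", side, conv_channels),
         input_side = side, channels = ch,
         embedding_dim = conv_channels, dropout = 0.30,
         weights = w, trained = FALSE, history = NULL, seed = seed),
    class = c("cnn_backbone", "backbone_adapter")
  )
}

## im2col neighbor indices for 3x3 same-padding conv on an s x s grid,
## into the zero-padded (s+2) x (s+2) image. Cached per side.
conv_idx_cache <- new.env(parent = emptyenv())
conv3_indices <- function(s) {
  key <- as.character(s)
  if (!is.null(conv_idx_cache[[key]])) return(conv_idx_cache[[key]])
  p <- s + 2L
  r <- rep(seq_len(s), times = s) + 1L   # padded row of each output pixel
  c <- rep(seq_len(s), each = s) + 1L
  idx <- matrix(0L, s * s, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    idx[, k] <- (c + dc - 1L) * p + (r + dr)
  }
  conv_idx_cache[[key]] <- idx
  idx
}

## x: s x s x cin array -> (s*s) x (9*cin) patch matrix
im2col3 <- function(x, s, cin) {
  idx <- conv3_indices(s)
  pad <- array(0, dim = c(s + 2L, s + 2L, cin))
  pad[2:(s + 1L), 2:(s + 1L), ] <- x
  out <- matrix(0, s * s, 9L * cin)
  for (ch in seq_len(cin)) {
    pv <- pad[, , ch]
    out[, (9L * (ch - 1L) + 1L):(9L * ch)] <- pv[idx]
  }
  out
}

## scatter-add column gradients back to the input array
col2im3 <- function(dcols, s, cin) {
  idx <- conv3_indices(s)
  dx <- array(0, dim = c(s + 2L, s + 2L, cin))
  for (ch in seq_len(cin)) {
    acc <- numeric((s + 2L)^2)
    block <- dcols[, (9L * (ch - 1L) + 1L):(9L * ch), drop = FALSE]
    for (k in 1:9) {
      tk <- rowsum(block[, k], idx[, k])
      acc[as.integer(rownames(tk))] <- acc[as.integer(rownames(tk))] + tk[, 1]
    }
    dx[, , ch] <- matrix(acc, s + 2L, s + 2L)
  }
  dx[2:(s + 1L), 2:(s + 1L), , drop = FALSE]
}

## 2x2 max pooling; returns pooled array and argmax slot (1..4) for backprop
maxpool2 <- function(x) {
  s <- dim(x)[1]; cin <- dim(x)[3]; h <- s %/% 2L
  o <- seq(1L, s, by = 2L)
  a <- x[o, o, , drop = FALSE];     b <- x[o + 1L, o, , drop = FALSE]
  cc <- x[o, o + 1L, , drop = FALSE]; d <- x[o + 1L, o + 1L, , drop = FALSE]
  m1 <- pmax(a, b); w1 <- ifelse(a >= b, 1L, 2L)
  m2 <- pmax(cc, d); w2 <- ifelse(cc >= d, 3L, 4L)
  out <- pmax(m1, m2)
  arg <- ifelse(m1 >= m2, w1, w2)
  list(out = out, arg = arg)
}

maxpool2_backward <- function(dout, arg) {
  h <- dim(dout)[1]; cin <- dim(dout)[3]; s <- 2L * h
  dx <- array(0, dim = c(s, s, cin))
  o <- seq(1L, s, by = 2L)
  for (slot in 1:4) {
    sel <- arg == slot
    g <- dout * sel
    dr <- if (slot %in% c(2L, 4L)) 1L else 0L
    dc <- if (slot %in% c(3L, 4L)) 1L else 0L
    dx[o + dr, o + dc, ] <- dx[o + dr, o + dc, ] + g
  }
  dx
}

## Full forward pass for one image; keep = TRUE retains caches for backprop.
cnn_forward <- function(bb, img, keep = FALSE, dropout_mask = NULL) {
  w <- bb$weights; s <- bb$input_side; ch <- bb$channels
  x0 <- array(img - 0.5, dim = c(s, s, 1L))   # center [0,1] inputs
  c1 <- im2col3(x0, s, 1L)
  z1 <- sweep(c1 %*% w$W1, 2, w$b1, "+")
  a1 <- array(pmax(z1, 0), dim = c(s, s, ch[1]))
  p1 <- maxpool2(a1)
  s2 <- s %/% 2L
  c2 <- im2col3(p1$out, s2, ch[1])
  z2 <- sweep(c2 %*% w$W2, 2, w$b2, "+")
  a2 <- array(pmax(z2, 0), dim = c(s2, s2, ch[2]))
  p2 <- maxpool2(a2)
  s3 <- s2 %/% 2L
  c3 <- im2col3(p2$out, s3, ch[2])
  z3 <- sweep(c3 %*% w$W3, 2, w$b3, "+")
  a3 <- array(pmax(z3, 0), dim = c(s3, s3, ch[3]))
  emb <- apply(a3, 3, mean)
  emb_d <- if (is.null(dropout_mask)) emb else emb * dropout_mask / (1 - bb$dropout)
  logits <- drop(emb_d %*% w$Wd) + w$bd
  res <- list(logits = logits, emb = emb, a3 = a3)
  if (keep) res$cache <- list(c1 = c1, z1 = z1, p1 = p1, c2 = c2, z2 = z2,
                              p2 = p2, c3 = c3, z3 = z3, emb_d = emb_d,
                              dropout_mask = dropout_mask, s2 = s2, s3 = s3)
  res
}

## Backward pass for one image given dlogits (length 2). Returns gradient list.
cnn_backward <- function(bb, fw, dlogits) {
  w <- bb$weights; ch <- bb$channels; cache <- fw$cache
  s <- bb$input_side; s2 <- cache$s2; s3 <- cache$s3
  g <- list()
  g$Wd <- outer(cache$emb_d, dlogits)
  g$bd <- dlogits
  demb <- drop(w$Wd %*% dlogits)
  if (!is.null(cache$dropout_mask))
    demb <- demb * cache$dropout_mask / (1 - bb$dropout)
  ## GAP: every spatial cell gets demb_k / (s3*s3)
  da3 <- array(rep(demb, each = s3 * s3) / (s3 * s3), dim = c(s3, s3, ch[3]))
  dz3 <- matrix(da3, s3 * s3, ch[3]) * (cache$z3 > 0)
  g$W3 <- crossprod(cache$c3, dz3)
  g$b3 <- colSums(dz3)
  dp2 <- col2im3(dz3 %*% t(w$W3), s3, ch[2])
  da2 <- maxpool2_backward(dp2, cache$p2$arg)
  dz2 <- matrix(da2, s2 * s2, ch[2]) * (cache$z2 > 0)
  g$W2 <- crossprod(cache$c2, dz2)
  g$b2 <- colSums(dz2)
  dp1 <- col2im3(dz2 %*% t(w$W2), s2, ch[1])
  da1 <- maxpool2_backward(dp1, cache$p1$arg)
  dz1 <- matrix(da1, s * s, ch[1]) * (cache$z1 > 0)
  g$W1 <- crossprod(cache$c1, dz1)
  g$b1 <- colSums(dz1)
  g
}

#' Train the test backbone
#'
#' Softmax cross-entropy with Adam, L2 weight decay on conv and dense
#' weights, dropout 0.30 before the head, and optional early stopping on a
#' validation set. Deterministic given `seed`.
#'
#' @param backbone a [build_test_backbone()] object.
#' @param samples training samples (resized internally if needed).
#' @param val_samples optional validation samples for early stopping.
#' @param epochs training epochs (default 40).
#' @param lr Adam learning rate. Default 1e-2, suited to from-scratch
#'   training of this small network, whose loss plateaus for tens of
#'   epochs before the localized lesion signal is found; use 1e-4 for
#'   fine-tuning-style runs on a pretrained adapter.
#' @param batch_size minibatch size.
#' @param l2 L2 weight-decay coefficient (default 1e-4).
#' @param patience early-stopping patience in epochs (default 10),
#'   monitored on the validation cross-entropy; the best-loss weights are
#'   restored. Set `patience = epochs` to disable.
#' @param augment optional [augmentation_policy()] applied to each
#'   training image per epoch.
#' @param seed integer seed for shuffling, dropout and augmentation draws.
#' @param verbose print per-epoch losses.
#' @return The trained backbone with a `history` tibble attached.
#' @export
train_backbone <- function(backbone, samples, val_samples = NULL,
                           epochs = 40L, lr = 1e-2, batch_size = 16L,
                           l2 = 1e-4, patience = 10L, augment = NULL,
                           seed = 1L, verbose = FALSE) {
  side <- backbone$input_side
  samples <- lapply(samples, function(s)
    if (all(dim(s$pixels) == side)) s else resize_sample(s, side))
  y <- vapply(samples, function(s) s$label, integer(1))
  n <- length(samples)
  wnames <- names(backbone$weights)
  adam_m <- lapply(backbone$weights, function(x) x * 0)
  adam_v <- adam_m
  t_step <- 0
  best <- list(loss = Inf, weights = backbone$weights, wait = 0L)
  hist <- list()
  val_y <- if (!is.null(val_samples))
    vapply(val_samples, function(s) s$label, integer(1)) else NULL
  val_imgs <- if (!is.null(val_samples))
    lapply(val_samples, function(s)
      if (all(dim(s$pixels) == side)) s$pixels else resize_sample(s, side)$pixels)
    else NULL

  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        bidx <- ord[start:min(start + batch_size - 1L, n)]
        grads <- NULL
        for (j in bidx) {
          img <- samples[[j]]$pixels
          if (!is.null(augment)) img <- augment_sample(samples[[j]], augment)$pixels
          mask <- as.numeric(runif(backbone$embedding_dim) >= backbone$dropout)
          fw <- cnn_forward(backbone, img, keep = TRUE, dropout_mask = mask)
          p <- softmax2(fw$logits)
          tgt <- y[j] + 1L
          ep_loss <- ep_loss - log(max(p[tgt], 1e-12))
          dlog <- p; dlog[tgt] <- dlog[tgt] - 1
          g <- cnn_backward(backbone, fw, dlog)
          grads <- if (is.null(grads)) g else
            stats::setNames(lapply(wnames, function(nm) grads[[nm]] + g[[nm]]), wnames)
        }
        nb <- length(bidx)
        t_step <- t_step + 1
        for (nm in wnames) {
          gr <- grads[[nm]] / nb
          if (grepl("^W", nm)) gr <- gr + l2 * backbone$weights[[nm]]
          adam_m[[nm]] <- 0.9 * adam_m[[nm]] + 0.1 * gr
          adam_v[[nm]] <- 0.999 * adam_v[[nm]] + 0.001 * gr^2
          mhat <- adam_m[[nm]] / (1 - 0.9^t_step)
          vhat <- adam_v[[nm]] / (1 - 0.999^t_step)
          backbone$weights[[nm]] <- backbone$weights[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
        }
      }
      val_acc <- NA_real_; val_loss <- NA_real_
      stop_now <- FALSE
      if (!is.null(val_samples)) {
        pv <- predict_proba(backbone, val_imgs)
        p_true <- ifelse(val_y == 1L, pv, 1 - pv)
        val_loss <- -mean(log(pmax(p_true, 1e-12)))
        val_acc <- mean((pv >= 0.5) == (val_y == 1L))
        if (val_loss < best$loss) {
          best$loss <- val_loss; best$weights <- backbone$weights; best$wait <- 0L
        } else {
          best$wait <- best$wait + 1L
          stop_now <- best$wait >= patience
        }
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss / n,
                                   val_loss = val_loss, val_accuracy = val_acc)
      if (verbose)
        message(sprintf("epoch %d  loss %.4f  val_loss %s val_acc %s", ep, ep_loss / n,
                        ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss)),
                        ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
      if (stop_now) break
    }
  })
  if (!is.null(val_samples) && is.finite(best$loss)) backbone$weights <- best$weights
  backbone$trained <- TRUE
  backbone$history <- dplyr::bind_rows(hist)
  backbone
}

softmax2 <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' @export
embed.cnn_backbone <- function(adapter, images, ...) {
  imgs <- as_image_list(images, adapter$input_side)
  out <- t(vapply(imgs, function(im) cnn_forward(adapter, im)$emb,
                  numeric(adapter$embedding_dim)))
  dimnames(out) <- list(NULL, paste0("emb_", seq_len(adapter$embedding_dim)))
  out
}

#' @export
predict_proba.cnn_backbone <- function(object, images, ...) {
  imgs <- as_image_list(images, object$input_side)
  vapply(imgs, function(im) softmax2(cnn_forward(object, im)$logits)[2], numeric(1))
}

#' @export
trace_conv.cnn_backbone <- function(adapter, image, target_class = NULL, ...) {
  img <- as_image_list(image, adapter$input_side)[[1]]
  fw <- cnn_forward(adapter, img)
  if (is.null(target_class)) target_class <- which.max(fw$logits) - 1L
  col <- as.integer(target_class) + 1L
  hw <- prod(dim(fw$a3)[1:2])
  ## head is GAP + dense, so d(logit_c)/dA[i,j,k] = Wd[k, c] / (h*w) exactly
  grads <- array(rep(adapter$weights$Wd[, col], each = hw) / hw, dim = dim(fw$a3))
  conv_trace(fw$a3, grads, target_class = target_class)
}

#' Save / load backbone weights
#'
#' @param backbone a `cnn_backbone`.
#' @param path file path (RDS, R's native serialization).
#' @return `load_backbone` returns the backbone; `save_backbone` the path.
#' @export
save_backbone <- function(backbone, path) {
  saveRDS(backbone, path)
  invisible(path)
}

#' @rdname save_backbone
#' @export
load_backbone <- function(path) readRDS(path)
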