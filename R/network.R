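# Forward and backward passes over the runtime layer list. Activations are
# (H, W, C, N) arrays; the FC head works on the flattened (feature_dim x N)
# Conv6 output. Batch-norm uses batch statistics only for layers that are both
# trainable and in training mode, so frozen layers stay bit-identical
# (including their running statistics) across training.

conv_block_fwd <- function(cb, x, training) {
  y0 <- conv_fwd(x, cb$w, cb$b, cb$stride, cb$pad)
  r <- bn_fwd(y0, cb$bn, training)
  y <- if (isTRUE(cb$act)) relu_fwd(r$y) else r$y
  list(y = y, bn = r$bn, cache = list(x = x, bnc = r$cache, y = y))
}

conv_block_bwd <- function(cb, cache, dy, need_dx, need_dw) {
  if (isTRUE(cb$act)) dy <- relu_bwd(dy, cache$y)
  bnb <- bn_bwd(dy, cache$bnc, cb$bn$gamma)
  cvb <- conv_bwd(cache$x, cb$w, bnb$dx, cb$stride, cb$pad, need_dx, need_dw)
  grads <- if (need_dw) {
    list(w = cvb$dw, b = cvb$db, gamma = bnb$dgamma, beta = bnb$dbeta)
  } else NULL
  list(dx = cvb$dx, grads = grads)
}

resunit_fwd <- function(unit, x, training) {
  c1 <- conv_block_fwd(unit$convs[[1]], x, training)
  c2 <- conv_block_fwd(unit$convs[[2]], c1$y, training)
  c3 <- conv_block_fwd(unit$convs[[3]], c2$y, training)
  unit$convs[[1]]$bn <- c1$bn
  unit$convs[[2]]$bn <- c2$bn
  unit$convs[[3]]$bn <- c3$bn
  if (is.null(unit$shortcut)) {
    short_y <- x
    sc <- NULL
  } else {
    sc <- conv_block_fwd(unit$shortcut, x, training)
    unit$shortcut$bn <- sc$bn
    short_y <- sc$y
  }
  y <- relu_fwd(c3$y + short_y)
  list(y = y, unit = unit,
       cache = list(c1 = c1$cache, c2 = c2$cache, c3 = c3$cache,
                    sc = if (is.null(sc)) NULL else sc$cache, y = y))
}

resunit_bwd <- function(unit, cache, dy, need_dx, need_dw) {
  dsum <- relu_bwd(dy, cache$y)
  b3 <- conv_block_bwd(unit$convs[[3]], cache$c3, dsum, TRUE, need_dw)
  b2 <- conv_block_bwd(unit$convs[[2]], cache$c2, b3$dx, TRUE, need_dw)
  b1 <- conv_block_bwd(unit$convs[[1]], cache$c1, b2$dx, need_dx, need_dw)
  grads <- list(convs = list(b1$grads, b2$grads, b3$grads), shortcut = NULL)
  dx <- NULL
  if (is.null(unit$shortcut)) {
    if (need_dx) dx <- b1$dx + dsum
  } else {
    bs <- conv_block_bwd(unit$shortcut, cache$sc, dsum, need_dx, need_dw)
    grads$shortcut <- bs$grads
    if (need_dx) dx <- b1$dx + bs$dx
  }
  list(dx = dx, grads = if (need_dw) grads else NULL)
}

# Forward pass. `capture` records the post-activation output of the named
# layers; `stop_after` short-circuits once that layer has run (e.g. "Conv6"
# for feature extraction). With training = TRUE the returned `model` carries
# updated batch-norm running statistics.
net_forward <- function(model, x, training = FALSE, capture = character(),
                        want_cache = FALSE, stop_after = NULL) {
  x <- as_batch(x)
  side <- model$spec$input_side
  if (!identical(dim(x)[1:3], c(side, side, 3L))) {
    stop("input must be ", side, "x", side, "x3 (got ",
         paste(dim(x)[1:3], collapse = "x"), ")")
  }
  caches <- if (want_cache) vector("list", length(model$layers)) else NULL
  captured <- list()
  feature <- NULL
  logits <- NULL
  probs <- NULL
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    train_here <- training && isTRUE(ly$trainable)
    if (ly$type == "conv") {
      r <- conv_block_fwd(ly, x, train_here)
      model$layers[[i]]$bn <- r$bn
      x <- r$y
      if (want_cache) caches[[i]] <- r$cache
    } else if (ly$type == "maxpool") {
      r <- maxpool_fwd(x, ly$k, ly$stride, ly$pad)
      if (want_cache) caches[[i]] <- list(idx = r$idx, xdim = dim(x))
      x <- r$y
    } else if (ly$type == "resunit") {
      r <- resunit_fwd(ly, x, train_here)
      model$layers[[i]] <- r$unit
      x <- r$y
      if (want_cache) caches[[i]] <- r$cache
    } else if (ly$type == "fc") {
      feature <- matrix(x, nrow = model$spec$feature_dim)
      logits <- ly$W %*% feature + ly$b
      if (want_cache) caches[[i]] <- list(feature = feature)
      x <- logits
    } else if (ly$type == "softmax") {
      z <- sweep(logits, 2, apply(logits, 2, max), "-")
      ez <- exp(z)
      probs <- sweep(ez, 2, colSums(ez), "/")
      x <- probs
    } else if (ly$type == "classification") {
      x <- probs
    }
    nm <- model$layers[[i]]$name
    if (nm %in% capture) captured[[nm]] <- x
    if (!is.null(stop_after) && identical(nm, stop_after)) break
  }
  if (is.null(feature) && !is.null(stop_after) && stop_after == "Conv6") {
    feature <- matrix(x, nrow = model$spec$feature_dim)
  }
  list(feature = feature, logits = logits, probs = probs,
       captured = captured, caches = caches, model = model)
}

first_trainable_index <- function(model) {
  for (i in seq_along(model$layers)) {
    if (isTRUE(model$layers[[i]]$trainable)) return(i)
  }
  Inf
}

# Backward pass from the FC logits gradient; returns per-layer gradients
# (NULL for frozen or parameter-free layers).
net_backward <- function(model, caches, dlogits) {
  grads <- vector("list", length(model$layers))
  first_tr <- first_trainable_index(model)
  dx <- NULL
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    if (ly$type %in% c("softmax", "classification")) next
    if (i < first_tr) break
    need_dx <- i > first_tr
    need_dw <- isTRUE(ly$trainable)
    if (ly$type == "fc") {
      feat <- caches[[i]]$feature
      if (need_dw) {
        grads[[i]] <- list(W = dlogits %*% t(feat), b = rowSums(dlogits))
      }
      if (need_dx) {
        # FC consumes the flattened 1x1x2048 Conv6 output
        dfeat <- t(ly$W) %*% dlogits
        dx <- array(dfeat, dim = c(1L, 1L, model$spec$feature_dim,
                                   ncol(dlogits)))
      }
    } else if (ly$type == "conv") {
      r <- conv_block_bwd(ly, caches[[i]], dx, need_dx, need_dw)
      grads[[i]] <- r$grads
      dx <- r$dx
    } else if (ly$type == "maxpool") {
      if (need_dx) dx <- maxpool_bwd(dx, caches[[i]]$idx, caches[[i]]$xdim)
    } else if (ly$type == "resunit") {
      r <- resunit_bwd(ly, caches[[i]], dx, need_dx, need_dw)
      grads[[i]] <- r$grads
      dx <- r$dx
    }
  }
  grads
}

#' Extract deep feature vectors
#'
#' Runs images through the network up to and including Conv6 (batch
#' normalization in inference mode, rectified output) and returns one
#' 2048-dimensional feature vector per image.
#'
#' @param model a `cbmir_model`.
#' @param images an (H, W, 3) image or (H, W, 3, N) batch sized to the
#'   model's input side.
#' @param batch_size forward-pass batch size.
#' @return an N x feature_dim numeric matrix, one row per image.
#' @export
extract_features <- function(model, images, batch_size = 16L) {
  images <- as_batch(images)
  N <- dim(images)[4]
  out <- matrix(NA_real_, N, model$spec$feature_dim)
  for (s in split(seq_len(N), ceiling(seq_len(N) / batch_size))) {
    fw <- net_forward(model, images[, , , s, drop = FALSE],
                      stop_after = "Conv6")
    out[s, ] <- t(fw$feature)
  }
  out
}

#' @rdname extract_features
#' @export
extract_feature <- function(model, images) {
  drop(extract_features(model, images))
}

#' Flattened activations of an intermediate layer
#'
#' @inheritParams extract_features
#' @param layer name of a layer in the spec (e.g. "Conv2-1", "Conv5-1",
#'   "Conv6", "FC", "Classification").
#' @return an N x d matrix of flattened activations at that layer.
#' @export
extract_intermediate <- function(model, images, layer, batch_size = 16L) {
  if (!layer %in% spec_layer_names(model$spec)) {
    stop("unknown layer: ", layer)
  }
  images <- as_batch(images)
  N <- dim(images)[4]
  rows <- vector("list", 0)
  for (s in split(seq_len(N), ceiling(seq_len(N) / batch_size))) {
    fw <- net_forward(model, images[, , , s, drop = FALSE],
                      capture = layer, stop_after = layer)
    a <- fw$captured[[layer]]
    m <- if (is.matrix(a)) t(a) else t(matrix(a, ncol = length(s)))
    rows[[length(rows) + 1L]] <- m
  }
  do.call(rbind, rows)
}

#' Closed-world class prediction through the softmax head
#'
#' @inheritParams extract_features
#' @return list with integer `labels` (1-based class indices) and the
#'   `probs` matrix (classes x images).
#' @export
predict_classes <- function(model, images, batch_size = 16L) {
  images <- as_batch(images)
  N <- dim(images)[4]
  K <- model$spec$num_classes
  probs <- matrix(NA_real_, K, N)
  for (s in split(seq_len(N), ceiling(seq_len(N) / batch_size))) {
    fw <- net_forward(model, images[, , , s, drop = FALSE])
    probs[, s] <- fw$probs
  }
  list(labels = apply(probs, 2, which.max), probs = probs)
}
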