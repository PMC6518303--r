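#' Training configuration
#'
#' Defaults follow the stochastic-gradient setup used to train the network:
#' mini-batch size 10, learning rate 0.001 dropped by a factor of 0.1 every 10
#' epochs, L2 regularization 0.0001 (weights only) and momentum 0.9, with the
#' training set reshuffled every epoch.
#'
#' @param minibatch_size images per SGD step.
#' @param learning_rate initial learning rate (0 allowed; then no update).
#' @param lr_drop_factor multiplicative drop applied each `lr_drop_period`.
#' @param lr_drop_period epochs between learning-rate drops.
#' @param l2_regularization weight-decay coefficient (conv/FC weights only,
#'   not biases or batch-norm parameters).
#' @param momentum classical momentum coefficient.
#' @param epochs number of passes over the training set.
#' @param seed seed controlling shuffling (one stream for the whole run).
#' @param fine_tune_fraction fraction of layers trained when fine-tuning.
#' @param shuffle_each_epoch reshuffle sample order every epoch.
#' @return a `cbmir_train_config` list.
#' @export
train_config <- function(minibatch_size = 10L, learning_rate = 0.001,
                         lr_drop_factor = 0.1, lr_drop_period = 10L,
                         l2_regularization = 1e-4, momentum = 0.9,
                         epochs = 30L, seed = 1L,
                         fine_tune_fraction = 0.30,
                         shuffle_each_epoch = TRUE) {
  cfg <- list(minibatch_size = as.integer(minibatch_size),
              learning_rate = learning_rate,
              lr_drop_factor = lr_drop_factor,
              lr_drop_period = as.integer(lr_drop_period),
              l2_regularization = l2_regularization,
              momentum = momentum, epochs = as.integer(epochs),
              seed = as.integer(seed),
              fine_tune_fraction = fine_tune_fraction,
              shuffle_each_epoch = isTRUE(shuffle_each_epoch))
  if (cfg$minibatch_size < 1L || cfg$epochs < 1L || cfg$lr_drop_period < 1L) {
    stop("minibatch_size, epochs and lr_drop_period must be >= 1")
  }
  if (cfg$learning_rate < 0 || cfg$lr_drop_factor <= 0 ||
        cfg$l2_regularization < 0 || cfg$momentum < 0) {
    stop("negative training scalars are not allowed")
  }
  if (cfg$fine_tune_fraction <= 0 || cfg$fine_tune_fraction > 1) {
    stop("fine_tune_fraction must be in (0, 1]")
  }
  structure(cfg, class = "cbmir_train_config")
}

#' Learning rate at a given epoch
#'
#' `lr(e) = learning_rate * lr_drop_factor ^ floor((e - 1) / lr_drop_period)`;
#' with the defaults, epoch 11 trains at 0.0001.
#'
#' @param config a [train_config()].
#' @param epoch 1-based epoch number.
#' @export
lr_schedule <- function(config, epoch) {
  config$learning_rate *
    config$lr_drop_factor ^ floor((epoch - 1) / config$lr_drop_period)
}

#' Replicate a single-channel image to three channels
#'
#' Single-channel modalities (CT, MRI, X-ray, ultrasound) are made
#' 3-channel by copying the first channel into the second and third;
#' 3-channel input passes through unchanged.
#'
#' @param image an (H, W) matrix, (H, W, 1) or (H, W, 3) array.
#' @return an (H, W, 3) array.
#' @export
gray_to_3channel <- function(image) {
  d <- dim(image)
  if (length(d) == 2L) {
    return(array(image, c(d, 3L)))
  }
  if (length(d) == 3L && d[3] == 1L) {
    return(array(image[, , 1L], c(d[1], d[2], 3L)))
  }
  if (length(d) == 3L && d[3] == 3L) {
    return(image)
  }
  stop("expected a 1- or 3-channel image; got channel count ",
       if (length(d) == 3L) d[3] else length(d))
}

#' Class-balance augmentation arithmetic
#'
#' For a class with fewer training images than the balanced target, the
#' number of augmented images to generate and the imbalance ratio (the
#' percentage of the balanced set contributed by augmentation).
#'
#' @param original_count images originally available (>= 1).
#' @param target balanced per-class size (default 500).
#' @return list with `augmented_needed` and `imbalance_ratio` (percent).
#' @export
balance_class <- function(original_count, target = 500L) {
  original_count <- as.integer(original_count)
  target <- as.integer(target)
  if (is.na(original_count) || original_count < 1L) {
    stop("original_count must be >= 1")
  }
  if (is.na(target) || target < original_count) {
    stop("target (", target, ") is below original_count (", original_count,
         "); downsampling is not an augmentation operation")
  }
  needed <- target - original_count
  list(augmented_needed = needed, imbalance_ratio = 100 * needed / target)
}

#' Augmentation policy
#'
#' Label-preserving perturbations used to balance under-represented classes:
#' in-plane rotation, translation and cropping (re-resized to the input
#' size). Magnitudes default to mild values.
#'
#' @param max_translation maximum shift as a fraction of the image side.
#' @param crop_fraction_range (low, high) crop side as a fraction of the
#'   image side; within (0, 1].
#' @param max_rotation maximum in-plane rotation in degrees.
#' @param seed policy seed; together with the draw counter it makes every
#'   augmented image reproducible.
#' @export
augmentation_policy <- function(max_translation = 0.1,
                                crop_fraction_range = c(0.9, 1.0),
                                max_rotation = 15, seed = 1L) {
  if (max_translation < 0 || max_rotation < 0) {
    stop("augmentation magnitudes must be non-negative")
  }
  if (length(crop_fraction_range) != 2L ||
        crop_fraction_range[1] <= 0 || crop_fraction_range[2] > 1 ||
        crop_fraction_range[1] > crop_fraction_range[2]) {
    stop("crop_fraction_range must be (low, high) within (0, 1]")
  }
  structure(list(max_translation = max_translation,
                 crop_fraction_range = crop_fraction_range,
                 max_rotation = max_rotation, seed = as.integer(seed)),
            class = "cbmir_augmentation_policy")
}

#' Randomly augment one image
#'
#' Applies a random in-plane rotation, translation and crop (re-resized to
#' the original size) drawn deterministically from `(policy$seed, draw)`.
#'
#' @param image an (H, W, 3) array.
#' @param policy an [augmentation_policy()].
#' @param draw integer draw counter; the same (seed, draw) pair always
#'   produces the same output.
#' @return an augmented image with the input dimensions.
#' @export
augment_image <- function(image, policy = augmentation_policy(), draw = 1L) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) {
    stop("augment_image expects an (H, W, 3) image")
  }
  if (policy$max_translation > 1) {
    stop("max_translation exceeds the image extent")
  }
  with_seed(policy$seed + 7919L * as.integer(draw), {
    ang <- if (policy$max_rotation > 0) {
      stats::runif(1, -policy$max_rotation, policy$max_rotation)
    } else 0
    tx <- if (policy$max_translation > 0) {
      stats::runif(1, -policy$max_translation, policy$max_translation) * d[2]
    } else 0
    ty <- if (policy$max_translation > 0) {
      stats::runif(1, -policy$max_translation, policy$max_translation) * d[1]
    } else 0
    f <- stats::runif(1, policy$crop_fraction_range[1],
                      policy$crop_fraction_range[2])
    out <- affine_image(image, ang, tx, ty)
    if (f < 1) {
      h <- max(1, round(f * d[1]))
      w <- max(1, round(f * d[2]))
      r0 <- 1 + stats::runif(1, 0, d[1] - h)
      c0 <- 1 + stats::runif(1, 0, d[2] - w)
      out <- crop_resize(out, r0, c0, h, w, d[1], d[2])
    }
    out
  })
}

#' Augment under-represented classes up to a balanced target
#'
#' Classes below `target` images are topped up with [augment_image()] copies
#' of randomly chosen originals; classes at or above `target` are untouched.
#'
#' @param x (H, W, 3, N) image batch.
#' @param y integer class labels of length N.
#' @param target balanced per-class size.
#' @param policy an [augmentation_policy()].
#' @param seed seed for choosing which originals get augmented.
#' @return list with the enlarged `x`, `y` and logical `augmented` flags.
#' @export
balance_images <- function(x, y, target = 500L, policy = augmentation_policy(),
                           seed = 1L) {
  x <- as_batch(x)
  counts <- table(y)
  extra <- list()
  extra_y <- integer()
  draw <- 0L
  with_seed(seed, {
    for (cl in names(counts)) {
      n <- counts[[cl]]
      if (n >= target) next
      need <- balance_class(n, target)$augmented_needed
      src <- which(y == as.integer(cl))
      pick <- sample(src, need, replace = TRUE)
      for (p in pick) {
        draw <- draw + 1L
        extra[[length(extra) + 1L]] <-
          augment_image(x[, , , p], policy, draw = draw)
        extra_y <- c(extra_y, as.integer(cl))
      }
    }
  })
  if (!length(extra)) {
    return(list(x = x, y = y, augmented = rep(FALSE, length(y))))
  }
  d <- dim(x)
  out <- array(NA_real_, c(d[1], d[2], d[3], d[4] + length(extra)))
  out[, , , seq_len(d[4])] <- x
  for (i in seq_along(extra)) out[, , , d[4] + i] <- extra[[i]]
  list(x = out, y = c(y, extra_y),
       augmented = c(rep(FALSE, length(y)), rep(TRUE, length(extra_y))))
}

#' Freeze leading layers for transfer learning
#'
#' Marks the trailing `ceiling(fraction * L)` entries of the ordered named
#' layer list (L = all named layers, softmax and classification included) as
#' trainable and freezes the rest; frozen layers receive no weight updates and
#' keep their batch-norm statistics fixed. With the default architecture and
#' `fraction = 0.30`, Conv1 through Conv4 are frozen and Conv5, Conv6 and the
#' FC head train.
#'
#' @param model a `cbmir_model`.
#' @param fraction fraction of layers to train, in (0, 1].
#' @export
freeze_for_transfer <- function(model, fraction = 0.30) {
  stopifnot(inherits(model, "cbmir_model"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  L <- length(model$layers)
  n_train <- ceiling(fraction * L)
  boundary <- L - n_train + 1L
  for (i in seq_along(model$layers)) {
    if (!is.null(model$layers[[i]]$trainable)) {
      model$layers[[i]]$trainable <- i >= boundary
    }
  }
  model
}

trainable_layer_names <- function(model) {
  keep <- vapply(model$layers,
                 function(l) isTRUE(l$trainable), logical(1))
  vapply(model$layers[keep], `[[`, character(1), "name")
}

update_conv_block <- function(cb, g, v, lr, mom, l2) {
  if (is.null(v)) v <- list(w = 0, b = 0, gamma = 0, beta = 0)
  v$w <- mom * v$w - lr * (g$w + l2 * cb$w)
  cb$w <- cb$w + v$w
  v$b <- mom * v$b - lr * g$b
  cb$b <- cb$b + v$b
  v$gamma <- mom * v$gamma - lr * g$gamma
  cb$bn$gamma <- cb$bn$gamma + v$gamma
  v$beta <- mom * v$beta - lr * g$beta
  cb$bn$beta <- cb$bn$beta + v$beta
  list(cb = cb, v = v)
}

sgd_step <- function(model, grads, vel, lr, mom, l2) {
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    if (is.null(g)) next
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      r <- update_conv_block(ly, g, vel[[i]], lr, mom, l2)
      r$cb$type <- ly$type
      r$cb$name <- ly$name
      r$cb$trainable <- ly$trainable
      model$layers[[i]] <- r$cb
      vel[[i]] <- r$v
    } else if (ly$type == "resunit") {
      if (is.null(vel[[i]])) {
        vel[[i]] <- list(convs = vector("list", 3L), shortcut = NULL)
      }
      for (k in 1:3) {
        r <- update_conv_block(ly$convs[[k]], g$convs[[k]],
                               vel[[i]]$convs[[k]], lr, mom, l2)
        ly$convs[[k]] <- r$cb
        vel[[i]]$convs[[k]] <- r$v
      }
      if (!is.null(ly$shortcut)) {
        r <- update_conv_block(ly$shortcut, g$shortcut, vel[[i]]$shortcut,
                               lr, mom, l2)
        ly$shortcut <- r$cb
        vel[[i]]$shortcut <- r$v
      }
      model$layers[[i]] <- ly
    } else if (ly$type == "fc") {
      if (is.null(vel[[i]])) vel[[i]] <- list(W = 0, b = 0)
      vel[[i]]$W <- mom * vel[[i]]$W - lr * (g$W + l2 * ly$W)
      model$layers[[i]]$W <- ly$W + vel[[i]]$W
      vel[[i]]$b <- mom * vel[[i]]$b - lr * g$b
      model$layers[[i]]$b <- ly$b + vel[[i]]$b
    }
  }
  list(model = model, vel = vel)
}

#' Train the network with stochastic gradient descent
#'
#' Mini-batch SGD with momentum, L2 weight decay on weights only, the stepped
#' learning-rate schedule of [lr_schedule()], and per-epoch reshuffling. The
#' weights kept are those of the epoch with minimum training loss (maximum
#' training accuracy breaking ties).
#'
#' @param model a `cbmir_model` (optionally after [freeze_for_transfer()]).
#' @param x (H, W, 3, N) training images sized to the model input side.
#' @param y integer labels in 1..num_classes.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return a `cbmir_fit` list: `model` (best-epoch weights), `final_model`
#'   (last-epoch weights) and `history` (data.frame epoch/loss/accuracy/lr).
#' @export
fit <- function(model, x, y, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "cbmir_model"))
  x <- as_batch(x)
  N <- dim(x)[4]
  if (N == 0L || length(y) != N) stop("empty dataset or label length mismatch")
  y <- as.integer(y)
  K <- model$spec$num_classes
  if (any(is.na(y)) || any(y < 1L) || any(y > K)) {
    stop("labels must lie in 1..", K)
  }
  vel <- vector("list", length(model$layers))
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric(), lr = numeric())
  best <- list(loss = Inf, acc = -Inf, layers = NULL)
  with_seed(config$seed, {
    for (e in seq_len(config$epochs)) {
      lr <- lr_schedule(config, e)
      ord <- if (config$shuffle_each_epoch) sample.int(N) else seq_len(N)
      batches <- split(ord, ceiling(seq_along(ord) / config$minibatch_size))
      tot_loss <- 0
      tot_correct <- 0L
      for (b in batches) {
        xb <- x[, , , b, drop = FALSE]
        yb <- y[b]
        fw <- net_forward(model, xb, training = TRUE, want_cache = TRUE)
        model <- fw$model
        sm <- softmax_xent(fw$logits, yb)
        tot_loss <- tot_loss + sm$loss * length(b)
        tot_correct <- tot_correct + sum(apply(sm$probs, 2, which.max) == yb)
        if (lr > 0) {
          grads <- net_backward(model, fw$caches, sm$dlogits)
          st <- sgd_step(model, grads, vel, lr, config$momentum,
                         config$l2_regularization)
          model <- st$model
          vel <- st$vel
        }
      }
      loss <- tot_loss / N
      acc <- tot_correct / N
      history[e, ] <- list(e, loss, acc, lr)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  accuracy %.4f  lr %.2g",
                        e, loss, acc, lr))
      }
      if (loss < best$loss - 1e-12 ||
            (abs(loss - best$loss) <= 1e-12 && acc > best$acc)) {
        best$loss <- loss
        best$acc <- acc
        best$layers <- model$layers
      }
    }
  })
  best_model <- model
  if (!is.null(best$layers)) best_model$layers <- best$layers
  structure(list(model = best_model, final_model = model, history = history),
            class = "cbmir_fit")
}
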