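# Shared fixtures. Models are cached per session because weight
# initialization of the full stack is not free.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- make()
  .fixture_env[[key]]
}

# small default build: 5 classes, 32px input (Conv5 output 1x1, Conv6 1x1)
tiny_model <- function() {
  cached("tiny_model", function() build_feature_extractor(5L, 32L, seed = 42L))
}

# 64px build used for shape/feature tests (Conv5 output 2x2)
small_model <- function() {
  cached("small_model", function() build_feature_extractor(5L, 64L, seed = 42L))
}

# deterministic small image batch from the synthetic generator (in memory)
synth_batch <- function(K = 3L, n = 6L, side = 32L, seed = 5L,
                        affine_magnitude = 0.15, noise_sd = 0.02) {
  spec <- synthetic_spec(K = K, n_per_class = n, image_side = side,
                         seed = seed, affine_magnitude = affine_magnitude,
                         noise_sd = noise_sd, illumination = 0.05)
  protos <- cbmir:::synthetic_prototypes(spec)
  x <- array(0, c(side, side, 3L, K * n))
  y <- integer(K * n)
  t <- 0L
  for (k in seq_len(K)) {
    for (i in seq_len(n)) {
      t <- t + 1L
      img <- cbmir:::synth_image(protos[[k]], spec$channels[k], spec,
                                 spec$seed + 100003L * k + 17L * i)
      x[, , , t] <- gray_to_3channel(img)
      y[t] <- k
    }
  }
  list(x = x, y = y)
}

model_checksums <- function(model, layers = NULL, stats = TRUE) {
  bn_sum <- function(bn) {
    sum(bn$gamma) + sum(bn$beta) +
      if (stats) sum(bn$running_mean) + sum(bn$running_var) else 0
  }
  sums <- c()
  for (ly in model$layers) {
    if (!is.null(layers) && !ly$name %in% layers) next
    if (ly$type == "conv") {
      sums[ly$name] <- sum(ly$w) + sum(ly$b) + bn_sum(ly$bn)
    } else if (ly$type == "resunit") {
      s <- 0
      for (cb in c(ly$convs, list(ly$shortcut))) {
        if (is.null(cb)) next
        s <- s + sum(cb$w) + sum(cb$b) + bn_sum(cb$bn)
      }
      sums[ly$name] <- s
    } else if (ly$type == "fc") {
      sums[ly$name] <- sum(ly$W) + sum(ly$b)
    }
  }
  sums
}

`%||%` <- function(a, b) if (is.null(a)) b else a
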