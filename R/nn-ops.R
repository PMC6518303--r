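#' @useDynLib cbmir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || !length(d) %in% c(3L, 4L)) {
    stop("expected an (H, W, C) image or an (H, W, C, N) batch")
  }
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

conv_fwd <- function(x, w, b, stride, pad) {
  cpp_conv_fwd(x, w, b, as.integer(stride), as.integer(pad))
}

conv_bwd <- function(x, w, dy, stride, pad, need_dx = TRUE, need_dw = TRUE) {
  cpp_conv_bwd(x, w, dy, as.integer(stride), as.integer(pad), need_dx, need_dw)
}

maxpool_fwd <- function(x, k, stride, pad) {
  cpp_maxpool_fwd(x, as.integer(k), as.integer(stride), as.integer(pad))
}

maxpool_bwd <- function(dy, idx, xdim) {
  cpp_maxpool_bwd(dy, idx, as.integer(xdim))
}

# --- batch normalization over the channel axis of an (H, W, C, N) array ---
# Per-channel statistics are taken over (H, W, N); the heavy elementwise
# passes run in compiled one-pass kernels.

bn_new <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       running_mean = rep(0, C), running_var = rep(1, C))
}

bn_fwd <- function(x, bn, training, eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mo <- cpp_bn_moments(x)
    mu <- mo$sum / m
    v <- pmax(mo$sumsq / m - mu * mu, 0)
    bn$running_mean <- (1 - momentum) * bn$running_mean + momentum * mu
    bn$running_var <- (1 - momentum) * bn$running_var + momentum * v
  } else {
    mu <- bn$running_mean
    v <- bn$running_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  y <- cpp_scale_shift(x, bn$gamma * inv_sd,
                       bn$beta - bn$gamma * inv_sd * mu)
  cache <- list(x = x, mu = mu, inv_sd = inv_sd, m = m, eval = !training)
  list(y = y, bn = bn, cache = cache)
}

bn_bwd <- function(dy, cache, gamma) {
  inv_sd <- cache$inv_sd
  C <- length(inv_sd)
  if (isTRUE(cache$eval)) {
    # inference statistics are constants: dx = dy * gamma * inv_sd
    dx <- cpp_scale_shift(dy, gamma * inv_sd, numeric(C))
    return(list(dx = dx, dgamma = numeric(C), dbeta = numeric(C)))
  }
  dots <- cpp_bn_dots(dy, cache$x)
  s_dy <- dots$sum_dy
  s_dyx_hat <- inv_sd * (dots$sum_dyx - cache$mu * s_dy)
  m <- cache$m
  A <- gamma * inv_sd
  B <- -(gamma * inv_sd^2 / m) * s_dyx_hat
  C0 <- -(gamma * inv_sd / m) * s_dy - B * cache$mu
  dx <- cpp_axpb(dy, cache$x, A, B, C0)
  list(dx = dx, dgamma = s_dyx_hat, dbeta = s_dy)
}

relu_fwd <- function(x) {
  cpp_relu_fwd(x)
}

relu_bwd <- function(dy, y) {
  cpp_relu_bwd(dy, y)
}

# softmax cross-entropy on logits (K x N) with integer labels in 1..K
softmax_xent <- function(logits, labels) {
  K <- nrow(logits)
  N <- ncol(logits)
  z <- sweep(logits, 2, apply(logits, 2, max), "-")
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  picked <- p[cbind(labels, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-300)))
  dlogits <- p
  dlogits[cbind(labels, seq_len(N))] <- dlogits[cbind(labels, seq_len(N))] - 1
  dlogits <- dlogits / N
  list(loss = loss, probs = p, dlogits = dlogits)
}
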