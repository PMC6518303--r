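#' Layer table of the modified residual network
#'
#' Builds the ordered layer specification of the 50-layer residual feature
#' extractor in which the terminal 7x7 global average pooling of a standard
#' ResNet50 is replaced by a learnable full-spatial convolution ("Conv6") with
#' 2048 filters, so the 2048-dimensional feature vector is produced by trained
#' filter weights rather than fixed averaging. The stack is
#' Conv1 -> MaxPool -> four residual groups (Conv2..Conv5, each one projection
#' unit followed by identity units) -> Conv6 -> FC -> SoftMax -> Classification.
#'
#' @param num_classes number of output classes (>= 2); width of the FC head.
#' @param input_side input image side in pixels; must be divisible by 32 so
#'   the stride arithmetic of the residual groups closes and Conv6 can cover
#'   the full terminal spatial extent (`input_side / 32`).
#' @return an object of class `cbmir_network_spec`: a list with `layers` (one
#'   entry per named layer; residual units carry their convolution sublayers),
#'   `num_classes`, `input_side` and `feature_dim` (2048).
#' @export
network_spec <- function(num_classes, input_side = 224L) {
  num_classes <- as.integer(num_classes)
  input_side <- as.integer(input_side)
  if (is.na(num_classes) || num_classes < 2L) {
    stop("num_classes must be an integer >= 2")
  }
  if (is.na(input_side) || input_side < 32L || input_side %% 32L != 0L) {
    stop("input_side must be a positive multiple of 32; got ", input_side,
         " (the stride arithmetic of the residual stack requires it)")
  }

  conv_spec <- function(filters, kh, depth, stride, pad) {
    list(num_filters = filters, kernel = c(kh, kh, depth),
         stride = stride, padding = pad)
  }
  layer <- function(name, kind, filters = NA_integer_, kernel = NULL,
                    stride = NA_integer_, padding = NA_integer_,
                    sublayers = NULL) {
    list(name = name, kind = kind, num_filters = filters, kernel = kernel,
         stride = stride, padding = padding, repeats = 1L,
         sublayers = sublayers)
  }

  groups <- list(
    list(name = "Conv2", width = 64L,  out = 256L,  n_identity = 2L, stride = 1L),
    list(name = "Conv3", width = 128L, out = 512L,  n_identity = 3L, stride = 2L),
    list(name = "Conv4", width = 256L, out = 1024L, n_identity = 5L, stride = 2L),
    list(name = "Conv5", width = 512L, out = 2048L, n_identity = 2L, stride = 2L)
  )

  layers <- list(
    layer("Conv1", "convolution", 64L, c(7L, 7L, 3L), 2L, 3L),
    layer("MaxPool", "max-pool", 1L, c(3L, 3L, 64L), 2L, 1L)
  )
  in_depth <- 64L
  for (g in groups) {
    # projection unit: main path 1x1 -> 3x3 -> 1x1 plus a 1x1 shortcut; the
    # downsampling stride sits on the first 1x1 and on the shortcut
    proj <- list(
      conv_spec(g$width, 1L, in_depth, g$stride, 0L),
      conv_spec(g$width, 3L, g$width, 1L, 1L),
      conv_spec(g$out, 1L, g$width, 1L, 0L),
      conv_spec(g$out, 1L, in_depth, g$stride, 0L)
    )
    layers[[length(layers) + 1L]] <-
      layer(paste0(g$name, "-1"), "residual-projection", g$out,
            sublayers = proj)
    for (i in seq_len(g$n_identity)) {
      ident <- list(
        conv_spec(g$width, 1L, g$out, 1L, 0L),
        conv_spec(g$width, 3L, g$width, 1L, 1L),
        conv_spec(g$out, 1L, g$width, 1L, 0L)
      )
      layers[[length(layers) + 1L]] <-
        layer(paste0(g$name, "-", i + 1L), "residual-identity", g$out,
              sublayers = ident)
    }
    in_depth <- g$out
  }
  tail_side <- input_side %/% 32L
  layers[[length(layers) + 1L]] <-
    layer("Conv6", "convolution", 2048L, c(tail_side, tail_side, 2048L), 1L, 0L)
  layers[[length(layers) + 1L]] <- layer("FC", "fully-connected", num_classes)
  layers[[length(layers) + 1L]] <- layer("SoftMax", "softmax", num_classes)
  layers[[length(layers) + 1L]] <-
    layer("Classification", "classification", num_classes)

  structure(
    list(layers = layers, num_classes = num_classes,
         input_side = input_side, feature_dim = 2048L),
    class = "cbmir_network_spec"
  )
}

#' @export
print.cbmir_network_spec <- function(x, ...) {
  cat("<cbmir_network_spec>", length(x$layers), "named layers,",
      x$num_classes, "classes, input side", x$input_side,
      ", feature dim", x$feature_dim, "\n")
  invisible(x)
}

spec_layer_names <- function(spec) {
  vapply(spec$layers, `[[`, character(1), "name")
}

he_init <- function(kh, kw, depth, filters) {
  fan_in <- kh * kw * depth
  array(stats::rnorm(kh * kw * depth * filters, 0, sqrt(2 / fan_in)),
        dim = c(kh, kw, depth, filters))
}

init_conv_block <- function(cs, act = TRUE) {
  k <- cs$kernel
  list(w = he_init(k[1], k[2], k[3], cs$num_filters),
       b = rep(0, cs$num_filters),
       bn = bn_new(cs$num_filters),
       stride = cs$stride, pad = cs$padding, act = act)
}

#' Build the modified residual feature extractor
#'
#' Instantiates the [network_spec()] layer stack with trainable weights.
#' Convolution weights are drawn from a fan-in-scaled Gaussian; the FC head is
#' drawn from a Gaussian with zero mean and standard deviation 0.001 with zero
#' biases. Every convolution (Conv6 included) is followed by batch
#' normalization and a rectifier, so extracted features are non-negative.
#'
#' @inheritParams network_spec
#' @param seed integer controlling all weight initialization; building twice
#'   with the same seed yields identical weights.
#' @return an object of class `cbmir_model` carrying the spec, the runtime
#'   layer list (weights, batch-norm state, trainability flags) and the seed.
#' @export
build_feature_extractor <- function(num_classes, input_side = 224L, seed = 1L) {
  spec <- network_spec(num_classes, input_side)
  layers <- with_seed(seed, {
    out <- vector("list", length(spec$layers))
    for (i in seq_along(spec$layers)) {
      ls <- spec$layers[[i]]
      out[[i]] <- switch(
        ls$kind,
        "convolution" = c(list(type = "conv", name = ls$name,
                               trainable = TRUE),
                          init_conv_block(ls, act = TRUE)),
        "max-pool" = list(type = "maxpool", name = ls$name, k = 3L,
                          stride = 2L, pad = 1L),
        "residual-projection" = ,
        "residual-identity" = {
          subs <- ls$sublayers
          convs <- list(init_conv_block(subs[[1]], act = TRUE),
                        init_conv_block(subs[[2]], act = TRUE),
                        init_conv_block(subs[[3]], act = FALSE))
          shortcut <- if (ls$kind == "residual-projection") {
            init_conv_block(subs[[4]], act = FALSE)
          } else NULL
          list(type = "resunit", name = ls$name,
               kind = if (is.null(shortcut)) "identity" else "projection",
               convs = convs, shortcut = shortcut, trainable = TRUE)
        },
        "fully-connected" = list(
          type = "fc", name = ls$name, trainable = TRUE,
          W = matrix(stats::rnorm(spec$num_classes * spec$feature_dim,
                                  0, 0.001),
                     spec$num_classes, spec$feature_dim),
          b = rep(0, spec$num_classes)),
        "softmax" = list(type = "softmax", name = ls$name),
        "classification" = list(type = "classification", name = ls$name)
      )
    }
    out
  })
  structure(list(spec = spec, layers = layers, seed = as.integer(seed)),
            class = "cbmir_model")
}

#' @export
print.cbmir_model <- function(x, ...) {
  cen <- count_residual_units(x)
  cat("<cbmir_model> modified residual feature extractor\n",
      " input ", x$spec$input_side, "x", x$spec$input_side, "x3, ",
      x$spec$num_classes, " classes, feature dim ", x$spec$feature_dim, "\n",
      " residual units: ", cen$total, " (", cen$identity, " identity + ",
      cen$projection, " projection)\n", sep = "")
  invisible(x)
}

#' Audit per-layer output shapes by a forward pass
#'
#' Runs one forward pass and records the output dimensions at every named
#' layer boundary, materializing the feature-map-size column of the
#' architecture table for inspection and testing.
#'
#' @param model a `cbmir_model`.
#' @param input_dim integer (h, w, c); c must be 3 (replicate single-channel
#'   images with [gray_to_3channel()] first).
#' @return a data.frame of class `cbmir_shape_audit` with columns
#'   `layer`, `h`, `w`, `depth`, starting with the input itself.
#' @export
audit_shapes <- function(model, input_dim = c(model$spec$input_side,
                                              model$spec$input_side, 3L)) {
  stopifnot(inherits(model, "cbmir_model"))
  input_dim <- as.integer(input_dim)
  if (length(input_dim) != 3L || any(input_dim <= 0L)) {
    stop("input_dim must be positive (h, w, c)")
  }
  if (input_dim[3] != 3L) {
    stop("input must have 3 channels; replicate grayscale input with ",
         "gray_to_3channel() before the forward pass")
  }
  x <- array(seq_len(prod(input_dim)) %% 255 / 255, dim = c(input_dim, 1L))
  nm <- spec_layer_names(model$spec)
  fw <- net_forward(model, x, training = FALSE, capture = nm)
  K <- model$spec$num_classes
  rows <- list(data.frame(layer = "Input", h = input_dim[1], w = input_dim[2],
                          depth = input_dim[3]))
  for (n in nm) {
    a <- fw$captured[[n]]
    d <- if (is.matrix(a)) c(1L, 1L, nrow(a)) else dim(a)[1:3]
    rows[[length(rows) + 1L]] <- data.frame(layer = n, h = d[1], w = d[2],
                                            depth = d[3])
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cbmir_shape_audit", "data.frame")
  out
}

#' Census of residual units
#'
#' @param model a `cbmir_model` or `cbmir_network_spec`.
#' @return list with `total`, `identity`, `projection` counts and
#'   `per_group_identity`, the identity-unit count of each residual group in
#'   order.
#' @export
count_residual_units <- function(model) {
  spec <- if (inherits(model, "cbmir_model")) model$spec else model
  stopifnot(inherits(spec, "cbmir_network_spec"))
  kinds <- vapply(spec$layers, `[[`, character(1), "kind")
  names <- spec_layer_names(spec)
  is_res <- kinds %in% c("residual-identity", "residual-projection")
  groups <- sub("-.*$", "", names[is_res])
  per_group <- vapply(unique(groups), function(g) {
    sum(kinds[is_res][groups == g] == "residual-identity")
  }, integer(1))
  list(total = sum(is_res),
       identity = sum(kinds == "residual-identity"),
       projection = sum(kinds == "residual-projection"),
       per_group_identity = per_group)
}

#' Replace the classifier head
#'
#' Re-initializes only the FC layer for a new class count (Gaussian with zero
#' mean and standard deviation 0.001, zero biases); every backbone weight is
#' left untouched, which is what permits transfer across datasets with
#' different class counts.
#'
#' @param model a `cbmir_model`.
#' @param new_num_classes new head width (>= 2).
#' @param seed seed for the head initialization.
#' @return the model with a fresh head.
#' @export
replace_head <- function(model, new_num_classes, seed = 1L) {
  stopifnot(inherits(model, "cbmir_model"))
  new_num_classes <- as.integer(new_num_classes)
  if (is.na(new_num_classes) || new_num_classes < 2L) {
    stop("new_num_classes must be an integer >= 2")
  }
  fd <- model$spec$feature_dim
  i <- which(vapply(model$layers, `[[`, character(1), "type") == "fc")
  model$layers[[i]]$W <- with_seed(seed, {
    matrix(stats::rnorm(new_num_classes * fd, 0, 0.001), new_num_classes, fd)
  })
  model$layers[[i]]$b <- rep(0, new_num_classes)
  model$spec$num_classes <- new_num_classes
  for (j in seq_along(model$spec$layers)) {
    if (model$spec$layers[[j]]$kind %in%
          c("fully-connected", "softmax", "classification")) {
      model$spec$layers[[j]]$num_filters <- new_num_classes
    }
  }
  model
}

#' Serialize a model with a JSON sidecar
#'
#' Writes the weights plus a `<path>.json` sidecar describing the
#' architecture (layer list, class count, input side, seed) so structure can
#' be audited without loading weights.
#'
#' @param model a `cbmir_model`.
#' @param path destination file.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cbmir_model"))
  saveRDS(model, path)
  side <- list(
    package = "cbmir",
    num_classes = model$spec$num_classes,
    input_side = model$spec$input_side,
    feature_dim = model$spec$feature_dim,
    seed = model$seed,
    layers = lapply(model$spec$layers, function(l) {
      list(name = l$name, kind = l$kind, num_filters = l$num_filters,
           kernel = l$kernel, stride = l$stride, padding = l$padding)
    })
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cbmir_model"))
  model
}
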