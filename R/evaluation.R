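#' Confusion matrix from label vectors
#'
#' Entry (i, j) counts samples of true class i predicted as class j.
#'
#' @param truth,pred equal-length integer label vectors with values in 1..K.
#' @param K class count.
#' @return a K x K integer matrix of class `cbmir_confusion`.
#' @export
confusion <- function(truth, pred, K) {
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  K <- as.integer(K)
  if (any(truth < 1L | truth > K) || any(pred < 1L | pred > K)) {
    stop("labels must lie in 1..", K)
  }
  cm <- table(factor(truth, levels = seq_len(K)),
              factor(pred, levels = seq_len(K)))
  cm <- matrix(as.integer(cm), K, K,
               dimnames = list(true = seq_len(K), predicted = seq_len(K)))
  class(cm) <- c("cbmir_confusion", class(cm))
  cm
}

#' One-vs-rest counts for one class
#'
#' @param cm a [confusion()] matrix.
#' @param k class index.
#' @return list with `TP`, `FP`, `FN`, `TN`; their sum equals the total
#'   sample count for every k.
#' @export
ovr_counts <- function(cm, k) {
  K <- nrow(cm)
  if (k < 1 || k > K) stop("class index out of range")
  TP <- cm[k, k]
  FP <- sum(cm[, k]) - TP
  FN <- sum(cm[k, ]) - TP
  TN <- sum(cm) - TP - FP - FN
  list(TP = TP, FP = FP, FN = FN, TN = TN)
}

#' Macro classification metrics
#'
#' One-vs-rest macro metrics over K classes: macro accuracy (the mean
#' per-class (TP+TN)/(TP+TN+FP+FN)), macro precision mAP, macro recall mAR,
#' their harmonic mean F1, and top-1 accuracy (trace/total). The printed
#' macro-recall formula of the source metric set divides by TP+TN; that
#' "literal" variant is kept available for auditability
#' (`recall_mode = "literal_eq4"`), while the default is the standard
#' TP/(TP+FN). Classes with an empty denominator contribute 0 to the macro
#' average.
#'
#' @param cm a [confusion()] matrix.
#' @param recall_mode "standard" or "literal_eq4".
#' @return a `cbmir_metrics` list: `top1_accuracy`, `macro_accuracy`, `mAP`,
#'   `mAR`, `F1`, `recall_mode`.
#' @export
macro_metrics <- function(cm, recall_mode = c("standard", "literal_eq4")) {
  recall_mode <- match.arg(recall_mode)
  K <- nrow(cm)
  total <- sum(cm)
  if (total == 0) stop("confusion matrix has no samples")
  frac0 <- function(num, den) ifelse(den > 0, num / den, 0)
  acc_k <- prec_k <- rec_k <- numeric(K)
  for (k in seq_len(K)) {
    o <- ovr_counts(cm, k)
    acc_k[k] <- (o$TP + o$TN) / total
    prec_k[k] <- frac0(o$TP, o$TP + o$FP)
    rec_k[k] <- if (recall_mode == "standard") {
      frac0(o$TP, o$TP + o$FN)
    } else {
      frac0(o$TP, o$TP + o$TN)
    }
  }
  mAP <- mean(prec_k)
  mAR <- mean(rec_k)
  F1 <- if (mAP + mAR > 0) 2 * mAP * mAR / (mAP + mAR) else 0
  structure(list(top1_accuracy = sum(diag(cm)) / total,
                 macro_accuracy = mean(acc_k),
                 mAP = mAP, mAR = mAR, F1 = F1,
                 recall_mode = recall_mode),
            class = "cbmir_metrics")
}

#' @export
print.cbmir_metrics <- function(x, ...) {
  cat(sprintf(paste0("<cbmir_metrics> top-1 %.4f | macro accuracy %.4f | ",
                     "mAP %.4f | mAR %.4f | F1 %.4f (%s recall)\n"),
              x$top1_accuracy, x$macro_accuracy, x$mAP, x$mAR, x$F1,
              x$recall_mode))
  invisible(x)
}

#' Closed-, open- and mixed-world split construction
#'
#' Two-fold cross-validation splits over a labeled image manifest.
#' Closed world: every class appears in training and testing with disjoint
#' image halves (fold 2 swaps the halves). Open world: the class set is cut
#' in half; fold 1 trains on the lower class ids and tests on the upper, fold
#' 2 swaps the class halves. Mixed world: the lower 80% of classes follow the
#' closed-world image split while the upper 20% of classes appear complete
#' and only in testing.
#'
#' @param manifest data.frame with at least `class_id` (and any id columns,
#'   carried through).
#' @param mode "closed", "open" or "mixed".
#' @param fold 1 or 2.
#' @param seed seed for the per-class image halving.
#' @return a `cbmir_world_split`: `mode`, `fold`, `train_classes`,
#'   `test_classes` and the manifest with a `split` column ("train", "test"
#'   or "unused").
#' @export
make_world_split <- function(manifest, mode = c("closed", "open", "mixed"),
                             fold = 1L, seed = 1L) {
  mode <- match.arg(mode)
  fold <- as.integer(fold)
  if (!fold %in% c(1L, 2L)) stop("fold must be 1 or 2")
  if (!"class_id" %in% names(manifest)) stop("manifest needs class_id")
  classes <- sort(unique(as.integer(manifest$class_id)))
  K <- length(classes)
  if (K < 2L) stop("need at least 2 classes")
  if (mode == "mixed" && K < 5L) {
    stop("mixed mode needs >= 5 classes to hold out a class quintile")
  }

  half_split <- function(rows, swap) {
    n <- length(rows)
    first <- sample(rows, ceiling(n / 2))
    if (swap) list(train = setdiff(rows, first), test = first)
    else list(train = first, test = setdiff(rows, first))
  }

  split <- rep("unused", nrow(manifest))
  with_seed(seed, {
    if (mode == "closed") {
      train_classes <- test_classes <- classes
      for (k in classes) {
        rows <- which(manifest$class_id == k)
        h <- half_split(rows, swap = fold == 2L)
        split[h$train] <- "train"
        split[h$test] <- "test"
      }
    } else if (mode == "open") {
      lower <- classes[seq_len(ceiling(K / 2))]
      upper <- setdiff(classes, lower)
      train_classes <- if (fold == 1L) lower else upper
      test_classes <- if (fold == 1L) upper else lower
      split[manifest$class_id %in% train_classes] <- "train"
      split[manifest$class_id %in% test_classes] <- "test"
    } else {
      n_seen <- floor(0.8 * K)
      seen <- classes[seq_len(n_seen)]
      unseen <- setdiff(classes, seen)
      train_classes <- seen
      test_classes <- classes
      for (k in seen) {
        rows <- which(manifest$class_id == k)
        h <- half_split(rows, swap = fold == 2L)
        split[h$train] <- "train"
        split[h$test] <- "test"
      }
      split[manifest$class_id %in% unseen] <- "test"
    }
  })
  manifest$split <- split
  structure(list(mode = mode, fold = fold, train_classes = train_classes,
                 test_classes = test_classes, manifest = manifest),
            class = "cbmir_world_split")
}

#' @export
print.cbmir_world_split <- function(x, ...) {
  cat("<cbmir_world_split>", x$mode, "world, fold", x$fold, "-",
      length(x$train_classes), "train classes,",
      length(x$test_classes), "test classes;",
      sum(x$manifest$split == "train"), "train /",
      sum(x$manifest$split == "test"), "test images\n")
  invisible(x)
}

#' Monte-Carlo sensitivity of classification metrics
#'
#' Repeatedly subsamples a fraction of the test predictions uniformly
#' without replacement and recomputes the metrics, summarizing their spread.
#'
#' @param truth,pred test-set label vectors.
#' @param K class count.
#' @param fraction subsample fraction in (0, 1] (default 0.2).
#' @param iterations number of subsamples (default 20).
#' @param seed master seed; each iteration draws from one seeded stream.
#' @param recall_mode passed to [macro_metrics()].
#' @return a `cbmir_sensitivity`: per-iteration data.frame of
#'   top1_accuracy/F1/mAP/mAR plus `mean` and `sd` per metric.
#' @export
monte_carlo_sensitivity <- function(truth, pred, K, fraction = 0.2,
                                    iterations = 20L, seed = 1L,
                                    recall_mode = "standard") {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")
  n <- length(truth)
  m <- max(1L, round(fraction * n))
  if (m < 1L) stop("subsample would be empty")
  rows <- with_seed(seed, {
    lapply(seq_len(iterations), function(i) {
      s <- if (fraction == 1) seq_len(n) else sample.int(n, m)
      mm <- macro_metrics(confusion(truth[s], pred[s], K), recall_mode)
      data.frame(iteration = i, top1_accuracy = mm$top1_accuracy,
                 F1 = mm$F1, mAP = mm$mAP, mAR = mm$mAR)
    })
  })
  per <- do.call(rbind, rows)
  metrics <- c("top1_accuracy", "F1", "mAP", "mAR")
  structure(list(per_iteration = per,
                 mean = vapply(per[metrics], mean, numeric(1)),
                 sd = vapply(per[metrics], stats::sd, numeric(1)),
                 fraction = fraction, iterations = iterations),
            class = "cbmir_sensitivity")
}

#' Two-sample t test of per-iteration metric values
#'
#' Welch's unequal-variance t test by default (pooled-variance optional);
#' two identical zero-variance samples report t = 0, p = 1 rather than
#' dividing by zero.
#'
#' @param values_a,values_b numeric samples (each of size >= 2).
#' @param var_equal use the pooled-variance variant.
#' @return list with `t` and two-sided `p`.
#' @export
two_sample_ttest <- function(values_a, values_b, var_equal = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each sample needs >= 2 values")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(values_a) - mean(values_b)) * Inf, p = 0))
  }
  ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

#' PCA eigenspace projection of deep features
#'
#' Centers on the training features and projects onto the leading
#' eigenvectors of their covariance. With all components retained, pairwise
#' distances (and therefore nearest-centroid classifications) are preserved.
#'
#' @param features training feature matrix (rows = vectors).
#' @param n_eigenvectors number of leading components to keep.
#' @return a `cbmir_pca`: `rotation` (dim x n), `center`, `eigenvalues`
#'   (non-increasing).
#' @export
pca_fit <- function(features, n_eigenvectors) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need >= 2 feature vectors")
  n_eigenvectors <- as.integer(n_eigenvectors)
  if (n_eigenvectors < 1L || n_eigenvectors > ncol(features)) {
    stop("n_eigenvectors must be in 1..", ncol(features))
  }
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE,
                      rank. = n_eigenvectors)
  structure(list(rotation = pc$rotation,
                 center = pc$center,
                 eigenvalues = pc$sdev[seq_len(n_eigenvectors)]^2),
            class = "cbmir_pca")
}

#' @rdname pca_fit
#' @param projection a `cbmir_pca` from [pca_fit()].
#' @export
pca_transform <- function(projection, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  sweep(as.matrix(features), 2, projection$center) %*% projection$rotation
}
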