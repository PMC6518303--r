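#' Per-class feature store
#'
#' Container for deep feature vectors grouped by class: the reference
#' database from which class mean vectors are computed and within which
#' class-scoped retrieval ranks candidates.
#'
#' @param features numeric matrix, one row per feature vector.
#' @param class_ids integer class of each row.
#' @param image_ids optional character identifiers (default `img_<i>`).
#' @return a `cbmir_feature_store`.
#' @export
feature_store <- function(features, class_ids, image_ids = NULL) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("features must be finite")
  class_ids <- as.integer(class_ids)
  if (length(class_ids) != nrow(features)) {
    stop("one class id per feature row required")
  }
  if (is.null(image_ids)) {
    image_ids <- sprintf("img_%06d", seq_len(nrow(features)))
  }
  if (anyDuplicated(image_ids)) stop("image ids must be unique")
  structure(list(features = features, class_ids = class_ids,
                 image_ids = as.character(image_ids)),
            class = "cbmir_feature_store")
}

#' @export
print.cbmir_feature_store <- function(x, ...) {
  cat("<cbmir_feature_store>", nrow(x$features), "vectors of dim",
      ncol(x$features), "in", length(unique(x$class_ids)), "classes\n")
  invisible(x)
}

store_class_counts <- function(store) {
  tab <- table(store$class_ids)
  stats::setNames(as.integer(tab), names(tab))
}

#' Build the class-centroid index
#'
#' The offline phase of the variable node classification (VNC) framework:
#' one arithmetic-mean feature vector per class.
#'
#' @param store a [feature_store()] with at least one vector per class.
#' @return a `cbmir_centroid_index`: class ids (ascending) and a K x dim
#'   matrix of mean vectors.
#' @export
build_centroid_index <- function(store) {
  stopifnot(inherits(store, "cbmir_feature_store"))
  ids <- sort(unique(store$class_ids))
  cen <- t(vapply(ids, function(k) {
    colMeans(store$features[store$class_ids == k, , drop = FALSE])
  }, numeric(ncol(store$features))))
  dimnames(cen) <- NULL
  structure(list(class_ids = ids, centroids = cen),
            class = "cbmir_centroid_index")
}

#' @export
print.cbmir_centroid_index <- function(x, ...) {
  cat("<cbmir_centroid_index>", length(x$class_ids), "class centroids of dim",
      ncol(x$centroids), "\n")
  invisible(x)
}

#' Nearest-centroid classification (VNC online phase)
#'
#' Assigns each query feature vector to the class whose mean feature vector
#' is nearest in Euclidean (L2) distance. Exact ties go to the smallest
#' class id.
#'
#' @param features a single feature vector or a matrix with one query per
#'   row.
#' @param index a `cbmir_centroid_index`.
#' @return data.frame with `class_id` and `distance` per query.
#' @export
classify_features <- function(features, index) {
  stopifnot(inherits(index, "cbmir_centroid_index"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != ncol(index$centroids)) {
    stop("feature dimension ", ncol(features),
         " does not match index dimension ", ncol(index$centroids))
  }
  if (!nrow(index$centroids)) stop("empty centroid index")
  # ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2, minimized per row
  d2 <- outer(rowSums(features^2), rep(1, nrow(index$centroids))) -
    2 * features %*% t(index$centroids) +
    outer(rep(1, nrow(features)), rowSums(index$centroids^2))
  # class ids ascend in the index, so which.min's first-match rule breaks
  # ties toward the smallest class id
  pick <- apply(d2, 1, which.min)
  # recompute the winning distance directly; the dot-product expansion can
  # lose ~1e-7 absolute precision to cancellation
  dist <- sqrt(rowSums((features - index$centroids[pick, , drop = FALSE])^2))
  data.frame(class_id = index$class_ids[pick], distance = dist)
}

#' Enroll a new class without retraining
#'
#' Adds one class to the reference database: its vectors join the store and
#' its mean vector joins the centroid index; existing centroids are left
#' untouched. This is what makes the class count variable after training
#' (open- and mixed-world operation).
#'
#' @param index a `cbmir_centroid_index` (possibly empty via
#'   [empty_centroid_index()]).
#' @param store the matching [feature_store()] (or NULL to track only the
#'   index).
#' @param new_class_id class id not already enrolled.
#' @param vectors matrix of feature vectors for the new class (>= 1 row).
#' @return list with the updated `index` and `store`.
#' @export
enroll_class <- function(index, store, new_class_id, vectors) {
  stopifnot(inherits(index, "cbmir_centroid_index"))
  new_class_id <- as.integer(new_class_id)
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  if (!nrow(vectors)) stop("need at least one vector to enroll a class")
  if (new_class_id %in% index$class_ids) {
    stop("class ", new_class_id, " is already enrolled")
  }
  if (nrow(index$centroids) && ncol(vectors) != ncol(index$centroids)) {
    stop("vector dimension does not match the index")
  }
  pos <- sum(index$class_ids < new_class_id)
  ins <- function(m, row, at) {
    rbind(m[seq_len(at), , drop = FALSE], row,
          m[setdiff(seq_len(nrow(m)), seq_len(at)), , drop = FALSE])
  }
  index$centroids <- if (nrow(index$centroids)) {
    ins(index$centroids, colMeans(vectors), pos)
  } else matrix(colMeans(vectors), nrow = 1)
  dimnames(index$centroids) <- NULL
  index$class_ids <- append(index$class_ids, new_class_id, after = pos)
  if (!is.null(store)) {
    store <- feature_store(
      rbind(store$features, vectors),
      c(store$class_ids, rep(new_class_id, nrow(vectors))),
      c(store$image_ids,
        sprintf("class%d_enrolled_%04d", new_class_id, seq_len(nrow(vectors))))
    )
  }
  list(index = index, store = store)
}

#' @rdname enroll_class
#' @param dim feature dimensionality of the index to create.
#' @export
empty_centroid_index <- function(dim) {
  structure(list(class_ids = integer(),
                 centroids = matrix(numeric(), 0, dim)),
            class = "cbmir_centroid_index")
}

#' Read and write feature stores and centroid indexes as TSV
#'
#' One row per vector with columns `image_id`, `class_id`, `f0`...; a
#' language-neutral, diffable on-disk form.
#'
#' @param store a [feature_store()].
#' @param path file path.
#' @export
write_feature_store <- function(store, path) {
  df <- data.frame(image_id = store$image_ids, class_id = store$class_ids,
                   store$features)
  names(df)[-(1:2)] <- paste0("f", seq_len(ncol(store$features)) - 1L)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_store
#' @export
read_feature_store <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  feature_store(as.matrix(df[, -(1:2), drop = FALSE]), df$class_id,
                df$image_id)
}

#' @rdname write_feature_store
#' @param index a `cbmir_centroid_index`.
#' @export
write_centroid_index <- function(index, path) {
  df <- data.frame(class_id = index$class_ids, index$centroids)
  names(df)[-1] <- paste0("f", seq_len(ncol(index$centroids)) - 1L)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_store
#' @export
read_centroid_index <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  structure(list(class_ids = as.integer(df$class_id),
                 centroids = as.matrix(df[, -1, drop = FALSE])),
            class = "cbmir_centroid_index")
}
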