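rank_within <- function(query, store, rows, top_k) {
  feats <- store$features[rows, , drop = FALSE]
  d <- sqrt(pmax(rowSums(sweep(feats, 2, query)^2), 0))
  ids <- store$image_ids[rows]
  ord <- order(d, ids)  # equal distances resolved by image id
  keep <- ord[seq_len(min(top_k, length(ord)))]
  data.frame(image_id = ids[keep], class_id = store$class_ids[rows][keep],
             distance = d[keep])
}

#' Class-prediction-based retrieval
#'
#' Predicts the query's class by nearest-centroid matching (K comparisons)
#' and ranks only that class's stored vectors by Euclidean distance
#' (n_predicted comparisons), so the comparison count is K + n_predicted
#' rather than the whole-database count.
#'
#' @param query a feature vector.
#' @param index a `cbmir_centroid_index`.
#' @param store the [feature_store()] holding the reference vectors.
#' @param top_k number of images to return (default 10).
#' @param n_fallback_classes if > 0, also report the next-nearest classes so
#'   a user can re-query them when the class prediction is wrong.
#' @return a `cbmir_retrieval_result`: query id, predicted class, the ranked
#'   (image_id, class_id, distance) table with non-decreasing distances, and
#'   `comparisons_performed`.
#' @export
retrieve_with_prediction <- function(query, index, store, top_k = 10L,
                                     n_fallback_classes = 0L) {
  stopifnot(inherits(store, "cbmir_feature_store"))
  if (top_k < 1L) stop("top_k must be >= 1")
  cls <- classify_features(query, index)
  rows <- which(store$class_ids == cls$class_id)
  if (!length(rows)) {
    stop("predicted class ", cls$class_id, " has no stored vectors")
  }
  ranking <- rank_within(query, store, rows, top_k)
  fallback <- NULL
  if (n_fallback_classes > 0L) {
    d <- sqrt(rowSums(sweep(index$centroids, 2, query)^2))
    ord <- order(d, index$class_ids)
    nxt <- ord[-1][seq_len(min(n_fallback_classes, length(ord) - 1L))]
    fallback <- index$class_ids[nxt]
  }
  structure(list(query_id = "query", predicted_class = cls$class_id,
                 ranking = ranking,
                 comparisons_performed = nrow(index$centroids) + length(rows),
                 fallback_classes = fallback),
            class = "cbmir_retrieval_result")
}

#' Exhaustive retrieval over the whole database
#'
#' Ranks every stored vector by Euclidean distance to the query; the
#' comparison count is the total number of stored vectors (K * n for K
#' balanced classes of n vectors).
#'
#' @inheritParams retrieve_with_prediction
#' @export
retrieve_exhaustive <- function(query, store, top_k = 10L) {
  stopifnot(inherits(store, "cbmir_feature_store"))
  if (!nrow(store$features)) stop("empty feature store")
  if (top_k < 1L) stop("top_k must be >= 1")
  ranking <- rank_within(query, store, seq_len(nrow(store$features)), top_k)
  structure(list(query_id = "query", predicted_class = NA_integer_,
                 ranking = ranking,
                 comparisons_performed = nrow(store$features),
                 fallback_classes = NULL),
            class = "cbmir_retrieval_result")
}

#' @export
print.cbmir_retrieval_result <- function(x, ...) {
  cat("<cbmir_retrieval_result>",
      if (is.na(x$predicted_class)) "exhaustive"
      else paste("predicted class", x$predicted_class),
      "-", nrow(x$ranking), "hits,",
      x$comparisons_performed, "feature comparisons\n")
  print(utils::head(x$ranking, 5))
  invisible(x)
}

#' Retrieval-time cost model
#'
#' Total retrieval time in the two modes for a database of K classes with n
#' vectors each: `tau_fe + tau_fc * (K + n)` with class prediction and
#' `tau_fe + tau_fc * (K * n)` without, where `tau_fe` is the one-off feature
#' extraction time of the query and `tau_fc` the time of one feature
#' comparison.
#'
#' @param K class count.
#' @param n vectors per class.
#' @param tau_fe feature-extraction time unit.
#' @param tau_fc per-comparison time unit.
#' @param mode "with_prediction" or "exhaustive".
#' @return predicted time in the units of `tau_fe`/`tau_fc`.
#' @export
predicted_cost <- function(K, n, tau_fe = 0, tau_fc = 1,
                           mode = c("with_prediction", "exhaustive")) {
  mode <- match.arg(mode)
  if (K < 1 || n < 1 || tau_fe < 0 || tau_fc < 0) {
    stop("counts must be positive and time units non-negative")
  }
  comparisons <- if (mode == "with_prediction") K + n else K * n
  tau_fe + tau_fc * comparisons
}
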