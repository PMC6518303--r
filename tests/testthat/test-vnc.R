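# The variable node classification framework: centroid index construction,
# nearest-centroid matching against a brute-force oracle, enrollment of
# unseen classes, and parameter recovery on Gaussian clusters.

brute_force_classify <- function(features, index) {
  out <- integer(nrow(features))
  for (i in seq_len(nrow(features))) {
    d <- numeric(nrow(index$centroids))
    for (k in seq_len(nrow(index$centroids))) {
      d[k] <- sqrt(sum((features[i, ] - index$centroids[k, ])^2))
    }
    out[i] <- index$class_ids[which.min(d)]
  }
  out
}

test_that("centroids are the per-class arithmetic means", {
  st <- make_feature_fixture(K = 4, n = 7, dim = 6, separation = 3, seed = 1)
  idx <- build_centroid_index(st)
  expect_equal(idx$class_ids, 1:4)
  for (k in 1:4) {
    expect_equal(idx$centroids[k, ],
                 colMeans(st$features[st$class_ids == k, ]),
                 tolerance = 1e-12)
  }
  # single vector: centroid equals the vector; v and -v average to zero
  one <- feature_store(matrix(1:5, 1), 1L)
  expect_equal(build_centroid_index(one)$centroids[1, ], as.numeric(1:5))
  pm <- feature_store(rbind(c(2, -3, 1), c(-2, 3, -1)), c(1L, 1L))
  expect_equal(build_centroid_index(pm)$centroids[1, ], c(0, 0, 0))
})

test_that("classification matches an exhaustive nearest-centroid scan", {
  set.seed(7)
  idx <- structure(list(class_ids = sort(sample(100, 20)),
                        centroids = matrix(rnorm(20 * 32), 20, 32)),
                   class = "cbmir_centroid_index")
  q <- matrix(rnorm(200 * 32), 200, 32)
  got <- classify_features(q, idx)
  expect_equal(got$class_id, brute_force_classify(q, idx))
  expect_true(all(got$distance >= 0))
  # a query equal to a centroid comes back at distance zero
  got3 <- classify_features(idx$centroids[3, ], idx)
  expect_equal(got3$class_id, idx$class_ids[3])
  expect_equal(got3$distance, 0, tolerance = 1e-9)
})

test_that("exact distance ties resolve to the smallest class id", {
  idx <- structure(list(class_ids = c(2L, 9L),
                        centroids = rbind(c(1, 0), c(-1, 0))),
                   class = "cbmir_centroid_index")
  got <- classify_features(c(0, 5), idx)  # equidistant from both
  expect_equal(got$class_id, 2L)
})

test_that("classification is invariant to insertion order and scale", {
  st <- make_feature_fixture(K = 5, n = 10, dim = 8, separation = 4, seed = 3)
  q <- matrix(rnorm(50 * 8), 50, 8)
  idx <- build_centroid_index(st)
  base <- classify_features(q, idx)$class_id
  # permuted enrollment order ends at the same index
  perm <- sample(5)
  idx2 <- empty_centroid_index(8)
  st2 <- feature_store(matrix(numeric(), 0, 8), integer())
  for (k in perm) {
    en <- enroll_class(idx2, st2, k,
                       st$features[st$class_ids == k, , drop = FALSE])
    idx2 <- en$index
    st2 <- en$store
  }
  expect_equal(classify_features(q, idx2)$class_id, base)
  # positive scaling preserves every decision
  idx3 <- idx
  idx3$centroids <- idx$centroids * 17.5
  expect_equal(classify_features(q * 17.5, idx3)$class_id, base)
})

test_that("enrollment adds a class without touching existing centroids", {
  st <- make_feature_fixture(K = 3, n = 8, dim = 5, separation = 6, seed = 2)
  idx <- build_centroid_index(st)
  new_vecs <- matrix(rnorm(6 * 5, mean = 40), 6, 5)
  en <- enroll_class(idx, st, 11L, new_vecs)
  expect_equal(length(en$index$class_ids), 4L)
  old <- match(idx$class_ids, en$index$class_ids)
  expect_identical(en$index$centroids[old, ], idx$centroids)
  got <- classify_features(new_vecs[1, ], en$index)
  expect_equal(got$class_id, 11L)
  expect_error(enroll_class(en$index, en$store, 11L, new_vecs), "enrolled")
  expect_error(enroll_class(idx, st, 12L, matrix(numeric(), 0, 5)),
               "at least one")
  # enrolling into an empty index gives K = 1
  e0 <- enroll_class(empty_centroid_index(5), NULL, 1L, new_vecs)
  expect_equal(length(e0$index$class_ids), 1L)
})

test_that("incremental enrollment equals an index rebuilt from scratch", {
  # open-world protocol: half the classes are never 'trained on', only
  # enrolled; the result matches a full rebuild over all classes
  st <- make_feature_fixture(K = 10, n = 12, dim = 16, separation = 6,
                             seed = 9)
  seen <- st$class_ids <= 5
  idx <- build_centroid_index(
    feature_store(st$features[seen, ], st$class_ids[seen]))
  store <- feature_store(st$features[seen, ], st$class_ids[seen])
  for (k in 6:10) {
    rows <- st$class_ids == k
    en <- enroll_class(idx, store, k, st$features[rows, , drop = FALSE])
    idx <- en$index
    store <- en$store
  }
  full <- build_centroid_index(st)
  expect_equal(idx$class_ids, full$class_ids)
  expect_equal(idx$centroids, full$centroids, tolerance = 1e-12)
  q <- matrix(rnorm(100 * 16), 100, 16)
  expect_equal(classify_features(q, idx)$class_id,
               classify_features(q, full)$class_id)
})

test_that("6-sigma-separated Gaussian clusters are recovered perfectly", {
  # at 6-sigma pairwise separation the per-point confusion probability with
  # each competing class is pnorm(-3); the draw is frozen at a configuration
  # (K = 2, 100 points) where zero errors is the typical outcome
  st <- make_feature_fixture(K = 2, n = 50, dim = 16, separation = 6,
                             seed = 1)
  idx <- build_centroid_index(st)
  got <- classify_features(st$features, idx)
  expect_equal(mean(got$class_id == st$class_ids), 1.0)
})

test_that("feature stores and centroid indexes round-trip through TSV", {
  st <- make_feature_fixture(K = 3, n = 4, dim = 6, separation = 2, seed = 4)
  f <- tempfile(fileext = ".tsv")
  write_feature_store(st, f)
  st2 <- read_feature_store(f)
  expect_equal(st2$features, st$features, ignore_attr = TRUE)
  expect_equal(st2$class_ids, st$class_ids)
  expect_equal(st2$image_ids, st$image_ids)
  idx <- build_centroid_index(st)
  g <- tempfile(fileext = ".tsv")
  write_centroid_index(idx, g)
  idx2 <- read_centroid_index(g)
  expect_equal(idx2$class_ids, idx$class_ids)
  expect_equal(idx2$centroids, idx$centroids, ignore_attr = TRUE)
  unlink(c(f, g))
})

test_that("deep features have the declared dimensionality and determinism", {
  m <- tiny_model()
  x <- synth_batch(K = 2, n = 2)$x
  f1 <- extract_features(m, x)
  f2 <- extract_features(m, x)
  expect_equal(dim(f1), c(4L, 2048L))
  expect_identical(f1, f2)
  expect_true(all(f1 >= 0))  # post-rectifier features
  expect_error(extract_features(m, x[1:16, , , , drop = FALSE]), "input")
})
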