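# Confusion counts, one-vs-rest macro metrics, world-split protocols,
# Monte-Carlo sensitivity, the t test and PCA post-processing.

random_cm <- function(K, max_count = 20) {
  matrix(sample(0:max_count, K * K, replace = TRUE), K, K)
}

test_that("confusion matrices equal a direct tally", {
  set.seed(1)
  truth <- sample(4, 500, replace = TRUE)
  pred <- sample(4, 500, replace = TRUE)
  cm <- confusion(truth, pred, 4)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(cm[i, j], sum(truth == i & pred == j))
  }
  expect_equal(rowSums(cm), as.numeric(table(factor(truth, levels = 1:4))),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 500)
  # degenerate cases
  expect_equal(diag(confusion(rep(1:3, 2), rep(1:3, 2), 3)), rep(2L, 3),
               ignore_attr = TRUE)
  one <- confusion(1, 2, 3)
  expect_equal(one[1, 2], 1L)
  expect_equal(sum(one), 1L)
  expect_error(confusion(1:3, 1:2, 3), "length")
  expect_error(confusion(c(1, 5), c(1, 1), 3), "labels")
})

test_that("one-vs-rest counts partition the sample for every class", {
  cm <- matrix(c(8, 2, 3, 7), 2, 2, byrow = TRUE)  # rows = truth
  o <- ovr_counts(cm, 1)
  expect_equal(o, list(TP = 8, FP = 3, FN = 2, TN = 7))
  set.seed(2)
  for (t in 1:20) {
    K <- sample(2:10, 1)
    cm <- random_cm(K)
    for (k in seq_len(K)) {
      o <- ovr_counts(cm, k)
      expect_equal(o$TP + o$FP + o$FN + o$TN, sum(cm))
    }
  }
  expect_error(ovr_counts(cm, 99), "range")
})

test_that("macro metrics match hand arithmetic on the worked 2-class case", {
  cm <- matrix(c(8, 2, 3, 7), 2, 2, byrow = TRUE)
  mm <- macro_metrics(cm)
  expect_equal(mm$mAP, (8 / 11 + 7 / 9) / 2)
  expect_equal(mm$mAR, (8 / 10 + 7 / 10) / 2)
  expect_equal(mm$top1_accuracy, 15 / 20)
  expect_equal(mm$F1, 2 * mm$mAP * mm$mAR / (mm$mAP + mm$mAR))
  # the literal printed recall formula divides by TP + TN instead
  lit <- macro_metrics(cm, recall_mode = "literal_eq4")
  expect_equal(lit$mAR, (8 / 15 + 7 / 15) / 2)
  expect_equal(lit$mAP, mm$mAP)
  perfect <- macro_metrics(diag(5L) * 3L)
  expect_equal(perfect$top1_accuracy, 1)
  expect_equal(perfect$F1, 1)
  expect_equal(perfect$macro_accuracy, 1)
})

test_that("macro metrics agree with a brute-force tally on random matrices", {
  set.seed(3)
  for (t in 1:50) {
    K <- sample(2:15, 1)
    cm <- random_cm(K)
    if (sum(cm) == 0) next
    mm <- macro_metrics(cm)
    acc <- prec <- rec <- numeric(K)
    for (k in seq_len(K)) {
      TP <- cm[k, k]
      FP <- sum(cm[, k]) - TP
      FN <- sum(cm[k, ]) - TP
      TN <- sum(cm) - TP - FP - FN
      acc[k] <- (TP + TN) / sum(cm)
      prec[k] <- if (TP + FP > 0) TP / (TP + FP) else 0
      rec[k] <- if (TP + FN > 0) TP / (TP + FN) else 0
    }
    expect_equal(mm$macro_accuracy, mean(acc), tolerance = 1e-12)
    expect_equal(mm$mAP, mean(prec), tolerance = 1e-12)
    expect_equal(mm$mAR, mean(rec), tolerance = 1e-12)
    expect_true(mm$F1 >= min(mm$mAP, mm$mAR) - 1e-12 &&
                  mm$F1 <= max(mm$mAP, mm$mAR) + 1e-12)
    # macro accuracy relates to top-1 algebraically
    expect_equal(mm$macro_accuracy,
                 1 - 2 * (1 - mm$top1_accuracy) / K, tolerance = 1e-12)
  }
})

test_that("world splits satisfy the class-set relations of each mode", {
  manifest <- data.frame(path = sprintf("img%03d.png", 1:200),
                         class_id = rep(1:10, each = 20))
  for (seed in c(1, 7)) {
    for (fold in 1:2) {
      cl <- make_world_split(manifest, "closed", fold, seed)
      expect_equal(cl$train_classes, cl$test_classes)
      tr <- cl$manifest$split == "train"
      te <- cl$manifest$split == "test"
      expect_equal(sum(tr) + sum(te), 200L)
      expect_false(any(tr & te))
      for (k in 1:10) {
        expect_equal(sum(tr & manifest$class_id == k), 10L)
      }

      op <- make_world_split(manifest, "open", fold, seed)
      expect_length(intersect(op$train_classes, op$test_classes), 0L)
      expect_setequal(union(op$train_classes, op$test_classes), 1:10)
      expect_true(all(manifest$class_id[op$manifest$split == "train"] %in%
                        op$train_classes))
      expect_true(all(manifest$class_id[op$manifest$split == "test"] %in%
                        op$test_classes))

      mx <- make_world_split(manifest, "mixed", fold, seed)
      expect_length(mx$train_classes, 8L)
      expect_setequal(mx$test_classes, 1:10)
      unseen <- setdiff(mx$test_classes, mx$train_classes)
      expect_true(all(mx$manifest$split[manifest$class_id %in% unseen] ==
                        "test"))
      shared <- mx$manifest$class_id %in% mx$train_classes
      expect_false(any(mx$manifest$split[shared] == "unused"))
    }
    # the two folds are complementary
    c1 <- make_world_split(manifest, "closed", 1, seed)
    c2 <- make_world_split(manifest, "closed", 2, seed)
    expect_equal(c1$manifest$split == "train", c2$manifest$split == "test")
    o1 <- make_world_split(manifest, "open", 1, seed)
    o2 <- make_world_split(manifest, "open", 2, seed)
    expect_setequal(o1$train_classes, o2$test_classes)
  }
  expect_error(make_world_split(manifest[manifest$class_id < 5, ], "mixed"),
               "5 classes")
})

test_that("open-world fold 1 trains on the lower half of the class ids", {
  manifest <- data.frame(path = sprintf("i%02d", 1:20),
                         class_id = rep(1:10, 2))
  op <- make_world_split(manifest, "open", fold = 1, seed = 1)
  expect_equal(op$train_classes, 1:5)
  expect_equal(op$test_classes, 6:10)
})

test_that("Monte-Carlo sensitivity summarizes subsample variation", {
  set.seed(4)
  truth <- sample(5, 400, replace = TRUE)
  pred <- ifelse(runif(400) < 0.8, truth, sample(5, 400, replace = TRUE))
  s <- monte_carlo_sensitivity(truth, pred, 5, fraction = 0.2,
                               iterations = 20, seed = 6)
  expect_equal(nrow(s$per_iteration), 20L)
  expect_true(all(s$sd >= 0))
  s2 <- monte_carlo_sensitivity(truth, pred, 5, fraction = 0.2,
                                iterations = 20, seed = 6)
  expect_identical(s$per_iteration, s2$per_iteration)
  # fraction 1 reproduces the full-set metric with zero spread
  full <- monte_carlo_sensitivity(truth, pred, 5, fraction = 1,
                                  iterations = 5, seed = 1)
  expect_equal(unname(full$sd["top1_accuracy"]), 0)
  expect_equal(unname(full$mean["top1_accuracy"]), mean(truth == pred))
  # sampling-theory check: subsample accuracies concentrate on the truth
  s3 <- monte_carlo_sensitivity(truth, pred, 5, fraction = 0.2,
                                iterations = 200, seed = 8)
  expect_lt(abs(s3$mean["top1_accuracy"] - mean(truth == pred)),
            3 * s3$sd["top1_accuracy"] / sqrt(200))
})

test_that("the t test matches the closed-form Welch computation", {
  a <- c(1, 2, 3)
  b <- c(4, 5, 6)
  got <- two_sample_ttest(a, b)
  # closed form: equal variances 1, n = 3 -> se = sqrt(2/3), df = 4
  t_exp <- (2 - 5) / sqrt(2 / 3)
  p_exp <- 2 * stats::pt(t_exp, df = 4)
  expect_equal(got$t, t_exp, tolerance = 1e-12)
  expect_equal(got$p, p_exp, tolerance = 1e-12)
  swapped <- two_sample_ttest(b, a)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)
  same <- two_sample_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same, list(t = 0, p = 1))
  ident <- two_sample_ttest(a, a)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(two_sample_ttest(1, b), ">= 2")
})

test_that("PCA projection preserves structure and VNC decisions", {
  set.seed(9)
  st <- make_feature_fixture(K = 4, n = 25, dim = 12, separation = 5,
                             seed = 10)
  # eigenvalues are non-increasing
  p <- pca_fit(st$features, 12)
  expect_true(all(diff(p$eigenvalues) <= 1e-9))
  # full-rank projection is an isometry on pairwise distances
  z <- pca_transform(p, st$features[1:20, ])
  d0 <- as.matrix(stats::dist(st$features[1:20, ]))
  d1 <- as.matrix(stats::dist(z))
  expect_equal(d1, d0, tolerance = 1e-6)
  # classifying in the full eigenspace reproduces the raw-feature labels
  idx_raw <- build_centroid_index(st)
  q <- matrix(rnorm(100 * 12), 100, 12) + 2
  st_p <- feature_store(pca_transform(p, st$features), st$class_ids)
  idx_p <- build_centroid_index(st_p)
  expect_equal(classify_features(pca_transform(p, q), idx_p)$class_id,
               classify_features(q, idx_raw)$class_id)
  expect_error(pca_fit(st$features, 13), "n_eigenvectors")
  expect_error(pca_fit(st$features[1, , drop = FALSE], 2), ">= 2")
})
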