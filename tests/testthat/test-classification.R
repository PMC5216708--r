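test_that("KNN handles coincident points and the k = 2 tie rule", {
  x <- matrix(c(0, 0, 1, 1, 5, 5), ncol = 2, byrow = TRUE)
  y <- c("responder", "non-responder", "responder")
  expect_equal(knn_predict(x, y, c(0, 0), knn_config(1)), "responder")
  # k = 2: one neighbor per class -> class of the single nearest
  expect_equal(knn_predict(x, y, c(0.1, 0.1), knn_config(2)), "responder")
  expect_equal(knn_predict(x, y, c(0.9, 0.9), knn_config(2)),
               "non-responder")
  expect_error(knn_predict(x[0, ], character(0), c(0, 0)), "empty")
})

test_that("KNN equals a brute-force all-pairs scan", {
  set.seed(71)
  train <- matrix(rnorm(60 * 3), 60, 3)
  labels <- sample(c("responder", "non-responder"), 60, replace = TRUE)
  queries <- matrix(rnorm(1000 * 3), 1000, 3)
  for (k in c(1, 2, 3)) {
    got <- knn_predict(train, labels, queries, knn_config(k))
    want <- apply(queries, 1, function(q) bf_knn(train, labels, q, k))
    expect_identical(got, unname(want))
  }
})

test_that("LOOCV separates well-separated clusters and not permuted labels", {
  set.seed(72)
  n <- 16
  x <- rbind(matrix(rnorm(2 * n, 0, 0.1), ncol = 2),
             matrix(rnorm(2 * n, 0.3, 0.1), ncol = 2))
  x[(n + 1):(2 * n), 1] <- x[(n + 1):(2 * n), 1] + 0.3
  y <- rep(c("responder", "non-responder"), each = n)
  acc <- mean(loocv(x, y) == y)
  expect_gte(acc, 0.95)
  yp <- sample(y)
  acc_null <- mean(loocv(x, yp) == yp)
  expect_gt(acc_null, 0.2)
  expect_lt(acc_null, 0.8)
})

test_that("LOOCV with one sample per class predicts each as the other", {
  x <- matrix(c(0, 1), ncol = 1)
  y <- c("responder", "non-responder")
  pred <- loocv(x, y, config = knn_config(1), standardize = FALSE)
  expect_equal(pred, rev(y))
  expect_equal(unname(classification_metrics(pred, y)["accuracy"]), 0)
})

test_that("duplicated patients leave the training fold together", {
  # patient 1 duplicated; without patient-wise exclusion its copy would
  # self-match at distance zero and always be classified correctly
  x <- matrix(c(0, 0, 5, 6), ncol = 1)
  y <- c("responder", "responder", "non-responder", "non-responder")
  pred <- loocv(x, y, patient_id = c(1, 1, 2, 3), config = knn_config(1),
                standardize = FALSE)
  expect_equal(pred[1:2], c("non-responder", "non-responder"))
})

test_that("balanced evaluation is seed-deterministic and guards class size", {
  set.seed(73)
  x <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
             matrix(rnorm(24, 3, 0.2), 12, 2))
  y <- rep(c("responder", "non-responder"), c(20, 12))
  a <- balance_and_evaluate(x, y, n_repeats = 4, seed = 9)
  b <- balance_and_evaluate(x, y, n_repeats = 4, seed = 9)
  expect_identical(a$per_repeat, b$per_repeat)
  expect_equal(unname(a$accuracy["mean"]), 100)
  expect_equal(unname(a$sensitivity["sd"]), 0)
  expect_error(balance_and_evaluate(x, y, n_balance = 16), "only 12")
})

test_that("subset enumeration counts match the binomial sums", {
  expect_length(enumerate_subsets(letters[1:7], 2:7), 120)
  expect_length(enumerate_subsets(letters[1:3], 2:3), 4)
  expect_length(enumerate_subsets(letters[1:7], 2), choose(7, 2))
  # requesting sizes beyond the pool is a no-op, not an error
  expect_length(enumerate_subsets(letters[1:3], 2:7), 4)
})

test_that("the exhaustive search evaluates 120 subsets of 7 features", {
  pf <- planted_feature_table(n_per_class = 8, n_noise = 5, seed = 5)
  res <- exhaustive_feature_search(pf$x, pf$labels, n_repeats = 1, seed = 2)
  expect_equal(res$n_evaluated, 120)
  expect_equal(nrow(res$leaderboard), 120)
  expect_equal(sort(unique(res$leaderboard$size)), 2:7)
})

test_that("paired baseline units double columns but not the enumeration", {
  pf <- planted_feature_table(n_per_class = 8, n_noise = 5, seed = 6)
  x <- pf$x
  units <- list()
  for (nm in names(x)) {
    x[[paste0(nm, "_wk0")]] <- rnorm(nrow(x), 0, 0.5)
    units[[nm]] <- c(nm, paste0(nm, "_wk0"))
  }
  res <- exhaustive_feature_search(x, pf$labels, units = units,
                                   subset_sizes = 2:3, n_repeats = 1,
                                   seed = 3)
  expect_equal(res$n_evaluated, choose(7, 2) + choose(7, 3))
  expect_equal(ncol(x), 14)
})

test_that("a planted informative pair is found by the search", {
  hits <- 0
  for (s in 1:10) {
    pf <- planted_feature_table(n_per_class = 16, n_noise = 5,
                                seed = 100 + s)
    res <- exhaustive_feature_search(pf$x, pf$labels, n_repeats = 3,
                                     seed = s)
    if (all(c("f1", "f2") %in% res$best_subset)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("metrics recomputed from a confusion matrix match definitions", {
  truth <- rep(c("responder", "non-responder"), c(6, 4))
  pred <- c(rep("responder", 5), "non-responder",
            rep("non-responder", 3), "responder")
  m <- classification_metrics(pred, truth)
  expect_equal(unname(m["sensitivity"]), 100 * 5 / 6)
  expect_equal(unname(m["specificity"]), 100 * 3 / 4)
  expect_equal(unname(m["accuracy"]), 100 * 8 / 10)
})
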