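#' K-nearest-neighbor configuration
#'
#' The working classifier: k = 2 neighbors under the Euclidean metric,
#' which gave the best response discrimination. With k = 2 a split vote is
#' resolved by the class of the single nearest neighbor (equivalent to a
#' distance-weighted vote); exact distance ties are broken toward the
#' lower training index.
#'
#' @param k number of neighbors (>= 1).
#' @return list of class `knn_config`.
#' @export
knn_config <- function(k = 2) {
  if (k < 1) stop("k must be >= 1")
  structure(list(k = as.integer(k), metric = "euclidean"),
            class = "knn_config")
}

#' KNN prediction
#'
#' Majority label among the k training points nearest to the query in
#' Euclidean distance. Features are assumed already standardized (the
#' cross-validation wrappers z-score per training fold). A tied vote falls
#' back to the nearest neighbor's class.
#'
#' @param train_x numeric matrix (rows = training samples).
#' @param train_labels character/factor labels, one per training row.
#' @param query numeric vector (one sample) or matrix of query rows.
#' @param config a `knn_config`.
#' @return character vector of predicted labels.
#' @export
knn_predict <- function(train_x, train_labels, query, config = knn_config()) {
  train_x <- as.matrix(train_x)
  if (nrow(train_x) == 0) stop("empty training set")
  if (config$k >= nrow(train_x) + 1) stop("k must be < training-set size + 1")
  train_labels <- as.character(train_labels)
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  query <- as.matrix(query)
  k <- min(config$k, nrow(train_x))
  # all pairwise squared distances in one cross-product
  d2 <- outer(rowSums(query^2), rowSums(train_x^2), `+`) -
    2 * tcrossprod(query, train_x)
  out <- character(nrow(query))
  for (i in seq_len(nrow(query))) {
    ord <- sort.list(d2[i, ], method = "radix")  # stable: index breaks ties
    nb <- train_labels[ord[seq_len(k)]]
    u <- unique(nb)
    if (length(u) == 1L) {
      out[i] <- u
    } else {
      cnt <- tabulate(match(nb, u))
      m <- which(cnt == max(cnt))
      out[i] <- if (length(m) == 1L) u[m] else nb[1L]
    }
  }
  out
}

#' Leave-one-patient-out cross-validation
#'
#' For each row, all rows belonging to the same patient are removed from
#' the training fold (so resampled duplicates of a held-out patient leave
#' with it, preventing self-matching leakage), features are z-scored with
#' the training fold's statistics, and the held-out row is predicted.
#' Deterministic given the table.
#'
#' @param x numeric matrix or data.frame of features.
#' @param labels labels, one per row.
#' @param patient_id patient identifier per row (default: each row its own
#'   patient).
#' @param config a `knn_config`.
#' @param standardize z-score per feature on each training fold.
#' @return character vector of per-row predictions.
#' @export
loocv <- function(x, labels, patient_id = seq_len(nrow(x)),
                  config = knn_config(), standardize = TRUE) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  preds <- character(n)
  for (pid in unique(patient_id)) {
    held <- which(patient_id == pid)
    train <- which(patient_id != pid)
    if (length(train) == 0) stop("cannot hold out the entire table")
    tx <- x[train, , drop = FALSE]
    qx <- x[held, , drop = FALSE]
    if (standardize) {
      nt <- nrow(tx)
      mu <- colMeans(tx)
      sdv <- sqrt(pmax(colSums(tx^2) - nt * mu^2, 0) / (nt - 1))
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      tx <- (tx - rep(mu, each = nt)) / rep(sdv, each = nt)
      qx <- (qx - rep(mu, each = nrow(qx))) / rep(sdv, each = nrow(qx))
    }
    preds[held] <- knn_predict(tx, labels[train], qx, config)
  }
  preds
}

#' Classification performance metrics
#'
#' Sensitivity = true responders / all responders, specificity = true
#' non-responders / all non-responders, accuracy = correctly classified /
#' all, each in percent.
#'
#' @param pred,truth label vectors (`"responder"` / `"non-responder"`).
#' @return named numeric vector (percent).
#' @export
classification_metrics <- function(pred, truth) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  resp <- truth == "responder"
  c(sensitivity = 100 * mean(pred[resp] == "responder"),
    specificity = 100 * mean(pred[!resp] == "non-responder"),
    accuracy = 100 * mean(pred == truth))
}

#' Class-balanced, repeat-averaged LOOCV evaluation
#'
#' Compensates class imbalance by sampling `n_balance` patients with
#' replacement from the majority class while keeping every minority-class
#' patient (on the study cohort: 16 responders drawn against all 16
#' non-responders). Each of `n_repeats` resamples (default 10) is
#' evaluated by leave-one-patient-out KNN, and sensitivity, specificity
#' and accuracy are reported as mean with across-repeat SD.
#' Seed-deterministic: repeat r uses a stream derived from `seed`.
#'
#' @param x features (matrix or data.frame), one row per patient.
#' @param labels labels per row.
#' @param config a `knn_config`.
#' @param n_repeats number of resampled evaluations.
#' @param seed master seed.
#' @param n_balance balanced class size; defaults to the minority-class
#'   count. Requesting more than the minority count is an error.
#' @return list of class `performance_summary` with `sensitivity`,
#'   `specificity`, `accuracy` (each `c(mean, sd)`), `n_repeats`, and the
#'   `per_repeat` data.frame.
#' @export
balance_and_evaluate <- function(x, labels, config = knn_config(),
                                 n_repeats = 10, seed = 1,
                                 n_balance = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- c("responder", "non-responder")
  n_by <- c(sum(labels == classes[1]), sum(labels == classes[2]))
  minority <- classes[which.min(n_by)]
  majority <- setdiff(classes, minority)
  if (is.null(n_balance)) n_balance <- min(n_by)
  if (n_balance > min(n_by)) {
    stop(sprintf("minority class (%s) has only %d patients, fewer than %d",
                 minority, min(n_by), n_balance))
  }
  min_idx <- which(labels == minority)
  maj_idx <- which(labels == majority)
  per <- matrix(NA_real_, n_repeats, 3,
                dimnames = list(NULL, c("sensitivity", "specificity",
                                        "accuracy")))
  for (r in seq_len(n_repeats)) {
    set.seed(seed * 1000L + r)
    keep_min <- if (length(min_idx) == n_balance) min_idx else
      sample(min_idx, n_balance, replace = TRUE)
    draw <- sample(maj_idx, n_balance, replace = TRUE)
    idx <- c(keep_min, draw)
    pred <- loocv(x[idx, , drop = FALSE], labels[idx], patient_id = idx,
                  config = config)
    per[r, ] <- classification_metrics(pred, labels[idx])
  }
  structure(list(
    sensitivity = c(mean = mean(per[, 1]), sd = stats::sd(per[, 1])),
    specificity = c(mean = mean(per[, 2]), sd = stats::sd(per[, 2])),
    accuracy = c(mean = mean(per[, 3]), sd = stats::sd(per[, 3])),
    n_repeats = n_repeats,
    per_repeat = as.data.frame(per)),
    class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("sensitivity %5.1f +/- %4.1f %%\n",
              x$sensitivity["mean"], x$sensitivity["sd"]))
  cat(sprintf("specificity %5.1f +/- %4.1f %%\n",
              x$specificity["mean"], x$specificity["sd"]))
  cat(sprintf("accuracy    %5.1f +/- %4.1f %%  (%d repeats)\n",
              x$accuracy["mean"], x$accuracy["sd"], x$n_repeats))
  invisible(x)
}

#' Enumerate feature subsets
#'
#' All subsets of the given sizes, in size order then lexicographic. Seven
#' features at sizes 2-7 give C(7,2)+...+C(7,7) = 120 subsets.
#'
#' @param features character vector of feature (unit) names.
#' @param sizes subset sizes to enumerate.
#' @return list of character vectors.
#' @export
enumerate_subsets <- function(features, sizes = 2:7) {
  sizes <- sizes[sizes <= length(features)]
  out <- list()
  for (s in sizes) {
    cmb <- utils::combn(features, s, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Exhaustive feature-subset search
#'
#' Evaluates every subset of the feature units at the given sizes with the
#' balanced repeated LOOCV and returns the subset maximizing mean
#' accuracy; ties prefer the smaller subset, then lexicographic order.
#' A feature "unit" is one QUS parameter: when baseline values are
#' included, the unit expands to its (week-0, delta) column pair, so the
#' enumeration is unchanged at 120 subsets.
#'
#' @param table data.frame holding the feature columns.
#' @param labels labels per row.
#' @param units named list mapping unit names to column names in `table`
#'   (default: every column is its own unit).
#' @param subset_sizes sizes to search (default 2:7).
#' @param config a `knn_config`.
#' @param n_repeats,seed,n_balance passed to [balance_and_evaluate()].
#' @return list with `best_subset`, `best` (its `performance_summary`),
#'   `leaderboard` (one row per subset), `n_evaluated`.
#' @export
exhaustive_feature_search <- function(table, labels, units = NULL,
                                      subset_sizes = 2:7,
                                      config = knn_config(),
                                      n_repeats = 10, seed = 1,
                                      n_balance = NULL) {
  if (is.null(units)) {
    units <- stats::setNames(as.list(names(table)), names(table))
  }
  subsets <- enumerate_subsets(names(units), subset_sizes)
  rows <- vector("list", length(subsets))
  best <- NULL
  best_key <- NULL
  for (i in seq_along(subsets)) {
    ss <- subsets[[i]]
    cols <- unlist(units[ss], use.names = FALSE)
    perf <- balance_and_evaluate(table[, cols, drop = FALSE], labels,
                                 config = config, n_repeats = n_repeats,
                                 seed = seed, n_balance = n_balance)
    rows[[i]] <- data.frame(subset = paste(ss, collapse = "+"),
                            size = length(ss),
                            accuracy = unname(perf$accuracy["mean"]),
                            accuracy_sd = unname(perf$accuracy["sd"]),
                            sensitivity = unname(perf$sensitivity["mean"]),
                            specificity = unname(perf$specificity["mean"]))
    key <- list(-perf$accuracy[["mean"]], length(ss),
                paste(ss, collapse = "+"))
    if (is.null(best_key) ||
        key[[1]] < best_key[[1]] ||
        (key[[1]] == best_key[[1]] && key[[2]] < best_key[[2]]) ||
        (key[[1]] == best_key[[1]] && key[[2]] == best_key[[2]] &&
         key[[3]] < best_key[[3]])) {
      best_key <- key
      best <- list(subset = ss, perf = perf)
    }
  }
  list(best_subset = best$subset, best = best$perf,
       leaderboard = do.call(rbind, rows), n_evaluated = length(subsets))
}
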