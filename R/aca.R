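#' Train the amplification-curve-analysis (ACA) classifier
#'
#' Classifies which target amplified in a single-channel reaction from its
#' kinetic feature vector. The default model is k-nearest-neighbours
#' (k = 5) on standardized features: deterministic, assumption-light, and
#' well suited to the separability-driven feature space the pipeline
#' constructs. Ties are broken deterministically towards the
#' lexicographically smallest class label; neighbour ties at the k-th
#' distance are resolved by training-row order.
#'
#' @param features numeric matrix or data frame of feature vectors.
#' @param labels target labels, one per row; at least 2 classes with at
#'   least 2 samples each.
#' @param k number of neighbours; default 5.
#' @param standardize standardize features (population SD) before storing;
#'   the same transform is applied to prediction inputs. Default `TRUE`.
#' @return An object of class `aca_knn`.
#' @export
aca_train <- function(features, labels, k = 5, standardize = TRUE) {
  x <- as.matrix(features)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need >= 2 classes")
  if (any(tab < 2))
    stop("class(es) with < 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  if (standardize) {
    std <- standardize_features(x)
    x <- std$x; ctr <- std$center; scl <- std$scale
  }
  structure(list(x = x, labels = labels, k = k,
                 center = ctr, scale = scl,
                 classes = sort(names(tab))),
            class = "aca_knn")
}

#' @export
print.aca_knn <- function(x, ...) {
  cat(sprintf("ACA k-NN classifier: k = %d, %d training curves, %d targets (%s)\n",
              x$k, nrow(x$x), length(x$classes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' @param object an `aca_knn` classifier.
#' @param newdata matrix or data frame of feature vectors to classify.
#' @param ... unused.
#' @rdname aca_train
#' @export
predict.aca_knn <- function(object, newdata, ...) {
  q <- sweep(sweep(as.matrix(newdata), 2, object$center), 2,
             object$scale, "/")
  k <- min(object$k, nrow(object$x))
  vapply(seq_len(nrow(q)), function(i) {
    d <- sqrt(colSums((t(object$x) - q[i, ])^2))
    nb <- object$labels[order(d)[seq_len(k)]]
    votes <- table(factor(nb, levels = object$classes))
    names(votes)[which.max(votes)]  # which.max -> first (lowest) label on ties
  }, character(1))
}

.aca_report <- function(truth, pred, classes, scheme, per_fold,
                        flagged = character(0), embedding_mss = NA_real_) {
  cm <- table(factor(truth, levels = classes),
              factor(pred, levels = classes))
  structure(list(scheme = scheme,
                 accuracy = sum(diag(cm)) / sum(cm),
                 confusion = unclass(cm),
                 per_fold_accuracies = per_fold,
                 flagged = flagged,
                 embedding_mss = embedding_mss),
            class = "aca_report")
}

#' @export
print.aca_report <- function(x, ...) {
  cat(sprintf("ACA evaluation (%s): accuracy = %.4f over %d curves, %d folds\n",
              x$scheme, x$accuracy, sum(x$confusion),
              length(x$per_fold_accuracies)))
  if (is.finite(x$embedding_mss))
    cat(sprintf("  feature-space MSS = %.4f\n", x$embedding_mss))
  if (length(x$flagged))
    cat("  flagged:", paste(x$flagged, collapse = "; "), "\n")
  invisible(x)
}

#' Stratified k-fold cross-validation of ACA classification
#'
#' Splits the curves into `k` folds stratified by target (default k = 30),
#' trains on k-1 folds, predicts the held-out fold, and aggregates all
#' out-of-fold predictions into one confusion matrix. The fold assignment
#' is the only random element and is controlled by `seed`.
#'
#' @inheritParams aca_train
#' @param k_folds number of folds; must not exceed the smallest class
#'   count.
#' @param seed integer seed for the fold shuffle.
#' @param knn_k neighbours for the k-NN classifier.
#' @return An `aca_report`: `scheme`, `accuracy`, `confusion` (rows true,
#'   columns predicted), `per_fold_accuracies`, `embedding_mss` (mean
#'   silhouette of the standardized features under true labels).
#' @export
cross_validate <- function(features, labels, k_folds = 30, seed = 1,
                           knn_k = 5) {
  x <- as.matrix(features)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need >= 2 classes")
  if (k_folds > min(tab))
    stop(sprintf("k_folds = %d exceeds the smallest class count (%d); use a smaller k",
                 k_folds, min(tab)))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k_folds), length(idx))
  }
  pred <- character(length(labels))
  per_fold <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    te <- fold == f
    model <- aca_train(x[!te, , drop = FALSE], labels[!te], k = knn_k)
    pred[te] <- predict(model, x[te, , drop = FALSE])
    per_fold[f] <- mean(pred[te] == labels[te])
  }
  mss <- mean_silhouette(standardize_features(x)$x, labels)
  .aca_report(labels, pred, sort(names(tab)), "kfold", per_fold,
              embedding_mss = mss)
}

#' Leave-one-concentration-out (LOCO) cross-validation
#'
#' One fold per concentration group: the classifier is trained on all other
#' concentrations and tested on the held-out one. Because template
#' concentration shifts curve timing but (by design of the selected
#' features) not the feature distributions, LOCO accuracy close to k-fold
#' accuracy is evidence of concentration robustness; a drop indicates
#' concentration leakage into the features. Folds whose test set contains a
#' class absent from training are flagged in the report, not silently
#' dropped.
#'
#' @inheritParams cross_validate
#' @param concentrations concentration labels, one per row; at least 2
#'   groups.
#' @return An `aca_report` with `scheme = "loco"`; per-fold accuracies are
#'   named by held-out concentration.
#' @export
loco_evaluate <- function(features, labels, concentrations, knn_k = 5) {
  x <- as.matrix(features)
  labels <- as.character(labels)
  conc <- as.character(concentrations)
  uc <- sort(unique(conc))
  if (length(uc) < 2) stop("need >= 2 concentration groups for LOCO")
  pred <- character(length(labels))
  per_fold <- stats::setNames(numeric(length(uc)), uc)
  flagged <- character(0)
  for (cc in uc) {
    te <- conc == cc
    absent <- setdiff(unique(labels[te]), unique(labels[!te]))
    if (length(absent))
      flagged <- c(flagged, sprintf(
        "concentration %s: class(es) %s absent from training", cc,
        paste(absent, collapse = ",")))
    if (length(unique(labels[!te])) < 2) {
      # degenerate fold: only one class left to train on
      pred[te] <- unique(labels[!te])
    } else {
      model <- aca_train(x[!te, , drop = FALSE], labels[!te], k = knn_k)
      pred[te] <- predict(model, x[te, , drop = FALSE])
    }
    per_fold[cc] <- mean(pred[te] == labels[te])
  }
  mss <- mean_silhouette(standardize_features(x)$x, labels)
  .aca_report(labels, pred, sort(unique(labels)), "loco", per_fold,
              flagged = flagged, embedding_mss = mss)
}

#' Panel-ensemble majority vote
#'
#' In digital PCR a sample yields a panel of many partition-level curves;
#' combining the per-curve predictions of one panel by majority vote gives
#' the sample-level call and typically improves on per-curve accuracy.
#' Ties are broken towards the lexicographically smallest class label.
#'
#' @param predictions character vector of per-curve predicted targets.
#' @param panel_ids panel identifier per prediction.
#' @param truth optional per-curve true labels (must be constant within a
#'   panel) for panel-level accuracy.
#' @return A list with `calls` (named character vector, one call per
#'   panel) and `accuracy` (panel-level fraction correct, or `NA` without
#'   `truth`).
#' @export
panel_ensemble <- function(predictions, panel_ids, truth = NULL) {
  panel_ids <- as.character(panel_ids)
  if (length(predictions) != length(panel_ids))
    stop("one panel id per prediction required")
  if (!length(predictions)) stop("empty panel set")
  calls <- vapply(split(as.character(predictions), panel_ids),
                  function(p) {
                    v <- sort(table(p), decreasing = TRUE)
                    top <- names(v)[v == max(v)]
                    sort(top)[1]
                  }, character(1))
  acc <- NA_real_
  if (!is.null(truth)) {
    pt <- vapply(split(as.character(truth), panel_ids),
                 function(tr) {
                   u <- unique(tr)
                   if (length(u) > 1)
                     stop("truth must be constant within a panel")
                   u
                 }, character(1))
    acc <- mean(calls == pt[names(calls)])
  }
  list(calls = calls, accuracy = acc)
}
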