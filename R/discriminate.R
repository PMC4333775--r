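# Linear SVC helpers -------------------------------------------------------

# z-score columns with given (training) stats; zero-variance columns map to 0
scale_cols <- function(x, mu, sds) {
  x <- sweep(x, 2L, mu, `-`)
  ok <- sds > .Machine$double.eps * 100
  x[, ok] <- sweep(x[, ok, drop = FALSE], 2L, sds[ok], `/`)
  x[, !ok] <- 0
  x
}

# Fit a linear soft-margin SVC and return the model plus hyperplane weights.
fit_linear_svc <- function(x, y, cost) {
  fit <- e1071::svm(x = x, y = factor(y), kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  list(fit = fit, w = w)
}

#' Rank directed-edge features by recursive feature elimination
#'
#' Trains a linear support vector classifier on the surviving features
#' (z-scored per column on the full sample; degenerate columns get zero
#' weight) and repeatedly removes the feature with the smallest absolute
#' hyperplane coefficient (ties: the higher column index is removed first)
#' until none remain. The ranking is the reverse elimination order, most
#' discriminative feature first.
#'
#' @param features A `feature_table` or numeric sample x feature matrix.
#' @param labels Class labels (two classes); defaults to the feature table's
#'   conditions.
#' @param svc_cost Soft-margin cost C (default 1).
#' @return Integer permutation of the feature indices, best first.
#' @export
rfe_ranking <- function(features, labels = NULL, svc_cost = 1) {
  x <- if (inherits(features, "feature_table")) features$matrix
       else as.matrix(features)
  if (is.null(labels) && inherits(features, "feature_table"))
    labels <- features$condition
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L)
    stop("exactly two classes are required")
  p <- ncol(x)
  xs <- scale_cols(x, colMeans(x), apply(x, 2L, stats::sd))
  surviving <- seq_len(p)
  eliminated <- integer(0)
  while (length(surviving) > 1L) {
    w <- fit_linear_svc(xs[, surviving, drop = FALSE], labels, svc_cost)$w
    aw <- abs(w)
    worst <- which(aw <= min(aw) + 1e-12)
    drop_local <- worst[which.max(surviving[worst])]
    eliminated <- c(eliminated, surviving[drop_local])
    surviving <- surviving[-drop_local]
  }
  eliminated <- c(eliminated, surviving)
  rev(eliminated)
}

# Enumerate LOO folds: list of held-out row index vectors.
loo_folds <- function(labels, subject_ids, mode) {
  switch(mode,
    by_sample = as.list(seq_along(labels)),
    by_subject = {
      ids <- unique(subject_ids)
      lapply(ids, function(s) which(subject_ids == s))
    },
    stop("unknown cross-validation mode: ", mode))
}

#' Leave-one-out accuracy of a linear SVC on a feature subset
#'
#' In `by_subject` mode each fold holds out every recording of one subject
#' (so both conditions of a subject leave together, respecting within-subject
#' dependence); `by_sample` is classic leave-one-sample-out. Column
#' standardization statistics are computed on the training fold only, so held
#' out rows never influence the trained model.
#'
#' @param features A `feature_table` or sample x feature matrix.
#' @param labels,subject_ids Per-row labels; default to the feature table's.
#' @param subset Non-empty feature column indices to use.
#' @param mode `"by_subject"` (default) or `"by_sample"`.
#' @param svc_cost Soft-margin cost C (default 1).
#' @return Fraction of held-out predictions that are correct.
#' @export
loo_accuracy <- function(features, labels = NULL, subject_ids = NULL,
                         subset = NULL, mode = "by_subject", svc_cost = 1) {
  x <- if (inherits(features, "feature_table")) features$matrix
       else as.matrix(features)
  if (inherits(features, "feature_table")) {
    labels <- labels %||% features$condition
    subject_ids <- subject_ids %||% features$subject_id
  }
  labels <- as.character(labels)
  if (is.null(subset)) subset <- seq_len(ncol(x))
  if (length(subset) == 0L) stop("'subset' must be non-empty")
  x <- x[, subset, drop = FALSE]
  folds <- loo_folds(labels, subject_ids, mode)
  correct <- 0L
  for (hold in folds) {
    train <- setdiff(seq_along(labels), hold)
    if (length(unique(labels[train])) != 2L)
      stop("a training fold lost one of the classes")
    mu <- colMeans(x[train, , drop = FALSE])
    sds <- apply(x[train, , drop = FALSE], 2L, stats::sd)
    xt <- scale_cols(x[train, , drop = FALSE], mu, sds)
    xh <- scale_cols(x[hold, , drop = FALSE], mu, sds)
    fit <- fit_linear_svc(xt, labels[train], svc_cost)$fit
    pred <- as.character(predict(fit, xh))
    correct <- correct + sum(pred == labels[hold])
  }
  correct / length(labels)
}

#' Accuracy curve over nested RFE-ranked feature subsets
#'
#' Evaluates [loo_accuracy()] on the top-1, top-2, ..., top-P ranked features
#' and reports the whole curve with its best subset. This reproduces the
#' protocol of ranking once on all samples and then validating each nested
#' subset by leave-one-out; for a selection-bias-free estimate use
#' [nested_rfe_accuracy()].
#'
#' @param features A `feature_table` or sample x feature matrix.
#' @param labels,subject_ids Per-row labels; default to the feature table's.
#' @param ranking Feature ranking from [rfe_ranking()]; computed if missing.
#' @param mode `"by_subject"` (default) or `"by_sample"`.
#' @param svc_cost Soft-margin cost C (default 1).
#' @return An object of class `classification_report`: `accuracy_by_k`
#'   (length-P numeric), `best_k` (smallest k attaining the maximum),
#'   `best_accuracy`, `ranking`, and `config`.
#' @export
accuracy_curve <- function(features, labels = NULL, subject_ids = NULL,
                           ranking = NULL, mode = "by_subject", svc_cost = 1) {
  x <- if (inherits(features, "feature_table")) features$matrix
       else as.matrix(features)
  if (inherits(features, "feature_table")) {
    labels <- labels %||% features$condition
    subject_ids <- subject_ids %||% features$subject_id
  }
  if (is.null(ranking)) ranking <- rfe_ranking(x, labels, svc_cost)
  p <- ncol(x)
  if (!setequal(ranking, seq_len(p)))
    stop("'ranking' must be a permutation of the feature indices")
  acc <- vapply(seq_len(p), function(k)
    loo_accuracy(x, labels, subject_ids, subset = ranking[seq_len(k)],
                 mode = mode, svc_cost = svc_cost), 0)
  best_k <- which.max(acc)  # smallest k attaining the maximum
  structure(
    list(accuracy_by_k = acc, best_k = as.integer(best_k),
         best_accuracy = acc[best_k], ranking = as.integer(ranking),
         config = list(mode = mode, svc_cost = svc_cost)),
    class = "classification_report")
}

#' @exportS3Method base::print
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> best accuracy %.1f%% at k = %d of %d features (%s LOO)\n",
              100 * x$best_accuracy, x$best_k, length(x$accuracy_by_k),
              x$config$mode))
  invisible(x)
}

#' Fold-nested RFE accuracy (selection-bias-free variant)
#'
#' Recomputes the RFE ranking inside each training fold and evaluates the
#' held-out rows on the fold's own top-k features, removing the selection
#' bias of ranking on all data.
#'
#' @inheritParams accuracy_curve
#' @param k_values Subset sizes to evaluate (default all).
#' @return Numeric vector of accuracies, one per element of `k_values`.
#' @export
nested_rfe_accuracy <- function(features, labels = NULL, subject_ids = NULL,
                                mode = "by_subject", svc_cost = 1,
                                k_values = NULL) {
  x <- if (inherits(features, "feature_table")) features$matrix
       else as.matrix(features)
  if (inherits(features, "feature_table")) {
    labels <- labels %||% features$condition
    subject_ids <- subject_ids %||% features$subject_id
  }
  labels <- as.character(labels)
  p <- ncol(x)
  if (is.null(k_values)) k_values <- seq_len(p)
  folds <- loo_folds(labels, subject_ids, mode)
  hits <- matrix(0, length(k_values), 2L)  # correct, total
  for (hold in folds) {
    train <- setdiff(seq_along(labels), hold)
    mu <- colMeans(x[train, , drop = FALSE])
    sds <- apply(x[train, , drop = FALSE], 2L, stats::sd)
    xt <- scale_cols(x[train, , drop = FALSE], mu, sds)
    xh <- scale_cols(x[hold, , drop = FALSE], mu, sds)
    rk <- rfe_ranking(xt, labels[train], svc_cost)
    for (m in seq_along(k_values)) {
      sel <- rk[seq_len(k_values[m])]
      fit <- fit_linear_svc(xt[, sel, drop = FALSE], labels[train], svc_cost)$fit
      pred <- as.character(predict(fit, xh[, sel, drop = FALSE]))
      hits[m, ] <- hits[m, ] + c(sum(pred == labels[hold]), length(hold))
    }
  }
  hits[, 1L] / hits[, 2L]
}

#' Top-k discriminative directed-edge pattern
#'
#' Lists the k best-ranked directed edges with their per-condition mean
#' weights and the between-condition difference, for reporting or plotting.
#'
#' @param report A `classification_report`.
#' @param features The `feature_table` the report was computed from.
#' @param k Number of top-ranked features to list (default `report$best_k`).
#' @return Data frame with `rank`, `source`, `target`, per-condition mean
#'   columns, and `difference` (second condition minus first in the order of
#'   `sort(unique(condition))`, i.e. EO minus EC for the default labels).
#' @export
discriminative_pattern <- function(report, features, k = report$best_k) {
  stopifnot(inherits(report, "classification_report"),
            inherits(features, "feature_table"))
  p <- ncol(features$matrix)
  if (k < 1L || k > p) stop("'k' must be between 1 and ", p)
  idx <- report$ranking[seq_len(k)]
  conds <- sort(unique(features$condition))
  means <- vapply(conds, function(cc)
    colMeans(features$matrix[features$condition == cc, idx, drop = FALSE]),
    numeric(length(idx)))
  means <- matrix(means, nrow = length(idx),
                  dimnames = list(NULL, paste0("mean_", conds)))
  out <- data.frame(rank = seq_len(k),
                    source = features$feature_key$source[idx],
                    target = features$feature_key$target[idx],
                    stringsAsFactors = FALSE)
  out <- cbind(out, means)
  out$difference <- if (ncol(means) >= 2L) means[, 2L] - means[, 1L] else means[, 1L]
  out
}
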