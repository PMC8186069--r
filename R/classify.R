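# Random-forest behaviour models and the feature-refinement workflow.

#' Train the behaviour random forest
#'
#' Fits a bootstrap-per-tree classification forest (500 trees by default,
#' Gini-impurity node splitting, square-root-of-p variables tried per
#' split) on the named feature columns of a feature table, exposing the
#' per-feature mean Gini decrease and the out-of-bag error trace per tree
#' count.
#'
#' @param feature_table a feature table (or any data.frame holding the
#'   feature columns).
#' @param label factor of class labels, one per row.
#' @param features character vector of feature column names (default: the
#'   full magnetometry registry intersected with the table's columns).
#' @param n_trees number of trees (default 500).
#' @param seed integer seed; the same seed reproduces the forest exactly.
#' @param ... passed to [randomForest::randomForest()].
#' @return object of class `behaviour_rf`: list with the fitted `forest`,
#'   `features`, `importance` (named mean Gini decrease), `oob_trace`
#'   (overall out-of-bag error per tree count 1..`n_trees`),
#'   `oob_trace_by_class`, `classes` and `meta`.
#' @export
train_forest <- function(feature_table, label,
                         features = intersect(feature_registry()$name,
                                              names(feature_table)),
                         n_trees = 500, seed = 1L, ...) {
  label <- droplevels(factor(label))
  if (nlevels(label) < 2) stop("need at least 2 classes to train")
  stopifnot(length(label) == nrow(feature_table), length(features) >= 1)
  missing <- setdiff(features, names(feature_table))
  if (length(missing))
    stop("feature columns absent: ", paste(missing, collapse = ", "))
  x <- as.data.frame(feature_table)[, features, drop = FALSE]
  if (anyNA(x)) stop("missing feature values")
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = label, ntree = n_trees,
                                    importance = FALSE, ...)
  imp <- setNames(fit$importance[, "MeanDecreaseGini"],
                  rownames(fit$importance))
  structure(list(forest = fit, features = features, importance = imp,
                 oob_trace = as.numeric(fit$err.rate[, "OOB"]),
                 oob_trace_by_class =
                   fit$err.rate[, setdiff(colnames(fit$err.rate), "OOB"),
                                drop = FALSE],
                 classes = levels(label),
                 meta = list(n_trees = n_trees, seed = seed,
                             n_rows = nrow(x),
                             sampling_frequency_hz =
                               attr(feature_table, "sampling_frequency_hz"))),
            class = "behaviour_rf")
}

#' @export
print.behaviour_rf <- function(x, ...) {
  cat(sprintf(
    "<behaviour_rf> %d trees, %d features, %d classes; final OOB error %.3f\n",
    x$meta$n_trees, length(x$features), length(x$classes),
    tail(x$oob_trace, 1)))
  invisible(x)
}

#' Predict behaviour labels
#'
#' Majority vote over trees; feature columns are bound by name, so column
#' order is irrelevant. Vote ties are broken by class order (alphabetical),
#' as fixed by the underlying forest.
#'
#' @param object a [train_forest()] model.
#' @param newdata data.frame carrying the model's feature columns.
#' @param ... ignored.
#' @return factor of predicted labels, one per row.
#' @export
predict.behaviour_rf <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing))
    stop("feature columns absent: ", paste(missing, collapse = ", "))
  x <- as.data.frame(newdata)[, object$features, drop = FALSE]
  predict(object$forest, x)
}

# pairwise Pearson correlations with constant columns treated as r = 0
safe_cor <- function(x) {
  sds <- vapply(x, sd, 0)
  if (any(sds == 0)) {
    warning("constant feature(s) treated as uncorrelated: ",
            paste(names(x)[sds == 0], collapse = ", "))
  }
  r <- suppressWarnings(cor(x))
  r[!is.finite(r)] <- 0
  r
}

#' Correlation-based feature pruning
#'
#' Repeatedly finds the feature pair with the highest absolute Pearson
#' correlation at or above `r_threshold` and removes the pair's less
#' important member (by mean Gini decrease), until no pair reaches the
#' threshold. Pairs are processed in descending |r| order; importance
#' ties are broken by name order. The retained set is therefore pairwise
#' |r| below the threshold, and pruning an already-pruned set removes
#' nothing.
#'
#' @param feature_table a feature table.
#' @param importances named numeric of per-feature importance covering all
#'   candidate features (e.g. from a preliminary [train_forest()] fit).
#' @param r_threshold Pearson threshold (default 0.70).
#' @param features candidate feature names (default: names of
#'   `importances`).
#' @return list with `retained`, and `removed` (data.frame: `feature`,
#'   `paired_with`, `r`, the offending correlation at removal time).
#' @export
correlation_prune <- function(feature_table, importances, r_threshold = 0.70,
                              features = names(importances)) {
  stopifnot(all(features %in% names(feature_table)),
            all(features %in% names(importances)))
  x <- as.data.frame(feature_table)[, features, drop = FALSE]
  removed <- list()
  repeat {
    if (ncol(x) < 2) break
    r <- safe_cor(x)
    diag(r) <- 0
    worst <- max(abs(r))
    if (worst < r_threshold) break
    ij <- which(abs(r) == worst, arr.ind = TRUE)[1, ]
    a <- colnames(r)[ij[1]]; b <- colnames(r)[ij[2]]
    # drop the less important member; ties by name order (later name goes)
    drop_f <- if (importances[a] < importances[b]) a
              else if (importances[b] < importances[a]) b
              else sort(c(a, b))[2]
    keep_f <- setdiff(c(a, b), drop_f)
    removed[[length(removed) + 1L]] <- data.frame(
      feature = drop_f, paired_with = keep_f, r = r[a, b],
      stringsAsFactors = FALSE)
    x <- x[, setdiff(colnames(x), drop_f), drop = FALSE]
  }
  list(retained = colnames(x),
       removed = if (length(removed)) do.call(rbind, removed)
                 else data.frame(feature = character(0),
                                 paired_with = character(0), r = numeric(0)))
}

# deterministic k-fold assignment, stratified by label
make_folds <- function(label, k, seed) {
  set.seed(seed)
  fold <- integer(length(label))
  for (cl in levels(label)) {
    idx <- sample(which(label == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Recursive feature elimination with cross-validated forests
#'
#' Starting from the full candidate set, repeatedly keeps the top-`size`
#' features by current mean Gini decrease for each candidate size (largest
#' to smallest), estimates the size's accuracy by stratified k-fold
#' cross-validation, and recomputes importances on the reduced set before
#' the next elimination step. The selected size maximises CV accuracy,
#' with ties resolved in favour of the smaller set; the returned model is
#' refit on all rows with the selected features.
#'
#' @param feature_table a feature table.
#' @param label factor of class labels.
#' @param features candidate feature names.
#' @param candidate_sizes subset sizes to evaluate (default
#'   `c(2, 4, 8, 12, 16, 20, 25, 30, p)` capped at p, the candidate
#'   count).
#' @param k_folds folds for cross-validation (default 5).
#' @param n_trees trees per fit.
#' @param seed integer seed.
#' @return list with `selected` (feature names), `trace` (data.frame
#'   `size`, `cv_accuracy`), `model` (final [train_forest()] fit) and
#'   `removed` (features eliminated, in elimination order).
#' @export
recursive_feature_elimination <- function(feature_table, label, features,
                                          candidate_sizes = NULL,
                                          k_folds = 5, n_trees = 200,
                                          seed = 1L) {
  label <- droplevels(factor(label))
  p <- length(features)
  if (is.null(candidate_sizes))
    candidate_sizes <- unique(pmin(c(2, 4, 8, 12, 16, 20, 25, 30, p), p))
  candidate_sizes <- sort(unique(as.integer(candidate_sizes)))
  if (min(candidate_sizes) < 1) stop("candidate sizes must be >= 1")
  if (max(candidate_sizes) > p)
    stop("candidate size exceeds number of candidate features")
  if (k_folds < 2) stop("k_folds must be >= 2")

  fold <- make_folds(label, k_folds, seed)
  cv_accuracy <- function(feats, seed_off) {
    correct <- 0L
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      fit <- train_forest(feature_table[tr, , drop = FALSE], label[tr],
                          features = feats, n_trees = n_trees,
                          seed = seed + seed_off * 100 + f)
      pred <- predict(fit, feature_table[!tr, , drop = FALSE])
      correct <- correct + sum(as.character(pred) ==
                                 as.character(label[!tr]))
    }
    correct / length(label)
  }

  current <- features
  sizes_desc <- rev(candidate_sizes)
  trace <- data.frame(size = sizes_desc, cv_accuracy = NA_real_)
  kept_sets <- list()
  for (s in seq_along(sizes_desc)) {
    size <- sizes_desc[s]
    # recompute importances on the current set, then keep the top `size`
    imp_fit <- train_forest(feature_table, label, features = current,
                            n_trees = n_trees, seed = seed + s)
    ord <- order(-imp_fit$importance, names(imp_fit$importance))
    current <- names(imp_fit$importance)[ord][seq_len(size)]
    kept_sets[[s]] <- current
    trace$cv_accuracy[s] <- cv_accuracy(current, s)
  }
  trace <- trace[order(trace$size), ]
  best_acc <- max(trace$cv_accuracy)
  best_size <- min(trace$size[trace$cv_accuracy == best_acc])
  selected <- kept_sets[[which(sizes_desc == best_size)]]
  model <- train_forest(feature_table, label, features = selected,
                        n_trees = n_trees, seed = seed)
  list(selected = selected, trace = trace, model = model,
       removed = setdiff(features, selected))
}

#' Run the full feature-refinement workflow
#'
#' Preliminary forest for importances, correlation pruning at
#' `r_threshold`, then recursive feature elimination on the surviving
#' set. When `feature_table` rows span several species and
#' `consistent_across` names a grouping column, pruning and RFE are run
#' on the pooled table so every group's model uses the same variables
#' (required for cross-species prediction).
#'
#' @inheritParams recursive_feature_elimination
#' @param r_threshold correlation-pruning threshold.
#' @param rfe run the (cross-validated, hence slower) elimination stage
#'   (default `TRUE`).
#' @return list with `selected`, `pruned` (the correlation-prune result),
#'   `rfe` (`NULL` when skipped) and `importances` (preliminary fit).
#' @export
refine_features <- function(feature_table, label,
                            features = intersect(feature_registry()$name,
                                                 names(feature_table)),
                            r_threshold = 0.70, rfe = TRUE,
                            candidate_sizes = NULL, k_folds = 5,
                            n_trees = 200, seed = 1L) {
  prelim <- train_forest(feature_table, label, features = features,
                         n_trees = n_trees, seed = seed)
  pruned <- correlation_prune(feature_table, prelim$importance,
                              r_threshold = r_threshold, features = features)
  out <- list(pruned = pruned, importances = prelim$importance, rfe = NULL,
              selected = pruned$retained)
  if (rfe) {
    out$rfe <- recursive_feature_elimination(
      feature_table, label, pruned$retained,
      candidate_sizes = candidate_sizes, k_folds = k_folds,
      n_trees = n_trees, seed = seed)
    out$selected <- out$rfe$selected
  }
  out
}
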