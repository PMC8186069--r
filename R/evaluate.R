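# Model scoring: confusion matrices, accuracy/precision/recall/F1,
# fold aggregation, the sampling-frequency sweep, cross-species transfer
# and the random-label null.

#' Confusion matrix of observed vs predicted labels
#'
#' @param observed,predicted label vectors of equal length; the matrix is
#'   square over the union of their levels (observed in rows, predicted in
#'   columns).
#' @return integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(observed, predicted) {
  if (!length(observed)) stop("empty label vectors")
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ")
  lev <- sort(union(as.character(observed), as.character(predicted)))
  m <- table(observed = factor(observed, levels = lev),
             predicted = factor(predicted, levels = lev))
  structure(unclass(m), class = c("confusion_matrix", "matrix"))
}

#' Classification metrics from a confusion matrix
#'
#' Per class (one-vs-rest): precision = TP / (TP + FP), recall =
#' TP / (TP + FN) and F1 = the harmonic mean of the two. Overall accuracy
#' is the proportion of correctly classified rows (trace / total),
#' reported as a percentage. Ratios with zero denominators are reported
#' as 0 and flagged in the `undefined` column. Mean and sd of F1 are
#' taken over classes present in the validation rows (classes never
#' observed contribute no F1).
#'
#' @param cm a [confusion()] matrix.
#' @param accuracy_form `"standard"` for (TP + TN) / total. The
#'   `"printed"` alternative divides each class's TP by the total
#'   (TP + FP + TN + FN) and sums over classes, reproducing a formula
#'   that sometimes appears in print; it equals the standard form only
#'   for the trace-sum and is provided for exactness audits.
#' @return list of class `evaluation_report`: `accuracy_pct`,
#'   `per_class` (data.frame `class`, `precision`, `recall`, `f1`,
#'   `support`, `undefined`), `mean_f1`, `sd_f1`, `n`.
#' @export
classification_metrics <- function(cm,
                                   accuracy_form = c("standard", "printed")) {
  accuracy_form <- match.arg(accuracy_form)
  stopifnot(inherits(cm, "confusion_matrix") || is.matrix(cm))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  undefined <- (tp + fp == 0) | (tp + fn == 0)
  acc <- if (accuracy_form == "standard") {
    sum(tp) / total
  } else {
    # aggregate one-vs-rest counts dropped into the printed formula
    tn <- total - tp - fp - fn
    sum(tp) / (sum(tp) + sum(fp) + sum(tn) + sum(fn))
  }
  present <- rowSums(cm) > 0
  per_class <- data.frame(class = rownames(cm), precision = unname(prec),
                          recall = unname(rec), f1 = unname(f1),
                          support = unname(rowSums(cm)),
                          undefined = unname(undefined),
                          stringsAsFactors = FALSE)
  rownames(per_class) <- NULL
  structure(list(accuracy_pct = 100 * acc, per_class = per_class,
                 mean_f1 = mean(f1[present]),
                 sd_f1 = if (sum(present) > 1) sd(f1[present]) else NA_real_,
                 n = total),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> accuracy %.1f%% | mean F1 %.3f +/- %s | n = %d\n",
              x$accuracy_pct, x$mean_f1,
              ifelse(is.na(x$sd_f1), "NA", sprintf("%.3f", x$sd_f1)), x$n))
  invisible(x)
}

#' Evaluate a model on a validation table
#'
#' @param model a [train_forest()] fit.
#' @param feature_table validation rows.
#' @param label observed labels for those rows.
#' @param ... passed to [classification_metrics()].
#' @return an `evaluation_report`, with the confusion matrix attached as
#'   `$confusion`.
#' @export
evaluate_model <- function(model, feature_table, label, ...) {
  pred <- predict(model, feature_table)
  cm <- confusion(as.character(label), as.character(pred))
  rep <- classification_metrics(cm, ...)
  rep$confusion <- cm
  rep
}

#' Aggregate evaluation reports across folds
#'
#' Unweighted mean and sd, across folds, of overall accuracy and mean F1.
#'
#' @param reports list of `evaluation_report`s.
#' @return data.frame with one row: `n_folds`, `accuracy_pct_mean`,
#'   `accuracy_pct_sd`, `f1_mean`, `f1_sd`.
#' @export
aggregate_folds <- function(reports) {
  if (!length(reports)) stop("no fold reports to aggregate")
  acc <- vapply(reports, `[[`, 0, "accuracy_pct")
  f1 <- vapply(reports, `[[`, 0, "mean_f1")
  data.frame(n_folds = length(reports),
             accuracy_pct_mean = mean(acc),
             accuracy_pct_sd = if (length(acc) > 1) sd(acc) else NA_real_,
             f1_mean = mean(f1),
             f1_sd = if (length(f1) > 1) sd(f1) else NA_real_)
}

# train/evaluate one split of a labelled table
evaluate_split <- function(feature_table, label, split, features,
                           n_trees = 500, seed = 1L) {
  fit <- train_forest(feature_table[split$train, , drop = FALSE],
                      label[split$train], features = features,
                      n_trees = n_trees, seed = seed)
  evaluate_model(fit, feature_table[split$valid, , drop = FALSE],
                 label[split$valid])
}

#' Fit and evaluate a behaviour model under a split design
#'
#' Convenience wrapper running one pipeline cell on a labelled feature
#' table: random split (one report) or all-combinations individual split
#' (mean over folds).
#'
#' @param feature_table a labelled feature table.
#' @param design `"random"` or `"per_individual"`.
#' @param include_slope classify slope-subdivided locomotion labels.
#' @param features feature columns to use.
#' @param n_trees,seed forest settings.
#' @param fraction training fraction.
#' @param max_folds fold cap for the individual design.
#' @return list with `summary` (an [aggregate_folds()] row) and `reports`
#'   (per-fold `evaluation_report`s).
#' @export
evaluate_design <- function(feature_table, design = c("random",
                                                      "per_individual"),
                            include_slope = FALSE,
                            features = intersect(feature_registry()$name,
                                                 names(feature_table)),
                            n_trees = 500, seed = 1L, fraction = 0.6,
                            max_folds = 10L) {
  design <- match.arg(design)
  label <- behaviour_labels(feature_table, include_slope)
  splits <- if (design == "random") {
    list(split_random(feature_table, fraction = fraction, seed = seed,
                      label = label))
  } else {
    split_by_individual(feature_table, fraction = fraction,
                        max_folds = max_folds, seed = seed)
  }
  reports <- lapply(seq_along(splits), function(i)
    evaluate_split(feature_table, label, splits[[i]], features,
                   n_trees = n_trees, seed = seed + i))
  list(summary = aggregate_folds(reports), reports = reports,
       design = design)
}

#' Sampling-frequency and magnetometry sweep
#'
#' Runs the full pipeline cell (decimate, derive features, optionally
#' refine, train, evaluate) for every combination of sampling frequency,
#' magnetometry inclusion and species, under the given split design.
#'
#' @param cohort a [generate_cohort()] cohort.
#' @param frequencies sampling frequencies (Hz), each dividing the
#'   cohort's base rate.
#' @param magnetometry logical vector: include / exclude the magnetometry
#'   variables.
#' @param design split design, `"random"` or `"per_individual"`.
#' @param refine `"none"` (use all registry features) or `"prune"`
#'   (preliminary fit + correlation pruning per cell; the full RFE stage
#'   is available through [refine_features()] and is too slow to run per
#'   sweep cell).
#' @param n_trees,seed,fraction,max_folds forest and split settings.
#' @param include_slope classify slope-subdivided locomotion.
#' @return data.frame with one row per (frequency, magnetometry, species):
#'   `frequency_hz`, `magnetometry`, `species`, `design`, `n_features`,
#'   `accuracy_pct_mean`, `accuracy_pct_sd`, `f1_mean`, `f1_sd`.
#' @export
frequency_sweep <- function(cohort, frequencies = c(40, 20, 10, 5, 1),
                            magnetometry = c(TRUE, FALSE),
                            design = "random", refine = c("prune", "none"),
                            n_trees = 500, seed = 1L, fraction = 0.6,
                            max_folds = 5L, include_slope = FALSE) {
  refine <- match.arg(refine)
  species <- unique(cohort$individuals$species)
  rows <- list()
  for (freq in frequencies) {
    ft_full <- cohort_features(cohort, registry = feature_registry(TRUE),
                               target_hz = freq)
    for (mag in magnetometry) {
      feats <- feature_registry(mag)$name
      for (sp in species) {
        ft <- ft_full[ft_full$species == sp, , drop = FALSE]
        attr(ft, "window_s") <- attr(ft_full, "window_s")
        use <- feats
        if (refine == "prune") {
          lab <- behaviour_labels(ft, include_slope)
          prelim <- train_forest(ft, lab, features = feats,
                                 n_trees = min(n_trees, 150), seed = seed)
          use <- correlation_prune(ft, prelim$importance,
                                   features = feats)$retained
        }
        res <- evaluate_design(ft, design = design,
                               include_slope = include_slope,
                               features = use, n_trees = n_trees,
                               seed = seed, fraction = fraction,
                               max_folds = max_folds)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(frequency_hz = freq, magnetometry = mag, species = sp,
                     design = design, n_features = length(use)),
          res$summary)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-species model transfer
#'
#' Trains entirely on one species' table and evaluates on another's,
#' restricted (by default) to the behaviours present in both, so
#' species-specific behaviours (e.g. climbing, browsing) are excluded
#' from the evaluation rows. An optional sex filter restricts the test
#' individuals (the sex-specific variant for dimorphic species).
#'
#' @param train_table,test_table labelled feature tables for the training
#'   and test species.
#' @param shared_behaviours_only restrict both sides to the shared
#'   behaviour set (default `TRUE`).
#' @param sex_filter optional sex label; keeps only matching test
#'   individuals.
#' @param include_slope classify slope-subdivided locomotion; if either
#'   table lacks slope labels, plain behaviour classes are used.
#' @param features,n_trees,seed forest settings.
#' @return an `evaluation_report` with the fitted model attached as
#'   `$model`.
#' @export
cross_species_transfer <- function(train_table, test_table,
                                   shared_behaviours_only = TRUE,
                                   sex_filter = NULL, include_slope = FALSE,
                                   features = intersect(
                                     feature_registry()$name,
                                     names(train_table)),
                                   n_trees = 500, seed = 1L) {
  if (include_slope &&
      (all(is.na(train_table$slope)) || all(is.na(test_table$slope)))) {
    include_slope <- FALSE  # merge slope classes when either side lacks them
  }
  if (!is.null(sex_filter))
    test_table <- test_table[test_table$sex %in% sex_filter, , drop = FALSE]
  if (shared_behaviours_only) {
    shared <- intersect(unique(train_table$behaviour),
                        unique(test_table$behaviour))
    if (!length(shared)) stop("no shared behaviours between species")
    train_table <- train_table[train_table$behaviour %in% shared, ,
                               drop = FALSE]
    test_table <- test_table[test_table$behaviour %in% shared, , drop = FALSE]
  }
  if (!nrow(test_table)) stop("no test rows after filtering")
  fit <- train_forest(train_table, behaviour_labels(train_table,
                                                    include_slope),
                      features = features, n_trees = n_trees, seed = seed)
  rep <- evaluate_model(fit, test_table,
                        behaviour_labels(test_table, include_slope))
  rep$model <- fit
  rep
}

#' Chance-level reference via randomly generated labels
#'
#' Redraws the behaviour labels i.i.d. with the table's empirical class
#' proportions, then trains and evaluates on a random split, yielding the
#' accuracy a model achieves when labels carry no signal.
#'
#' @param feature_table a labelled feature table.
#' @param include_slope use slope-subdivided locomotion labels.
#' @param features,n_trees,fraction forest and split settings.
#' @param seed integer seed for the label redraw and split.
#' @return an `evaluation_report`; its `$null_labels` holds the redrawn
#'   labels.
#' @export
random_label_null <- function(feature_table, include_slope = FALSE,
                              features = intersect(feature_registry()$name,
                                                   names(feature_table)),
                              n_trees = 500, fraction = 0.6, seed = 1L) {
  lab <- behaviour_labels(feature_table, include_slope)
  if (nlevels(lab) < 2) stop("need at least 2 classes")
  prop <- table(lab) / length(lab)
  set.seed(seed)
  null_lab <- factor(sample(names(prop), length(lab), replace = TRUE,
                            prob = as.numeric(prop)),
                     levels = names(prop))
  split <- split_random(feature_table, fraction = fraction, seed = seed + 1,
                        label = null_lab)
  rep <- evaluate_split(feature_table, null_lab, split, features,
                        n_trees = n_trees, seed = seed + 2)
  rep$null_labels <- null_lab
  rep
}
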