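# Assembling analysis datasets: class balancing, behaviour reduction and
# the two train/validation split designs.

#' Down-sample majority behaviour classes
#'
#' Classes whose total labelled duration (rows times window length)
#' exceeds `threshold_s` are randomly down-sampled, whole windows at a
#' time, to approximately the threshold; classes at or below it are left
#' untouched. Selection is uniform over the class's rows and seeded.
#'
#' @param feature_table a feature table (see [compute_feature_table()]).
#' @param threshold_s duration threshold in seconds, typically
#'   [median_duration_threshold()] of the study ethogram.
#' @param seed integer seed.
#' @param label optional factor of class labels (default
#'   `behaviour_labels(feature_table)`); balancing is performed per label
#'   level, so pass slope-subdivided labels to balance those classes.
#' @return the down-sampled feature table (row order preserved).
#' @export
balance_classes <- function(feature_table, threshold_s, seed = 1L,
                            label = behaviour_labels(feature_table)) {
  stopifnot(threshold_s > 0, length(label) == nrow(feature_table))
  w <- attr(feature_table, "window_s")
  if (is.null(w)) w <- 2
  max_rows <- floor(threshold_s / w)
  set.seed(seed)
  keep <- logical(nrow(feature_table))
  for (cl in levels(factor(label))) {
    idx <- which(label == cl)
    if (length(idx) > max_rows) idx <- sort(sample(idx, max_rows))
    keep[idx] <- TRUE
  }
  out <- feature_table[keep, , drop = FALSE]
  for (a in c("sampling_frequency_hz", "window_s"))
    attr(out, a) <- attr(feature_table, a)
  out
}

#' Remove behaviour classes from a feature table
#'
#' Drops rows whose behaviour is in `drop`; by default the classes
#' usually considered least relevant to ethological studies (aggression,
#' grooming, shaking). Unknown behaviours in `drop` raise an error to
#' guard against typos.
#'
#' @param feature_table a feature table.
#' @param drop character vector of behaviours to remove.
#' @return the reduced feature table.
#' @export
reduce_behaviours <- function(feature_table,
                              drop = c("aggression", "grooming", "shaking")) {
  if (!length(drop)) return(feature_table)
  unknown <- setdiff(drop, unique(feature_table$behaviour))
  if (length(unknown))
    stop("behaviours not present in table: ", paste(unknown, collapse = ", "))
  out <- feature_table[!feature_table$behaviour %in% drop, , drop = FALSE]
  if (!nrow(out)) stop("all behaviour classes dropped: empty dataset")
  for (a in c("sampling_frequency_hz", "window_s"))
    attr(out, a) <- attr(feature_table, a)
  out
}

new_split_plan <- function(design, train, valid, fold = 1L, fraction = 0.6) {
  stopifnot(!anyDuplicated(c(train, valid)))
  structure(list(design = design, train = train, valid = valid,
                 fold = fold, fraction = fraction),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s fold %d: %d train / %d validation rows\n",
              x$design, x$fold, length(x$train), length(x$valid)))
  invisible(x)
}

#' Stratified random train/validation split
#'
#' Splits rows at the target training fraction, stratified by class label
#' so rare behaviours keep their proportion on both sides. Individuals
#' may (and generally do) appear on both sides of the split.
#'
#' @param feature_table a feature table.
#' @param fraction training fraction (default 0.6).
#' @param seed integer seed.
#' @param label stratification labels (default behaviour).
#' @return a `split_plan` with integer row indices `train` and `valid`.
#' @export
split_random <- function(feature_table, fraction = 0.6, seed = 1L,
                         label = behaviour_labels(feature_table)) {
  stopifnot(fraction > 0, fraction < 1, length(label) == nrow(feature_table))
  tab <- table(label)
  if (any(tab < 2))
    stop("class with fewer than 2 rows: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  set.seed(seed)
  train <- integer(0)
  for (cl in levels(factor(label))) {
    idx <- which(label == cl)
    n_tr <- max(1L, round(length(idx) * fraction))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  new_split_plan("random", train, setdiff(seq_len(nrow(feature_table)), train),
                 fraction = fraction)
}

#' All-combinations individual-level splits
#'
#' Enumerates subsets of individuals whose share of rows lies within
#' `tolerance` of the target training fraction and emits one fold per
#' admissible subset, so every fold places each individual wholly in
#' either the training or the validation set. This is the design that
#' estimates performance on unobserved animals. If more than `max_folds`
#' subsets qualify, a seeded subsample of them is used; if none qualify,
#' the subsets closest to the target fraction are used, with a warning.
#'
#' @param feature_table a feature table.
#' @param fraction target training fraction of rows (default 0.6).
#' @param tolerance admissible deviation of the subset's row share from
#'   `fraction` (default 0.10, i.e. 50--70% of rows for the default
#'   fraction).
#' @param max_folds cap on the number of folds (default 20).
#' @param seed seed for the subset subsample when over the cap.
#' @return list of `split_plan`s; each carries the training individuals in
#'   its `train_individuals` field.
#' @export
split_by_individual <- function(feature_table, fraction = 0.6,
                                tolerance = 0.10, max_folds = 20L,
                                seed = 1L) {
  ids <- unique(feature_table$individual_id)
  n_ind <- length(ids)
  if (n_ind < 2) stop("individual-level split needs at least 2 individuals")
  rows_per <- table(factor(feature_table$individual_id, levels = ids))
  n_rows <- nrow(feature_table)

  subsets <- list(); shares <- numeric(0)
  for (k in seq_len(n_ind - 1L)) {
    cmb <- combn(n_ind, k)
    for (j in seq_len(ncol(cmb))) {
      members <- cmb[, j]
      subsets[[length(subsets) + 1L]] <- members
      shares <- c(shares, sum(rows_per[members]) / n_rows)
    }
  }
  ok <- abs(shares - fraction) <= tolerance
  if (!any(ok)) {
    warning("no individual subset within tolerance of the target fraction; ",
            "using the closest subsets")
    ok <- abs(shares - fraction) <= min(abs(shares - fraction)) + 1e-12
  }
  chosen <- which(ok)
  if (length(chosen) > max_folds) {
    set.seed(seed)
    chosen <- sort(sample(chosen, max_folds))
  }
  plans <- vector("list", length(chosen))
  for (f in seq_along(chosen)) {
    members <- subsets[[chosen[f]]]
    tr_ids <- ids[members]
    tr <- which(feature_table$individual_id %in% tr_ids)
    plan <- new_split_plan("per_individual", tr,
                           setdiff(seq_len(n_rows), tr),
                           fold = f, fraction = fraction)
    plan$train_individuals <- tr_ids
    plan$valid_individuals <- setdiff(ids, tr_ids)
    plans[[f]] <- plan
  }
  plans
}
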