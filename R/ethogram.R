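#' Reference Caprid ethogram with observed durations
#'
#' Published observation totals for two captive Caprid species (an Alpine
#' ibex group of 6 individuals and a pygmy goat group of 9), in seconds.
#' Locomotion behaviours (walking, trotting, running, climbing) carry a
#' slope-of-terrain subdivision: flat (-2.5 to 2.5 degrees), uphill
#' (> 2.5 degrees) or downhill (< -2.5 degrees). Ibex were never observed
#' browsing and goats never climbing, so each species contributes ten
#' behaviour classes.
#'
#' These durations are the canonical class-imbalance regime the synthetic
#' cohort generator emulates, and the input to
#' [median_duration_threshold()] used for down-sampling majority classes.
#'
#' @param species optional filter, `"ibex"` or `"goat"`.
#' @return A data.frame with columns `species`, `behaviour`, `slope`
#'   (`NA` for non-locomotion and for the undivided locomotion rows),
#'   `total_s`, `mean_s`, `sd_s` and logical `is_locomotion`. Undivided
#'   locomotion totals have `slope = NA`; the slope subdivisions are
#'   separate rows that sum to them.
#' @export
#' @examples
#' eth <- caprid_ethogram()
#' median_duration_threshold(eth)
caprid_ethogram <- function(species = NULL) {
  row <- function(sp, beh, slope, tot, mn, sdv, loco) {
    data.frame(species = sp, behaviour = beh, slope = slope, total_s = tot,
               mean_s = mn, sd_s = sdv, is_locomotion = loco,
               stringsAsFactors = FALSE)
  }
  ib <- rbind(
    row("ibex", "standing",   NA, 8714.1, 1452.4, 788.9, FALSE),
    row("ibex", "resting",    NA, 6165.9, 1027.6, 648.9, FALSE),
    row("ibex", "eating",     NA, 8104.7, 1350.8, 640.7, FALSE),
    row("ibex", "aggression", NA,  590.7,   98.5,  91.1, FALSE),
    row("ibex", "grooming",   NA,  242.7,   40.4,  43.4, FALSE),
    row("ibex", "shaking",    NA,  164.0,   27.3,  16.4, FALSE),
    row("ibex", "walking",    NA, 6027.7, 1004.6, 118.3, TRUE),
    row("ibex", "walking",    "flat",     4704.2, 784.0, 126.9, TRUE),
    row("ibex", "walking",    "uphill",    668.4, 111.4,  49.5, TRUE),
    row("ibex", "walking",    "downhill",  655.2, 109.2,  48.9, TRUE),
    row("ibex", "trotting",   NA,  327.1,   54.5,  41.5, TRUE),
    row("ibex", "trotting",   "flat",      264.9,  44.2,  28.9, TRUE),
    row("ibex", "trotting",   "uphill",     20.7,   6.9,   8.0, TRUE),
    row("ibex", "trotting",   "downhill",   41.4,  13.8,  10.6, TRUE),
    row("ibex", "running",    NA,  332.9,   55.5,  41.1, TRUE),
    row("ibex", "running",    "flat",      259.2,  43.2,  38.1, TRUE),
    row("ibex", "running",    "uphill",     34.0,   6.8,  38.1, TRUE),
    row("ibex", "running",    "downhill",   39.7,  13.2,  10.7, TRUE),
    row("ibex", "climbing",   NA,  338.4,   28.2,  22.55, TRUE),
    row("ibex", "climbing",   "uphill",    160.0,  26.7,  21.0, TRUE),
    row("ibex", "climbing",   "downhill",  178.4,  29.7,  24.1, TRUE)
  )
  gt <- rbind(
    row("goat", "standing",   NA, 8665.3,  962.8,  315.9, FALSE),
    row("goat", "resting",    NA, 7863.6,  982.9, 1015.3, FALSE),
    row("goat", "eating",     NA, 13295.9, 1477.3, 756.4, FALSE),
    row("goat", "browsing",   NA, 1953.5,  217.2,  412.3, FALSE),
    row("goat", "aggression", NA,  296.9,   33.0,   19.9, FALSE),
    row("goat", "grooming",   NA,  428.5,   53.6,   61.9, FALSE),
    row("goat", "shaking",    NA,   57.8,    6.4,    5.3, FALSE),
    row("goat", "walking",    NA, 5952.8,  661.4,  216.1, TRUE),
    row("goat", "walking",    "flat",     4544.3, 504.9, 158.5, TRUE),
    row("goat", "walking",    "uphill",    649.0,  81.1,  41.2, TRUE),
    row("goat", "walking",    "downhill",  759.6,  94.9,  57.0, TRUE),
    row("goat", "trotting",   NA,  530.1,   58.9,   45.0, TRUE),
    row("goat", "trotting",   "flat",      433.9,  54.2,  32.2, TRUE),
    row("goat", "trotting",   "uphill",     28.2,   7.0,   3.8, TRUE),
    row("goat", "trotting",   "downhill",   68.1,  13.6,  15.5, TRUE),
    row("goat", "running",    NA,  254.8,   28.3,   16.8, TRUE),
    row("goat", "running",    "flat",      240.9,  26.8,  14.8, TRUE),
    row("goat", "running",    "uphill",      9.2,   3.1,   1.5, TRUE),
    row("goat", "running",    "downhill",    4.7,   2.4,   1.5, TRUE)
  )
  out <- rbind(ib, gt)
  if (!is.null(species)) out <- out[out$species %in% species, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise labelled behaviour intervals into an ethogram
#'
#' Computes, per species and behaviour (and per slope category where slope
#' labels are present), the total labelled duration, the mean per-individual
#' total and its standard deviation across individuals. Means and sds are
#' taken over all individuals of the species, counting zero for individuals
#' that never showed the behaviour, so `mean_s = total_s / n_individuals`.
#'
#' @param intervals data.frame of behaviour intervals with columns
#'   `individual_id`, `species`, `start_s`, `end_s`, `behaviour` and
#'   optionally `slope`.
#' @param by_slope also emit slope-subdivided rows for intervals carrying a
#'   non-missing slope label (default `TRUE` when a `slope` column exists).
#' @return data.frame in the same layout as [caprid_ethogram()]: columns
#'   `species`, `behaviour`, `slope`, `total_s`, `mean_s`, `sd_s`.
#'   Undivided totals (over all slopes) have `slope = NA`.
#' @export
ethogram_summary <- function(intervals,
                             by_slope = "slope" %in% names(intervals)) {
  stopifnot(all(c("individual_id", "species", "start_s", "end_s",
                  "behaviour") %in% names(intervals)))
  iv <- as.data.table(intervals)
  iv[, dur := end_s - start_s]
  if (any(iv$dur < 0)) stop("interval with end_s < start_s")

  summarise_group <- function(d, slope_label) {
    # per-individual totals within each species x behaviour cell,
    # zero-filled over the full individual roster of the species
    out <- list()
    for (sp in unique(d$species)) {
      ids <- unique(iv[species == sp, individual_id])
      dsp <- d[species == sp]
      for (beh in unique(dsp$behaviour)) {
        per <- dsp[behaviour == beh, .(s = sum(dur)), by = individual_id]
        tot <- setNames(rep(0, length(ids)), ids)
        tot[as.character(per$individual_id)] <- per$s
        out[[length(out) + 1L]] <- data.frame(
          species = sp, behaviour = beh, slope = slope_label,
          total_s = sum(tot), mean_s = mean(tot),
          sd_s = if (length(tot) > 1) sd(tot) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }

  res <- summarise_group(iv, NA_character_)
  if (by_slope) {
    sl <- iv[!is.na(slope)]
    if (nrow(sl)) {
      parts <- lapply(split(sl, sl$slope), function(d)
        summarise_group(d, unique(d$slope)))
      res <- rbind(res, do.call(rbind, parts))
    }
  }
  rownames(res) <- NULL
  res[order(res$species, res$behaviour, !is.na(res$slope)), ]
}

#' Pooled median class duration used as the down-sampling threshold
#'
#' Pools the undivided per-(species, behaviour) total durations of an
#' ethogram summary across species and returns their median. Locomotion
#' classes enter as their undivided totals (slope subdivisions are ignored).
#' Majority behaviour classes whose labelled duration exceeds this threshold
#' are candidates for random down-sampling by [balance_classes()].
#'
#' @param summary data.frame as returned by [ethogram_summary()] or
#'   [caprid_ethogram()].
#' @return median total duration in seconds.
#' @export
#' @examples
#' median_duration_threshold(caprid_ethogram())  # 560.4
median_duration_threshold <- function(summary) {
  stopifnot(all(c("species", "behaviour", "total_s") %in% names(summary)))
  pooled <- if ("slope" %in% names(summary))
    summary[is.na(summary$slope), , drop = FALSE] else summary
  if (!nrow(pooled)) stop("empty ethogram summary")
  median(pooled$total_s)
}

#' Compare a simulated cohort's behaviour-duration shares with a target
#'
#' Measures how the class imbalance of a simulated cohort matches a target
#' ethogram, per species. Used to configure bout distributions so that
#' dominant classes (eating, standing) and rare ones (shaking) keep their
#' observed proportions.
#'
#' @param cohort a cohort from [generate_cohort()], or a bare intervals
#'   data.frame.
#' @param target data.frame with columns `species`, `behaviour`, `total_s`
#'   (undivided rows; slope rows, if present, are ignored).
#' @return data.frame with per (species, behaviour): `target_share`,
#'   `simulated_share`, `discrepancy` (simulated minus target share) and
#'   `flag` marking classes off by more than `tol`.
#' @param tol absolute share discrepancy above which a class is flagged
#'   (default 0.05).
#' @export
ethogram_realism_check <- function(cohort, target, tol = 0.05) {
  intervals <- if (is.data.frame(cohort)) cohort else cohort$intervals
  if ("slope" %in% names(target)) target <- target[is.na(target$slope), ]
  sim <- ethogram_summary(intervals, by_slope = FALSE)
  out <- list()
  for (sp in unique(target$species)) {
    tg <- target[target$species == sp, ]
    sm <- sim[sim$species == sp, ]
    missing <- setdiff(tg$behaviour, sm$behaviour)
    # behaviours absent from the simulated cohort contribute share 0,
    # but a behaviour the simulator cannot emit at all is an error
    if (length(missing) && !is.null(attr(cohort, "repertoire"))) {
      bad <- setdiff(missing, attr(cohort, "repertoire"))
      if (length(bad))
        stop("target behaviours absent from simulator repertoire: ",
             paste(bad, collapse = ", "))
    }
    tgt_share <- tg$total_s / sum(tg$total_s)
    sim_tot <- setNames(rep(0, nrow(tg)), tg$behaviour)
    hit <- intersect(tg$behaviour, sm$behaviour)
    sim_tot[hit] <- sm$total_s[match(hit, sm$behaviour)]
    sim_share <- if (sum(sim_tot) > 0) sim_tot / sum(sim_tot) else sim_tot
    out[[sp]] <- data.frame(
      species = sp, behaviour = tg$behaviour,
      target_share = tgt_share, simulated_share = as.numeric(sim_share),
      discrepancy = as.numeric(sim_share) - tgt_share,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$flag <- abs(res$discrepancy) > tol
  rownames(res) <- NULL
  res
}
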