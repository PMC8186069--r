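# Metrics, fold aggregation, the sweep/transfer/null stages.

test_that("confusion matrices cross-tabulate exactly", {
  y <- c("a", "a", "b", "b", "c")
  cm <- confusion(y, y)
  expect_equal(diag(cm), c(a = 2, b = 2, c = 1))
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  # hand-counted 2-class example: 3 TP(a), 1 FP(a), 2 TN, 0 FN(a)
  obs <- c("a", "a", "a", "b", "b", "b")
  pred <- c("a", "a", "a", "a", "b", "b")
  cm2 <- confusion(obs, pred)
  expect_equal(unname(unclass(cm2)), rbind(c(3, 0), c(1, 2)))

  expect_error(confusion(character(0), character(0)), "empty")
  expect_error(confusion(c("a", "b"), "a"), "lengths differ")
})

test_that("metrics match the hand-derived values", {
  # perfect prediction
  m <- classification_metrics(confusion(c("a", "b", "b"), c("a", "b", "b")))
  expect_equal(m$accuracy_pct, 100)
  expect_equal(m$per_class$f1, c(1, 1))

  # [[3,0],[1,2]]: class-a precision 3/4, recall 1, F1 6/7
  cm <- confusion(c(rep("a", 3), rep("b", 3)),
                  c(rep("a", 3), "a", "b", "b"))
  m2 <- classification_metrics(cm)
  a_row <- m2$per_class[m2$per_class$class == "a", ]
  expect_equal(a_row$precision, 0.75)
  expect_equal(a_row$recall, 1)
  expect_equal(a_row$f1, 6 / 7)
  expect_equal(m2$accuracy_pct, 100 * 5 / 6)

  # harmonic-mean identity when precision == recall
  expect_equal(2 / (1 / 0.5 + 1 / 0.5), 0.5)

  # undefined ratios are zero-filled and flagged
  cm3 <- confusion(c("a", "a", "b"), c("a", "a", "a"))
  m3 <- classification_metrics(cm3)
  b_row <- m3$per_class[m3$per_class$class == "b", ]
  expect_equal(b_row$recall, 0)
  expect_true(b_row$undefined | b_row$f1 == 0)
})

test_that("self-prediction scores 100% for arbitrary label vectors", {
  set.seed(21)
  for (i in 1:20) {
    y <- sample(letters[1:sample(2:6, 1)], sample(5:60, 1), replace = TRUE)
    m <- classification_metrics(confusion(y, y))
    expect_equal(m$accuracy_pct, 100)
  }
})

test_that("accuracy equals the prevalence-weighted mean of recalls", {
  set.seed(22)
  for (i in 1:20) {
    k <- sample(2:5, 1); n <- sample(30:100, 1)
    obs <- sample(letters[1:k], n, replace = TRUE)
    pred <- sample(letters[1:k], n, replace = TRUE)
    cm <- confusion(obs, pred)
    m <- classification_metrics(cm)
    w <- m$per_class$support / sum(m$per_class$support)
    expect_equal(m$accuracy_pct / 100, sum(w * m$per_class$recall))
  }
})

test_that("fold aggregation is the unweighted mean and sd", {
  mk <- function(acc, f1) structure(list(accuracy_pct = acc, mean_f1 = f1),
                                    class = "evaluation_report")
  same <- aggregate_folds(list(mk(80, 0.7), mk(80, 0.7)))
  expect_equal(same$accuracy_pct_sd, 0)
  two <- aggregate_folds(list(mk(40, 0.4), mk(60, 0.6)))
  expect_equal(two$accuracy_pct_mean, 50)
  expect_equal(two$f1_mean, 0.5)

  set.seed(23)
  accs <- runif(10, 40, 100); f1s <- runif(10)
  agg <- aggregate_folds(Map(mk, accs, f1s))
  expect_equal(agg$accuracy_pct_mean, mean(accs))
  expect_equal(agg$accuracy_pct_sd, sd(accs))
})

test_that("magnetometry rescues heading-distinguished behaviour pairs", {
  # two behaviours with identical accelerometry, differing only in how
  # fast the animal turns: only the magnetometer can tell them apart
  calm <- behaviour_profile("calm_stand", heading_volatility = 0.05)
  turny <- behaviour_profile("turning_stand", heading_volatility = 4)
  sp <- species_profile("test", list(calm, turny), individual_sd = 0)
  cfg <- simulation_config(species_profiles = list(test = sp),
                           n_individuals = c(test = 3),
                           total_duration_s = 300, seed = 24)
  co <- generate_cohort(cfg)
  ft <- cohort_features(co, target_hz = 10)
  with_mag <- evaluate_design(ft, "random", n_trees = 150, seed = 1,
                              features = feature_registry(TRUE)$name)
  no_mag <- evaluate_design(ft, "random", n_trees = 150, seed = 1,
                            features = feature_registry(FALSE)$name)
  expect_gt(with_mag$summary$accuracy_pct_mean,
            no_mag$summary$accuracy_pct_mean + 10)
})

test_that("random-label null scores at chance level", {
  ft <- labelled_table(n = 400, classes = letters[1:4], effect = 1.5,
                       seed = 25)
  null <- random_label_null(ft, features = grep("^(inf|noise)_", names(ft),
                                                value = TRUE),
                            n_trees = 150, seed = 26)
  expect_lt(abs(null$accuracy_pct - 25), 8)  # 4 balanced classes
  # redrawn label proportions match the empirical ones
  prop_in <- table(ft$behaviour) / nrow(ft)
  prop_out <- table(null$null_labels) / nrow(ft)
  expect_equal(as.numeric(prop_out), as.numeric(prop_in), tolerance = 0.12)
  # a trained model on real labels beats the null handily
  real <- evaluate_design(ft, "random", n_trees = 150, seed = 26,
                          features = grep("^(inf|noise)_", names(ft),
                                          value = TRUE))
  expect_gt(real$summary$accuracy_pct_mean, null$accuracy_pct + 20)
})

test_that("transfer between identical species matches within-species", {
  profs <- default_species_profiles(individual_sd = 0)
  profs$goat <- profs$ibex  # make the two species indistinguishable
  profs$goat$species <- "goat"
  cfg <- simulation_config(species_profiles = profs,
                           n_individuals = c(ibex = 3, goat = 3),
                           total_duration_s = 420, seed = 27)
  co <- generate_cohort(cfg)
  ft <- cohort_features(co, target_hz = 10)
  fa <- drop_rare(species_table(ft, "ibex"))
  fb <- drop_rare(species_table(ft, "goat"))
  within <- evaluate_design(fa, "random", n_trees = 150,
                            seed = 2)$summary$accuracy_pct_mean
  tr <- cross_species_transfer(fb, fa, n_trees = 150, seed = 2)
  expect_gt(tr$accuracy_pct, within - 5)
})

test_that("species-specific behaviours are excluded from transfer rows", {
  ft <- labelled_table(n = 240, classes = c("walking", "standing"),
                       effect = 2, seed = 28)
  test_ft <- labelled_table(n = 120, classes = c("walking", "standing",
                                                 "climbing"),
                            effect = 2, seed = 29)
  rep <- cross_species_transfer(
    ft, test_ft, n_trees = 100, seed = 3,
    features = grep("^(inf|noise)_", names(ft), value = TRUE))
  expect_equal(rep$n, sum(test_ft$behaviour != "climbing"))
  expect_false("climbing" %in% rownames(rep$confusion))
})

test_that("slope classes are learnable only through the slope-pitch effect", {
  mk_cohort <- function(pitch_effect) {
    cfg <- simulation_config(n_individuals = c(ibex = 3, goat = 0),
                             total_duration_s = 500,
                             slope_effort = c(uphill = 1, downhill = 1),
                             slope_pitch_effect = pitch_effect,
                             seed = 30)
    generate_cohort(cfg)
  }
  run <- function(co) {
    ft <- cohort_features(co, target_hz = 10)
    ft <- ft[!is.na(ft$slope) & ft$behaviour == "walking", ]
    attr(ft, "window_s") <- 2
    tab <- table(ft$slope)
    if (any(tab < 4)) ft <- ft[ft$slope %in% names(tab)[tab >= 4], ]
    lab <- factor(ft$slope)
    sp <- split_random(ft, seed = 4, label = lab)
    fit <- train_forest(ft[sp$train, ], lab[sp$train], n_trees = 150,
                        seed = 4)
    mean(as.character(predict(fit, ft[sp$valid, ])) == lab[sp$valid])
  }
  acc_sloped <- run(mk_cohort(TRUE))
  # same slope labels, but the gradient no longer tilts the device:
  # the postural cue is gone and slope recall collapses
  acc_flat <- run(mk_cohort(FALSE))
  expect_gt(acc_sloped, 0.85)
  expect_lt(acc_flat, acc_sloped - 0.15)
})
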