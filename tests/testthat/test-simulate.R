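# Synthetic stream generator: orientation model, labelling, determinism.

test_that("static behaviour at zero noise reads pure gravity", {
  beh <- behaviour_profile("standing")
  sp <- one_behaviour_species(beh)
  cfg <- simulation_config(species_profiles = list(test = sp),
                           n_individuals = c(test = 1),
                           total_duration_s = 30, accel_noise_sd_g = 0,
                           mag_noise_sd = 0, seed = 1)
  out <- generate_stream(sp, neutral_individual(), cfg, seed = 5)
  expect_equal(max(abs(out$stream$acc[, 1])), 0)
  expect_equal(max(abs(out$stream$acc[, 2])), 0)
  expect_equal(max(abs(out$stream$acc[, 3] - 1)), 0)
  # acceleration norm is exactly 1 g at every sample
  expect_equal(range(sqrt(rowSums(out$stream$acc^2))), c(1, 1))
})

test_that("uphill locomotion tilts the static surge axis by the slope angle", {
  beh <- behaviour_profile("walking", stride_hz = 1.2, amp_g = c(0, 0, 0),
                           is_locomotion = TRUE,
                           slope_repertoire = c(uphill = 1))
  sp <- one_behaviour_species(beh)
  cfg <- simulation_config(species_profiles = list(test = sp),
                           n_individuals = c(test = 1),
                           total_duration_s = 60, accel_noise_sd_g = 0,
                           mag_noise_sd = 0,
                           slope_deg_range = c(10, 10), seed = 2)
  out <- generate_stream(sp, neutral_individual(), cfg, seed = 9)
  # closed-form inverse of the rotation, applied sample-wise
  pitch <- asin(pmin(1, pmax(-1, out$stream$acc[, 1]))) * 180 / pi
  expect_equal(mean(pitch), 10, tolerance = 1e-6)
  expect_true(all(out$intervals$slope == "uphill"))
  expect_equal(unique(out$intervals$slope_deg), 10)
})

test_that("same seed reproduces the stream bit-for-bit; seeds differ", {
  cfg <- tiny_config(n_ibex = 1, n_goat = 1, duration_s = 60, seed = 3)
  sp <- cfg$species_profiles$ibex
  ind <- neutral_individual("ib_01", "ibex")
  a <- generate_stream(sp, ind, cfg, seed = 42)
  b <- generate_stream(sp, ind, cfg, seed = 42)
  c <- generate_stream(sp, ind, cfg, seed = 43)
  expect_identical(a$stream$acc, b$stream$acc)
  expect_identical(a$stream$mag, b$stream$mag)
  expect_identical(a$intervals, b$intervals)
  expect_false(identical(a$stream$acc, c$stream$acc))
})

test_that("intervals tile each stream with no gaps or overlaps", {
  co <- generate_cohort(tiny_config(duration_s = 90, seed = 7))
  for (id in names(co$streams)) {
    iv <- co$intervals[co$intervals$individual_id == id, ]
    iv <- iv[order(iv$start_s), ]
    expect_equal(iv$start_s[1], 0)
    expect_equal(iv$end_s[nrow(iv)], co$config$total_duration_s)
    if (nrow(iv) > 1)
      expect_equal(iv$start_s[-1], iv$end_s[-nrow(iv)])
  }
})

test_that("slope categories are consistent with the signed slope angle", {
  co <- generate_cohort(tiny_config(duration_s = 300, seed = 13))
  iv <- co$intervals
  loco <- iv[!is.na(iv$slope), ]
  expect_gt(nrow(loco), 0)
  expect_identical(loco$slope, slope_category(loco$slope_deg))
  expect_true(all(is.na(iv$slope_deg[is.na(iv$slope)])))
  # the boundary definition itself
  expect_identical(slope_category(c(-2.5, 0, 2.5, 2.6, -2.6)),
                   c("flat", "flat", "flat", "uphill", "downhill"))
})

test_that("cohorts are seeded: identical at same seed, distinct otherwise", {
  a <- generate_cohort(tiny_config(seed = 21))
  b <- generate_cohort(tiny_config(seed = 21))
  c <- generate_cohort(tiny_config(seed = 22))
  expect_identical(a$intervals, b$intervals)
  expect_identical(a$streams[[1]]$acc, b$streams[[1]]$acc)
  expect_false(identical(a$intervals, c$intervals))
})

test_that("individual_sd = 0 collapses individual variation", {
  co <- generate_cohort(tiny_config(n_ibex = 3, n_goat = 2,
                                    individual_sd = 0, seed = 5))
  ib <- co$individuals[co$individuals$species == "ibex", ]
  expect_equal(ib$stride_scale, rep(1, 3))
  expect_equal(ib$amp_scale, rep(1, 3))
  expect_equal(ib$pitch_offset_deg, rep(0, 3))
  expect_equal(length(co$streams), 5)
})

test_that("species stride_scale shifts the dominant gait frequency", {
  walk <- function(scale) {
    beh <- behaviour_profile("walking", stride_hz = 1.2,
                             amp_g = c(0.25, 0.15, 0.35),
                             is_locomotion = TRUE,
                             slope_repertoire = c(flat = 1))
    sp <- one_behaviour_species(beh)
    sp$stride_scale <- scale
    cfg <- simulation_config(species_profiles = list(test = sp),
                             n_individuals = c(test = 1),
                             total_duration_s = 60, accel_noise_sd_g = 0.01,
                             seed = 1)
    out <- generate_stream(sp, neutral_individual(), cfg, seed = 31)
    # independent periodogram peak on the heave axis
    z <- out$stream$acc[, 3] - mean(out$stream$acc[, 3])
    spec <- Mod(fft(z))[2:(length(z) / 2)]
    freq <- (seq_along(spec)) * 40 / length(z)
    freq[which.max(spec)]
  }
  f_ibex <- walk(0.6); f_goat <- walk(1.0)
  expect_equal(f_ibex / f_goat, 0.6, tolerance = 0.1)
})

test_that("realism check flags under-represented dominant classes", {
  target <- caprid_ethogram("ibex")
  # uniform simulated shares across the ten ibex behaviours
  beh10 <- unique(target$behaviour[is.na(target$slope)])
  iv <- data.frame(individual_id = "x", species = "ibex", sex = "female",
                   start_s = seq_along(beh10) * 10 - 10,
                   end_s = seq_along(beh10) * 10,
                   behaviour = beh10, stringsAsFactors = FALSE)
  rep <- ethogram_realism_check(iv, target)
  standing <- rep[rep$behaviour == "standing", ]
  expect_lt(standing$discrepancy, 0)   # under-represented
  expect_true(standing$flag)

  # target equal to simulated shares: all discrepancies zero
  tgt2 <- data.frame(species = "ibex", behaviour = beh10, total_s = 10)
  rep2 <- ethogram_realism_check(iv, tgt2)
  expect_equal(rep2$discrepancy, rep(0, length(beh10)))

  # hand-built 3-interval cohort matches manual share sums
  iv3 <- data.frame(individual_id = "x", species = "ibex", sex = "female",
                    start_s = c(0, 10, 40), end_s = c(10, 40, 100),
                    behaviour = c("standing", "eating", "walking"),
                    stringsAsFactors = FALSE)
  tgt3 <- data.frame(species = "ibex",
                     behaviour = c("standing", "eating", "walking"),
                     total_s = c(50, 25, 25))
  rep3 <- ethogram_realism_check(iv3, tgt3)
  expect_equal(rep3$simulated_share, c(0.1, 0.3, 0.6))
  expect_equal(rep3$discrepancy, c(0.1, 0.3, 0.6) - c(0.5, 0.25, 0.25))
})
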