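# Windowed variable derivation: decomposition, VeDBA, posture,
# oscillation amplitudes, magnetometry, decimation, table assembly.

test_that("static/dynamic decomposition is exact and handles edges", {
  # constant stream: static carries it all
  acc <- matrix(rep(c(0, 0, 1), each = 200), 200, 3)
  d <- decompose_static_dynamic(acc, window_s = 2, sample_rate_hz = 40)
  expect_equal(d$static, acc)
  expect_equal(max(abs(d$dynamic)), 0)

  # reconstruction on arbitrary input, including the edges: the dynamic
  # component is bit-identical to raw minus static, and the sum recovers
  # the raw signal to within one ulp
  set.seed(4)
  acc <- matrix(rnorm(600), 200, 3)
  d <- decompose_static_dynamic(acc, window_s = 2, sample_rate_hz = 40)
  expect_identical(d$dynamic, acc - d$static)
  expect_lt(max(abs(d$static + d$dynamic - acc)), 1e-14)

  # running mean agrees with a naive windowed mean (independent oracle)
  x <- rnorm(50)
  half <- 7L
  naive <- vapply(seq_along(x), function(i)
    mean(x[max(1, i - half):min(50, i + half)]), 0)
  got <- decompose_static_dynamic(cbind(x, 0, 0), window_s = 15 / 40,
                                  sample_rate_hz = 40)$static[, 1]
  expect_equal(got, naive)
})

test_that("fast oscillations end up in the dynamic component", {
  fs <- 40; t <- (0:799) / fs
  acc <- cbind(0, 0, 1 + 0.3 * sin(2 * pi * 4 * t))  # period 0.25 s << 2 s
  d <- decompose_static_dynamic(acc, window_s = 2, sample_rate_hz = fs)
  core <- 41:760  # away from shrinking edges
  expect_lt(max(abs(d$static[core, 3] - 1)), 0.01)
  expect_equal(d$dynamic[core, 3], acc[core, 3] - d$static[core, 3])
})

test_that("VeDBA is the dynamic norm and smoothing recovers 2A/pi", {
  expect_equal(vedba(matrix(0, 10, 3)), rep(0, 10))
  expect_equal(vedba(matrix(c(0.3, 0, 0.4), 1)), 0.5)  # 3-4-5 triangle
  # mean absolute sine of amplitude A is 2A/pi
  fs <- 40; t <- (0:(40 * fs - 1)) / fs; A <- 0.8
  # discrete sampling at 20 points per period sits ~0.8% under the
  # continuous integral, hence the 1% band
  v <- vedba(cbind(A * sin(2 * pi * 2 * t), 0, 0))
  expect_equal(mean(v), 2 * A / pi, tolerance = 0.01)
  sm <- smooth_series(v, 2, fs)
  expect_equal(mean(sm[81:(length(sm) - 80)]), 2 * A / pi, tolerance = 0.01)
})

test_that("posture angles invert the gravity rotation", {
  expect_equal(posture_angles(matrix(c(0, 0, 1), 1)),
               list(pitch_deg = 0, roll_deg = 0))
  expect_equal(posture_angles(matrix(c(1, 0, 0), 1))$pitch_deg, 90)
  th <- 10 * pi / 180
  got <- posture_angles(matrix(c(sin(th), 0, cos(th)), 1))
  expect_equal(got$pitch_deg, 10, tolerance = 1e-10)
  expect_error(posture_angles(matrix(0, 1, 3)), "zero-norm")
  # range invariant on random inputs
  set.seed(8)
  pa <- posture_angles(matrix(rnorm(300), 100, 3) + 1e-6)
  expect_true(all(pa$pitch_deg >= -90 & pa$pitch_deg <= 90))
  expect_true(all(pa$roll_deg >= -90 & pa$roll_deg <= 90))
})

test_that("oscillation amplitude recovers pure tones (direct-DFT oracle)", {
  fs <- 40; w <- 2; n <- fs * w
  expect_equal(oscillation_amplitude(rep(3, 2 * n), w, fs), c(0, 0))
  # tone whose period divides the window
  A <- 0.7; f <- 2.5
  t <- (0:(4 * n - 1)) / fs
  x <- A * sin(2 * pi * f * t + 0.3)
  got <- oscillation_amplitude(x, w, fs)
  # independent oracle: direct DFT sum at each bin of the first window
  xs <- x[1:n] - mean(x[1:n])
  k <- 1:(n / 2)
  direct <- vapply(k, function(kk)
    Mod(sum(xs * exp(-2i * pi * kk * (0:(n - 1)) / n))), 0)
  expect_equal(got[1], 2 * max(direct) / n)
  expect_equal(got, rep(A, 4), tolerance = 1e-10)
  # white-noise amplitude decreases with window length (Monte-Carlo)
  set.seed(9)
  amp_short <- mean(oscillation_amplitude(rnorm(4000), 1, fs))
  amp_long <- mean(oscillation_amplitude(rnorm(4000), 4, fs))
  expect_gt(amp_short, amp_long)
})

test_that("magnetometry features: constants, rotation rate, symmetry", {
  fs <- 40
  const <- matrix(rep(c(0.4, 0.1, -0.8), each = 200), 200, 3)
  mf <- magnetometry_features(const, 2, fs)
  expect_equal(unname(unlist(mf[1, ])), rep(0, 5))

  # field rotating about the vertical at omega: angular change = omega/fs
  omega <- 30  # deg/s
  t <- (0:799) / fs
  rot <- cbind(cos(omega * pi / 180 * t), sin(omega * pi / 180 * t), 0)
  mf <- magnetometry_features(rot, 2, fs)
  expect_equal(mean(mf$mag_angular_change), omega / fs, tolerance = 1e-6)

  # permuting axes permutes per-axis sds, leaves combined features alone
  set.seed(2)
  m <- matrix(rnorm(600, sd = 0.2), 200, 3) + 1
  a <- magnetometry_features(m, 2, fs)
  b <- magnetometry_features(m[, c(2, 3, 1)], 2, fs)
  expect_equal(unname(b[, 1:3]), unname(a[, c(2, 3, 1)]))
  expect_equal(b$mag_norm_sd, a$mag_norm_sd)
  expect_equal(b$mag_angular_change, a$mag_angular_change)
  expect_error(magnetometry_features(matrix(0, 10, 3), 2, fs), "degenerate")
})

test_that("decimation keeps every k-th sample and is order-sensitive", {
  co <- generate_cohort(tiny_config(n_ibex = 1, n_goat = 1,
                                    duration_s = 30, seed = 17))
  s <- co$streams[[1]]
  d <- subsample_stream(s, 10)
  expect_equal(d$sample_rate_hz, 10)
  expect_equal(length(d$time_s), ceiling(length(s$time_s) / 4))
  expect_identical(d$acc[2, ], s$acc[5, ])
  expect_identical(subsample_stream(s, 40), s)
  expect_error(subsample_stream(s, 7), "divide")

  # decimate-then-decompose differs from decompose-then-decimate
  dec_first <- decompose_static_dynamic(subsample_stream(s, 10))$static
  dec_last <- decompose_static_dynamic(s)$static[seq(1, length(s$time_s), 4), ]
  expect_gt(max(abs(dec_first - dec_last)), 1e-6)
})

test_that("feature table: window counts, straddle dropping, registry width", {
  beh <- behaviour_profile("standing")
  sp <- one_behaviour_species(beh)
  cfg <- simulation_config(species_profiles = list(test = sp),
                           n_individuals = c(test = 1),
                           total_duration_s = 60, seed = 3)
  out <- generate_stream(sp, neutral_individual(), cfg, seed = 21)
  one_iv <- data.frame(individual_id = "t_01", start_s = 0, end_s = 60,
                       behaviour = "standing", slope = NA_character_)
  ft <- compute_feature_table(out$stream, one_iv)
  expect_equal(nrow(ft), 30)
  expect_equal(unique(ft$behaviour), "standing")
  expect_equal(ncol(ft) - 6, 39)   # meta columns + full registry
  expect_false(anyNA(ft[, feature_registry()$name]))

  # a boundary at 3 s makes window [2,4) straddle: it must be dropped
  two_iv <- data.frame(individual_id = "t_01", start_s = c(0, 3),
                       end_s = c(3, 60), behaviour = c("walking", "standing"),
                       slope = NA_character_)
  ft2 <- compute_feature_table(out$stream, two_iv)
  expect_equal(nrow(ft2), 29)
  expect_false(2 %in% ft2$window_start_s)
  expect_equal(attr(ft2, "n_dropped_straddling"), 1)
})

test_that("zero-noise standing windows recover the configured pitch", {
  beh <- behaviour_profile("standing", pitch_deg = -12, roll_deg = 5)
  sp <- one_behaviour_species(beh)
  cfg <- simulation_config(species_profiles = list(test = sp),
                           n_individuals = c(test = 1),
                           total_duration_s = 30, accel_noise_sd_g = 0,
                           mag_noise_sd = 0, seed = 4)
  out <- generate_stream(sp, neutral_individual(), cfg, seed = 8)
  ft <- compute_feature_table(out$stream, out$intervals)
  expect_lt(max(abs(ft$pitch_mean - (-12))), 0.1)
})

test_that("slope-subdivided labels merge and split as requested", {
  co <- generate_cohort(tiny_config(duration_s = 240, seed = 19))
  ft <- cohort_features(co, target_hz = 10)
  plain <- behaviour_labels(ft)
  slp <- behaviour_labels(ft, include_slope = TRUE)
  expect_true(all(levels(plain) %in% unique(ft$behaviour)))
  loco <- !is.na(ft$slope)
  if (any(loco)) {
    expect_true(all(grepl("_(flat|uphill|downhill)$", as.character(slp)[loco])))
    expect_identical(as.character(plain)[!loco], as.character(slp)[!loco])
  }
})
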