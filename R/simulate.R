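# Synthetic collar-sensor streams.
#
# Orientation model: intrinsic heading (about the world vertical), then
# pitch (about sway), then roll (about surge); device frame x = surge,
# y = sway, z = heave. With pitch p and roll r the gravity vector reads
# (sin p, cos p sin r, cos p cos r) in the device frame, so pitch is
# recoverable as asin(static surge) and heading leaves gravity untouched --
# heading is only observable through the magnetometer.

#' Construct a sensor stream
#'
#' @param individual_id,species,sex metadata labels.
#' @param sample_rate_hz sampling frequency.
#' @param time_s numeric timestamps, uniformly spaced at
#'   `1/sample_rate_hz`.
#' @param acc n x 3 acceleration matrix (g), columns surge/sway/heave.
#' @param mag n x 3 magnetometer matrix (arbitrary units).
#' @return object of class `sensor_stream`.
#' @export
sensor_stream <- function(individual_id, species, sex, sample_rate_hz,
                          time_s, acc, mag) {
  acc <- as.matrix(acc); mag <- as.matrix(mag)
  stopifnot(nrow(acc) == length(time_s), nrow(mag) == length(time_s),
            ncol(acc) == 3, ncol(mag) == 3, sample_rate_hz > 0)
  if (length(time_s) > 1) {
    dt <- diff(time_s)
    stopifnot(all(dt > 0),
              max(abs(dt - 1 / sample_rate_hz)) < 1e-8 / sample_rate_hz + 1e-9)
  }
  colnames(acc) <- c("x", "y", "z"); colnames(mag) <- c("x", "y", "z")
  structure(list(individual_id = individual_id, species = species, sex = sex,
                 sample_rate_hz = sample_rate_hz, time_s = time_s,
                 acc = acc, mag = mag),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %s (%s, %s): %d samples @ %g Hz (%.1f s)\n",
              x$individual_id, x$species, x$sex, length(x$time_s),
              x$sample_rate_hz, length(x$time_s) / x$sample_rate_hz))
  invisible(x)
}

#' Slope category from a signed slope angle
#'
#' Flat between -2.5 and 2.5 degrees, uphill above 2.5, downhill below
#' -2.5 (uphill positive).
#'
#' @param angle_deg signed slope angle(s), degrees.
#' @return character vector in `c("flat", "uphill", "downhill")`.
#' @export
slope_category <- function(angle_deg) {
  ifelse(angle_deg > 2.5, "uphill",
         ifelse(angle_deg < -2.5, "downhill", "flat"))
}

# world->device rotation for constant pitch/roll: M = Rx(-roll) Ry(pitch)
rotation_pitch_roll <- function(pitch_deg, roll_deg) {
  p <- pitch_deg * pi / 180; r <- roll_deg * pi / 180
  ry <- rbind(c(cos(p), 0, sin(p)), c(0, 1, 0), c(-sin(p), 0, cos(p)))
  rx <- rbind(c(1, 0, 0), c(0, cos(r), sin(r)), c(0, -sin(r), cos(r)))
  rx %*% ry
}

# reflect a random walk into [lo, hi]
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  y <- (x - lo) %% (2 * width)
  lo + ifelse(y > width, 2 * width - y, y)
}

draw_bout_sequence <- function(sp, config) {
  total <- config$total_duration_s
  weights <- vapply(sp$behaviours, `[[`, 0, "weight")
  bouts <- list(); t0 <- 0
  while (t0 < total) {
    dur <- rlnorm(1, log(config$bout_median_s), config$bout_sdlog)
    dur <- min(dur, total - t0)
    beh <- sp$behaviours[[sample(length(weights), 1, prob = weights)]]
    slope_deg <- NA_real_; slope <- NA_character_
    if (isTRUE(beh$is_locomotion)) {
      rep_w <- if (!is.null(beh$slope_repertoire)) beh$slope_repertoire
               else sp$slope_repertoire
      if (!length(rep_w)) stop("empty slope repertoire for ", beh$name)
      slope <- names(rep_w)[sample(length(rep_w), 1, prob = rep_w)]
      slope_deg <- switch(slope,
        flat = runif(1, -2.5, 2.5),
        uphill = runif(1, config$slope_deg_range[1], config$slope_deg_range[2]),
        downhill = -runif(1, config$slope_deg_range[1],
                          config$slope_deg_range[2]),
        stop("unknown slope category: ", slope))
    }
    bouts[[length(bouts) + 1L]] <- list(behaviour = beh$name, start = t0,
                                        end = t0 + dur, slope = slope,
                                        slope_deg = slope_deg)
    t0 <- t0 + dur
  }
  bouts
}

#' Generate a labelled sensor stream for one individual
#'
#' Simulates a collar-mounted tri-axial accelerometer and magnetometer
#' recording as a sequence of behaviour bouts. Each bout has a posture
#' (behaviour pitch/roll plus the individual's collar offset, plus the
#' terrain slope angle for locomotion), a gait oscillation (fundamental
#' sinusoid plus one harmonic, per-axis phases with heave leading surge by
#' 90 degrees), a bounded heading random walk with behaviour-specific
#' volatility, and additive Gaussian sensor noise. The magnetometer reads
#' the local field vector rotated into the device frame by the same
#' orientation, so heading dynamics are observable only through it.
#' Uphill/downhill bouts scale gait amplitude by the configured effort
#' factors.
#'
#' @param species_prof [species_profile()].
#' @param individual [individual_profile()].
#' @param config [simulation_config()].
#' @param seed integer seed; the same seed reproduces the stream
#'   bit-for-bit.
#' @return list with `stream` ([sensor_stream()]) and `intervals`
#'   (data.frame `individual_id`, `species`, `sex`, `start_s`, `end_s`,
#'   `behaviour`, `slope`, `slope_deg`), half-open `[start_s, end_s)`
#'   intervals tiling the stream without gaps or overlaps.
#' @export
generate_stream <- function(species_prof, individual, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sample_rate_hz
  n_total <- round(config$total_duration_s * fs)
  if (n_total < 1) stop("non-positive duration")

  bouts <- draw_bout_sequence(species_prof, config)
  acc <- matrix(0, n_total, 3); mag <- matrix(0, n_total, 3)
  heading <- runif(1, -180, 180)
  iv <- vector("list", length(bouts))

  for (k in seq_along(bouts)) {
    b <- bouts[[k]]
    beh <- species_prof$behaviours[[b$behaviour]]
    i0 <- round(b$start * fs) + 1L; i1 <- round(b$end * fs)
    iv[[k]] <- data.frame(individual_id = individual$individual_id,
                          species = individual$species, sex = individual$sex,
                          start_s = b$start, end_s = b$end,
                          behaviour = b$behaviour, slope = b$slope,
                          slope_deg = b$slope_deg, stringsAsFactors = FALSE)
    if (i1 < i0) next  # bout shorter than half a sample: label only
    n <- i1 - i0 + 1L
    tt <- (seq_len(n) - 1L) / fs

    is_male <- identical(individual$sex, "male")
    sex_stride <- if (is_male) species_prof$male_stride_factor else 1
    sex_amp <- if (is_male) species_prof$male_amp_factor else 1
    sex_pitch <- if (is_male) species_prof$male_pitch_offset_deg %||% 0 else 0
    slope_tilt <- if (isFALSE(config$slope_pitch_effect)) 0
                  else ifelse(is.na(b$slope_deg), 0, b$slope_deg)
    pitch <- beh$pitch_deg + individual$posture_offset_deg[1] + sex_pitch +
      slope_tilt
    roll <- beh$roll_deg + individual$posture_offset_deg[2]
    effort <- if (is.na(b$slope)) 1
              else switch(b$slope, uphill = config$slope_effort[["uphill"]],
                          downhill = config$slope_effort[["downhill"]], 1)
    amp <- beh$amp_g * individual$amp_scale * sex_amp * effort
    freq <- beh$stride_hz * species_prof$stride_scale *
      individual$stride_scale * sex_stride

    M <- rotation_pitch_roll(pitch, roll)
    grav <- M[, 3]  # device-frame gravity, unit norm

    dyn <- matrix(0, n, 3)
    if (freq > 0 && any(amp > 0)) {
      ph0 <- runif(1, 0, 2 * pi)
      phase <- c(ph0, ph0 + pi, ph0 + pi / 2)  # heave leads surge by 90 deg
      for (j in 1:3) {
        w <- 2 * pi * freq * tt + phase[j]
        dyn[, j] <- amp[j] * (sin(w) + beh$harmonic_ratio * sin(2 * w))
      }
    }

    steps <- rnorm(n, 0, beh$heading_volatility)
    psi <- reflect_into(heading + cumsum(steps), heading - 60, heading + 60)
    heading <- psi[n]
    psi_r <- psi * pi / 180
    mw <- config$local_field_vector
    m1 <- cbind(cos(psi_r) * mw[1] + sin(psi_r) * mw[2],
                -sin(psi_r) * mw[1] + cos(psi_r) * mw[2],
                rep(mw[3], n))
    mdev <- m1 %*% t(M)

    idx <- i0:i1
    acc[idx, ] <- rep(grav, each = n) + dyn +
      matrix(rnorm(3 * n, 0, config$accel_noise_sd_g), n, 3)
    mag[idx, ] <- mdev + matrix(rnorm(3 * n, 0, config$mag_noise_sd), n, 3)
  }

  stream <- sensor_stream(individual$individual_id, individual$species,
                          individual$sex, fs, (seq_len(n_total) - 1L) / fs,
                          acc, mag)
  list(stream = stream, intervals = do.call(rbind, iv))
}

# deterministic child seed, kept below 2^31
child_seed <- function(master, i) {
  ((as.double(master) %% 100003) * 10007 + i * 7919) %% 2147483647
}

#' Generate a full multi-species cohort
#'
#' Draws one individual profile per animal (log-normal stride/amplitude
#' scales with sd `individual_sd`, Gaussian posture offsets with sd
#' `30 * individual_sd` degrees, sexes recycled from the species profile)
#' and simulates one labelled stream per individual. Per-individual child
#' seeds are derived deterministically from the master seed, so streams
#' are reproducible individually and as a cohort.
#'
#' @param config [simulation_config()].
#' @return object of class `caprid_cohort`: list with `streams` (named
#'   list of [sensor_stream()]), `intervals` (row-bound interval
#'   data.frame), `individuals` (metadata data.frame with the drawn
#'   profile scales) and `config`.
#' @export
generate_cohort <- function(config) {
  streams <- list(); intervals <- list(); meta <- list()
  idx <- 0L
  for (sp_name in names(config$n_individuals)) {
    sp <- config$species_profiles[[sp_name]]
    n_ind <- config$n_individuals[[sp_name]]
    sexes <- rep(sp$sexes, length.out = n_ind)
    for (i in seq_len(n_ind)) {
      idx <- idx + 1L
      seed_i <- child_seed(config$seed, idx)
      set.seed(seed_i)
      ind <- individual_profile(
        individual_id = sprintf("%s_%02d", sp_name, i),
        species = sp_name, sex = sexes[i],
        stride_scale = rlnorm(1, 0, sp$individual_sd),
        amp_scale = rlnorm(1, 0, sp$individual_sd),
        posture_offset_deg = rnorm(2, 0, 30 * sp$individual_sd))
      out <- generate_stream(sp, ind, config, seed = child_seed(seed_i, 1))
      streams[[ind$individual_id]] <- out$stream
      intervals[[ind$individual_id]] <- out$intervals
      meta[[ind$individual_id]] <- data.frame(
        individual_id = ind$individual_id, species = sp_name, sex = sexes[i],
        stride_scale = ind$stride_scale, amp_scale = ind$amp_scale,
        pitch_offset_deg = ind$posture_offset_deg[1],
        roll_offset_deg = ind$posture_offset_deg[2],
        stringsAsFactors = FALSE)
    }
  }
  cohort <- structure(list(streams = streams,
                           intervals = do.call(rbind, intervals),
                           individuals = do.call(rbind, meta),
                           config = config),
                      class = "caprid_cohort")
  attr(cohort, "repertoire") <- unique(unlist(lapply(
    config$species_profiles, function(s) names(s$behaviours))))
  rownames(cohort$intervals) <- NULL
  rownames(cohort$individuals) <- NULL
  cohort
}

#' @export
print.caprid_cohort <- function(x, ...) {
  cat(sprintf("<caprid_cohort> %d individuals (%s), %d intervals, %g Hz\n",
              length(x$streams),
              paste(sprintf("%s: %d", names(x$config$n_individuals),
                            x$config$n_individuals), collapse = ", "),
              nrow(x$intervals), x$config$sample_rate_hz))
  invisible(x)
}
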