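#' Behaviour signal profile
#'
#' Describes how one behaviour manifests on a collar-mounted device: the
#' mean posture (device pitch and roll), the gait oscillation (fundamental
#' stride frequency, per-axis dynamic amplitude, relative strength of the
#' first harmonic) and how erratically the animal changes heading. Static
#' behaviours have `stride_hz = 0` and near-zero amplitude, so their
#' acceleration signal is gravity plus sensor noise.
#'
#' @param name behaviour label.
#' @param pitch_deg,roll_deg mean device pitch/roll in degrees (pitch
#'   positive = nose up; e.g. head-down grazing is a negative pitch).
#' @param stride_hz fundamental oscillation frequency in Hz; 0 for static
#'   behaviours.
#' @param amp_g length-3 dynamic amplitude (g) on surge, sway, heave.
#' @param harmonic_ratio amplitude of the 2x frequency component relative
#'   to the fundamental.
#' @param heading_volatility sd of the per-sample heading random-walk step,
#'   degrees.
#' @param is_locomotion if `TRUE`, bouts of this behaviour are performed on
#'   a slope drawn from the species' slope repertoire and the slope angle
#'   adds to the device pitch.
#' @param slope_repertoire optional per-behaviour override of the slope
#'   categories available (e.g. climbing occurs only uphill/downhill).
#' @param weight relative probability of the behaviour when bouts are drawn.
#' @return object of class `behaviour_profile`.
#' @export
behaviour_profile <- function(name, pitch_deg = 0, roll_deg = 0,
                              stride_hz = 0, amp_g = c(0, 0, 0),
                              harmonic_ratio = 0, heading_volatility = 0.2,
                              is_locomotion = FALSE,
                              slope_repertoire = NULL, weight = 1) {
  stopifnot(stride_hz >= 0, all(amp_g >= 0), length(amp_g) == 3,
            harmonic_ratio >= 0, heading_volatility >= 0, weight > 0)
  structure(list(name = name, pitch_deg = pitch_deg, roll_deg = roll_deg,
                 stride_hz = stride_hz, amp_g = amp_g,
                 harmonic_ratio = harmonic_ratio,
                 heading_volatility = heading_volatility,
                 is_locomotion = is_locomotion,
                 slope_repertoire = slope_repertoire, weight = weight),
            class = "behaviour_profile")
}

#' Individual animal profile
#'
#' Per-animal deviations from the species-level behaviour profiles:
#' multiplicative scales on stride frequency and dynamic amplitude and an
#' additive posture offset (collar seating differs between animals).
#'
#' @param individual_id identifier.
#' @param species,sex labels.
#' @param stride_scale,amp_scale multiplicative deviations (> 0).
#' @param posture_offset_deg length-2 additive (pitch, roll) offset, degrees.
#' @return object of class `individual_profile`.
#' @export
individual_profile <- function(individual_id, species, sex = "female",
                               stride_scale = 1, amp_scale = 1,
                               posture_offset_deg = c(0, 0)) {
  stopifnot(stride_scale > 0, amp_scale > 0, length(posture_offset_deg) == 2)
  structure(list(individual_id = individual_id, species = species, sex = sex,
                 stride_scale = stride_scale, amp_scale = amp_scale,
                 posture_offset_deg = posture_offset_deg),
            class = "individual_profile")
}

#' Species profile
#'
#' A behaviour repertoire plus species-level morphology: a stride-frequency
#' multiplier encoding limb length (short-legged animals stride faster), the
#' dispersion of individual deviations, the slope categories available in
#' the species' environment, and the sex composition of the cohort.
#' Sexual dimorphism is modelled as a stride/amplitude factor applied to
#' males.
#'
#' @param species label.
#' @param behaviours list of [behaviour_profile()] objects (at least two).
#' @param stride_scale species-level stride frequency multiplier.
#' @param individual_sd sd of the individual log-scales (stride and
#'   amplitude); per-individual posture offsets are drawn with sd
#'   `30 * individual_sd` degrees, so one knob controls all individual
#'   variation.
#' @param slope_repertoire named numeric of slope-category weights, a subset
#'   of `c(flat=, uphill=, downhill=)`.
#' @param sexes character vector recycled over individuals (deployment sex
#'   composition).
#' @param male_stride_factor,male_amp_factor dimorphism multipliers applied
#'   to male individuals.
#' @param male_pitch_offset_deg systematic device-pitch shift for males
#'   (larger neck and horn mass seat the collar differently), degrees.
#' @return object of class `species_profile`.
#' @export
species_profile <- function(species, behaviours, stride_scale = 1,
                            individual_sd = 0.15,
                            slope_repertoire = c(flat = 0.78, uphill = 0.11,
                                                 downhill = 0.11),
                            sexes = "female",
                            male_stride_factor = 0.7,
                            male_amp_factor = 1.5,
                            male_pitch_offset_deg = 8) {
  stopifnot(length(behaviours) >= 2, individual_sd >= 0,
            all(names(slope_repertoire) %in% c("flat", "uphill", "downhill")))
  names(behaviours) <- vapply(behaviours, `[[`, "", "name")
  structure(list(species = species, behaviours = behaviours,
                 stride_scale = stride_scale, individual_sd = individual_sd,
                 slope_repertoire = slope_repertoire, sexes = sexes,
                 male_stride_factor = male_stride_factor,
                 male_amp_factor = male_amp_factor,
                 male_pitch_offset_deg = male_pitch_offset_deg),
            class = "species_profile")
}

#' Default Caprid behaviour repertoire
#'
#' A stipulated nine/ten-class Caprid repertoire: standing, resting,
#' eating (head-down), browsing (reared up; goat-like species only),
#' aggression, grooming, shaking, and the locomotion gaits walking,
#' trotting, running plus climbing (steep terrain; ibex-like species only).
#' Postures, stride frequencies and amplitudes are plausible for a
#' collar-mounted device on a mid-sized Caprid; bout weights follow the
#' duration shares of [caprid_ethogram()] so the simulated class imbalance
#' matches the observed regime.
#'
#' @param species `"ibex"` or `"goat"`: selects the species-specific
#'   behaviour (climbing vs browsing) and the matching ethogram weights.
#' @return named list of [behaviour_profile()] objects.
#' @export
caprid_behaviours <- function(species = c("ibex", "goat")) {
  species <- match.arg(species)
  eth <- caprid_ethogram(species)
  eth <- eth[is.na(eth$slope), ]
  w <- setNames(eth$total_s / sum(eth$total_s), eth$behaviour)
  b <- list(
    behaviour_profile("standing", pitch_deg = 0, roll_deg = 0,
                      heading_volatility = 0.2, weight = w[["standing"]]),
    behaviour_profile("resting", pitch_deg = -15, roll_deg = 8,
                      heading_volatility = 0.05, weight = w[["resting"]]),
    behaviour_profile("eating", pitch_deg = -32, stride_hz = 1.0,
                      amp_g = c(0.05, 0.03, 0.06), heading_volatility = 0.5,
                      weight = w[["eating"]]),
    behaviour_profile("aggression", pitch_deg = 5, stride_hz = 2.6,
                      amp_g = c(0.45, 0.25, 0.40), harmonic_ratio = 0.2,
                      heading_volatility = 2.5, weight = w[["aggression"]]),
    behaviour_profile("grooming", pitch_deg = -10, roll_deg = 18,
                      stride_hz = 1.6, amp_g = c(0.12, 0.18, 0.10),
                      heading_volatility = 0.4, weight = w[["grooming"]]),
    behaviour_profile("shaking", stride_hz = 6, amp_g = c(0.5, 0.9, 0.6),
                      harmonic_ratio = 0.1, heading_volatility = 1.5,
                      weight = w[["shaking"]]),
    behaviour_profile("walking", stride_hz = 1.2,
                      amp_g = c(0.25, 0.15, 0.35), harmonic_ratio = 0.3,
                      heading_volatility = 1.0, is_locomotion = TRUE,
                      weight = w[["walking"]]),
    behaviour_profile("trotting", stride_hz = 2.2,
                      amp_g = c(0.45, 0.25, 0.60), harmonic_ratio = 0.3,
                      heading_volatility = 1.0, is_locomotion = TRUE,
                      weight = w[["trotting"]]),
    behaviour_profile("running", stride_hz = 3.0,
                      amp_g = c(0.70, 0.40, 0.90), harmonic_ratio = 0.25,
                      heading_volatility = 1.2, is_locomotion = TRUE,
                      weight = w[["running"]])
  )
  if (species == "ibex") {
    b <- c(b, list(behaviour_profile("climbing", pitch_deg = 0,
      stride_hz = 1.0, amp_g = c(0.35, 0.30, 0.50), harmonic_ratio = 0.2,
      heading_volatility = 1.5, is_locomotion = TRUE,
      slope_repertoire = c(uphill = 0.5, downhill = 0.5),
      weight = w[["climbing"]])))
  } else {
    b <- c(b, list(behaviour_profile("browsing", pitch_deg = 28,
      stride_hz = 0.8, amp_g = c(0.06, 0.04, 0.08),
      heading_volatility = 0.4, weight = w[["browsing"]])))
  }
  names(b) <- vapply(b, `[[`, "", "name")
  b
}

#' Default two-species Caprid cohort profiles
#'
#' An ibex-like and a goat-like species sharing the core repertoire.
#' The goat-like species has short legs, hence a higher stride frequency:
#' the ibex/goat frequency ratio is `stride_ratio` (default 0.6). The
#' default sex composition mirrors typical zoo deployments: mixed-sex
#' ibex (2 males, 4 females per 6 animals) and all-female goats.
#'
#' @param individual_sd dispersion of individual deviations (see
#'   [species_profile()]).
#' @param stride_ratio ibex:goat stride-frequency ratio.
#' @return named list of two [species_profile()] objects.
#' @export
default_species_profiles <- function(individual_sd = 0.15,
                                     stride_ratio = 0.6) {
  list(
    ibex = species_profile("ibex", caprid_behaviours("ibex"),
      stride_scale = stride_ratio, individual_sd = individual_sd,
      sexes = c("male", "male", "female", "female", "female", "female")),
    goat = species_profile("goat", caprid_behaviours("goat"),
      stride_scale = 1.0, individual_sd = individual_sd,
      sexes = "female")
  )
}

#' Simulation configuration
#'
#' @param species_profiles named list of [species_profile()] objects.
#' @param n_individuals named integer vector, individuals per species
#'   (names matching `species_profiles`).
#' @param total_duration_s recorded duration per individual, seconds.
#' @param bout_median_s median bout duration (bouts are log-normal).
#' @param bout_sdlog log-sd of bout durations.
#' @param sample_rate_hz sampling frequency (default 40 Hz).
#' @param accel_noise_sd_g accelerometer noise sd, g.
#' @param mag_noise_sd magnetometer noise sd, field units.
#' @param local_field_vector geomagnetic field in the world frame
#'   (arbitrary units; needs a horizontal component for heading to be
#'   observable).
#' @param slope_deg_range absolute slope angle range (degrees) for
#'   uphill/downhill locomotion bouts; flat bouts draw from
#'   (-2.5, 2.5). The lower bound must exceed 2.5 so slope categories
#'   stay consistent with the signed angle.
#' @param slope_effort uphill/downhill gait-amplitude factors.
#' @param slope_pitch_effect add the slope angle to the device pitch
#'   during locomotion (the postural cue slope classification relies
#'   on); disable to simulate terrain whose gradient leaves posture
#'   unchanged.
#' @param seed master seed; per-individual child seeds are derived
#'   deterministically from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(species_profiles = default_species_profiles(),
                              n_individuals = c(ibex = 6, goat = 9),
                              total_duration_s = 1800,
                              bout_median_s = 18,
                              bout_sdlog = 0.6,
                              sample_rate_hz = 40,
                              accel_noise_sd_g = 0.02,
                              mag_noise_sd = 0.01,
                              local_field_vector = c(0.45, 0, -0.85),
                              slope_deg_range = c(5, 15),
                              slope_effort = c(uphill = 1.1, downhill = 0.9),
                              slope_pitch_effect = TRUE,
                              seed = 1L) {
  stopifnot(sample_rate_hz > 0, accel_noise_sd_g >= 0, mag_noise_sd >= 0,
            total_duration_s > 0, bout_median_s > 0,
            all(names(n_individuals) %in% names(species_profiles)),
            length(local_field_vector) == 3,
            slope_deg_range[1] > 2.5,
            slope_deg_range[2] >= slope_deg_range[1])
  structure(list(species_profiles = species_profiles,
                 n_individuals = n_individuals,
                 total_duration_s = total_duration_s,
                 bout_median_s = bout_median_s, bout_sdlog = bout_sdlog,
                 sample_rate_hz = sample_rate_hz,
                 accel_noise_sd_g = accel_noise_sd_g,
                 mag_noise_sd = mag_noise_sd,
                 local_field_vector = local_field_vector,
                 slope_deg_range = slope_deg_range,
                 slope_effort = slope_effort,
                 slope_pitch_effect = slope_pitch_effect,
                 seed = as.integer(seed)),
            class = "simulation_config")
}
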