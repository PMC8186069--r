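# Shared fixture builders. Everything is generated in code; nothing is
# stored on disk.

# a small two-species cohort configuration for fast end-to-end tests
tiny_config <- function(n_ibex = 2, n_goat = 2, duration_s = 120,
                        individual_sd = 0.15, seed = 11, ...) {
  simulation_config(
    species_profiles = default_species_profiles(individual_sd = individual_sd),
    n_individuals = c(ibex = n_ibex, goat = n_goat),
    total_duration_s = duration_s, seed = seed, ...)
}

# a species with a single-behaviour signal structure for closed-form checks;
# species_profile requires >= 2 behaviours, so a never-drawn filler is added
one_behaviour_species <- function(beh, species = "test") {
  filler <- behaviour_profile("filler", weight = 1e-9)
  species_profile(species, list(beh, filler), individual_sd = 0)
}

neutral_individual <- function(id = "t_01", species = "test",
                               sex = "female") {
  individual_profile(id, species, sex)
}

# feature-table-shaped data.frame with known class structure for
# classifier tests: `n_inform` informative + `n_noise` pure-noise columns
labelled_table <- function(n = 300, classes = c("a", "b", "c"),
                           n_inform = 5, n_noise = 5, effect = 0.45,
                           n_individuals = 4, seed = 1) {
  set.seed(seed)
  cls <- factor(sample(classes, n, TRUE))
  x <- data.frame(matrix(rnorm(n * n_noise), n, n_noise))
  names(x) <- paste0("noise_", seq_len(n_noise))
  for (j in seq_len(n_inform))
    x[[paste0("inf_", j)]] <- as.integer(cls) * effect + rnorm(n)
  out <- cbind(data.frame(
    window_start_s = seq_len(n) * 2 - 2,
    individual_id = sprintf("id_%02d", rep_len(seq_len(n_individuals), n)),
    species = "test", sex = "female",
    behaviour = as.character(cls), slope = NA_character_,
    stringsAsFactors = FALSE), x)
  attr(out, "window_s") <- 2
  attr(out, "sampling_frequency_hz") <- 10
  out
}

# restrict a cohort feature table to one species, keeping attributes
species_table <- function(ft, sp) {
  out <- ft[ft$species == sp, , drop = FALSE]
  attr(out, "window_s") <- attr(ft, "window_s")
  attr(out, "sampling_frequency_hz") <- attr(ft, "sampling_frequency_hz")
  out
}

# drop behaviour classes too rare to split (guards stochastic tiny cohorts)
drop_rare <- function(ft, min_rows = 5) {
  tab <- table(ft$behaviour)
  out <- ft[ft$behaviour %in% names(tab)[tab >= min_rows], , drop = FALSE]
  attr(out, "window_s") <- attr(ft, "window_s")
  attr(out, "sampling_frequency_hz") <- attr(ft, "sampling_frequency_hz")
  out
}
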