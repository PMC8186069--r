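# Plain-text interchange: sensor CSV, interval CSV, YAML configuration.

#' Write / read a sensor stream as CSV
#'
#' Columns `time_s`, `acc_x_g`, `acc_y_g`, `acc_z_g`, `mag_x`, `mag_y`,
#' `mag_z`, one file per individual, header row mandatory. Metadata
#' (individual, species, sex, sampling rate) travels in the companion
#' interval file and the read arguments.
#'
#' @param stream [sensor_stream()].
#' @param path output file.
#' @export
write_sensor_csv <- function(stream, path) {
  df <- data.frame(time_s = stream$time_s,
                   acc_x_g = stream$acc[, 1], acc_y_g = stream$acc[, 2],
                   acc_z_g = stream$acc[, 3],
                   mag_x = stream$mag[, 1], mag_y = stream$mag[, 2],
                   mag_z = stream$mag[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensor_csv
#' @param individual_id,species,sex metadata for the stream being read.
#' @param sample_rate_hz sampling frequency; inferred from the timestamps
#'   when `NULL`.
#' @export
read_sensor_csv <- function(path, individual_id, species, sex = "female",
                            sample_rate_hz = NULL) {
  df <- read.csv(path)
  need <- c("time_s", "acc_x_g", "acc_y_g", "acc_z_g",
            "mag_x", "mag_y", "mag_z")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("sensor CSV missing columns: ", paste(missing, collapse = ", "))
  if (is.null(sample_rate_hz))
    sample_rate_hz <- round(1 / median(diff(df$time_s)), 6)
  sensor_stream(individual_id, species, sex, sample_rate_hz, df$time_s,
                as.matrix(df[, c("acc_x_g", "acc_y_g", "acc_z_g")]),
                as.matrix(df[, c("mag_x", "mag_y", "mag_z")]))
}

#' Write / read behaviour-interval annotations as CSV
#'
#' Columns `individual_id`, `species`, `sex`, `start_s`, `end_s`,
#' `behaviour`, `slope` (`flat`, `uphill`, `downhill` or `NA`); intervals
#' are half-open `[start_s, end_s)`.
#'
#' @param intervals interval data.frame.
#' @param path file path.
#' @export
write_interval_csv <- function(intervals, path) {
  cols <- c("individual_id", "species", "sex", "start_s", "end_s",
            "behaviour", "slope")
  if (!"slope" %in% names(intervals)) intervals$slope <- NA_character_
  write.csv(intervals[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_interval_csv
#' @export
read_interval_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "species", "sex", "start_s", "end_s",
            "behaviour", "slope")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("interval CSV missing columns: ", paste(missing, collapse = ", "))
  df$slope <- as.character(df$slope)
  df
}

#' Write a simulated cohort to per-individual CSV files
#'
#' Writes one sensor CSV and one interval CSV per individual plus a JSON
#' cohort manifest (`manifest.json`) recording the seed, sampling rate and
#' every artefact written. Refuses to write into a non-empty directory
#' unless `force = TRUE`.
#'
#' @param cohort a [generate_cohort()] cohort.
#' @param dir output directory (created if needed).
#' @param force overwrite a non-empty directory.
#' @return invisibly, the manifest as a list.
#' @export
simulate_cohort_csv <- function(cohort, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("output directory not empty (use force = TRUE): ", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (id in names(cohort$streams)) {
    sf <- file.path(dir, paste0(id, "_sensor.csv"))
    ivf <- file.path(dir, paste0(id, "_intervals.csv"))
    write_sensor_csv(cohort$streams[[id]], sf)
    write_interval_csv(cohort$intervals[
      cohort$intervals$individual_id == id, , drop = FALSE], ivf)
    files[[id]] <- list(sensor = basename(sf), intervals = basename(ivf))
  }
  manifest <- list(seed = cohort$config$seed,
                   sample_rate_hz = cohort$config$sample_rate_hz,
                   n_individuals = as.list(cohort$config$n_individuals),
                   individuals = cohort$individuals,
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [simulate_cohort_csv()]
#'
#' @param dir directory holding the per-individual CSVs and
#'   `manifest.json`.
#' @return a cohort-shaped list with `streams`, `intervals`,
#'   `individuals` and `config` (sampling rate and seed only).
#' @export
read_cohort_csv <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  streams <- list(); intervals <- list()
  meta <- as.data.frame(mf$individuals)
  for (id in names(mf$files)) {
    row <- meta[meta$individual_id == id, ]
    iv <- read_interval_csv(file.path(dir, mf$files[[id]]$intervals))
    streams[[id]] <- read_sensor_csv(file.path(dir, mf$files[[id]]$sensor),
                                     individual_id = id,
                                     species = row$species, sex = row$sex,
                                     sample_rate_hz = mf$sample_rate_hz)
    intervals[[id]] <- iv
  }
  structure(list(streams = streams, intervals = do.call(rbind, intervals),
                 individuals = meta,
                 config = list(sample_rate_hz = mf$sample_rate_hz,
                               seed = mf$seed)),
            class = "caprid_cohort")
}

#' Write / read the feature registry as YAML
#'
#' @param registry a [feature_registry()] data.frame.
#' @param path YAML file path.
#' @export
write_registry_yaml <- function(registry, path) {
  yaml::write_yaml(lapply(seq_len(nrow(registry)), function(i)
    as.list(registry[i, ])), path)
  invisible(path)
}

#' @rdname write_registry_yaml
#' @export
read_registry_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(lst, function(e)
    data.frame(name = e$name, kind = e$kind, description = e$description,
               stringsAsFactors = FALSE)))
  if (anyDuplicated(out$name)) stop("duplicate registry names")
  out
}

#' Read a simulation configuration from YAML
#'
#' Recognised keys mirror the [simulation_config()] arguments (species
#' profiles are taken from [default_species_profiles()], optionally
#' re-dispersed via an `individual_sd` key). Unknown keys raise an error
#' naming the key.
#'
#' @param path YAML file path.
#' @return a [simulation_config()].
#' @export
read_simulation_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("individual_sd", "stride_ratio", "n_individuals",
             "total_duration_s", "bout_median_s", "bout_sdlog",
             "sample_rate_hz", "accel_noise_sd_g", "mag_noise_sd",
             "local_field_vector", "slope_deg_range", "slope_effort",
             "slope_pitch_effect", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  profiles <- default_species_profiles(
    individual_sd = cfg$individual_sd %||% 0.15,
    stride_ratio = cfg$stride_ratio %||% 0.6)
  args <- cfg[setdiff(names(cfg), c("individual_sd", "stride_ratio"))]
  if (!is.null(args$n_individuals))
    args$n_individuals <- unlist(args$n_individuals)
  if (!is.null(args$slope_effort))
    args$slope_effort <- unlist(args$slope_effort)
  do.call(simulation_config, c(list(species_profiles = profiles), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
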