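# Windowed accelerometry / magnetometry variables.

# centred running mean with shrinking edges; always exact (cumsum-based)
running_mean <- function(x, half) {
  n <- length(x)
  if (half < 1L) return(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Decompose acceleration into static and dynamic components
#'
#' The static component is a centred running mean per axis over
#' `window_s` seconds (posture, i.e. the gravity projection); the dynamic
#' component is the raw signal minus the static one (body movement).
#' Edges use a shrinking window, so `static + dynamic == raw` at every
#' sample, exactly. The running-mean half-width is floored at one sample,
#' so the decomposition remains defined at very low sampling rates.
#'
#' @param stream a [sensor_stream()], or an n x 3 acceleration matrix with
#'   `sample_rate_hz` supplied.
#' @param window_s smoothing window in seconds (default 2).
#' @param sample_rate_hz required when `stream` is a bare matrix.
#' @return list with n x 3 matrices `static` and `dynamic`.
#' @export
decompose_static_dynamic <- function(stream, window_s = 2,
                                     sample_rate_hz = NULL) {
  if (inherits(stream, "sensor_stream")) {
    acc <- stream$acc; fs <- stream$sample_rate_hz
  } else {
    acc <- as.matrix(stream); fs <- sample_rate_hz
    if (is.null(fs)) stop("sample_rate_hz required for matrix input")
  }
  stopifnot(window_s > 0, ncol(acc) == 3)
  if (nrow(acc) < 2) stop("stream shorter than one window")
  half <- max(1L, floor(round(window_s * fs) / 2))
  static <- apply(acc, 2, running_mean, half = half)
  list(static = static, dynamic = acc - static)
}

#' Vectorial dynamic body acceleration (VeDBA)
#'
#' Per-sample Euclidean norm of the three dynamic-acceleration axes.
#'
#' @param dynamic n x 3 dynamic acceleration matrix (g).
#' @return numeric vector of VeDBA values (g), one per sample.
#' @seealso [smooth_series()] for the smoothed variant (smVeDBA).
#' @export
vedba <- function(dynamic) {
  dynamic <- as.matrix(dynamic)
  stopifnot(ncol(dynamic) == 3)
  sqrt(rowSums(dynamic^2))
}

#' Running-mean smoothing of a per-sample series
#'
#' Used for smVeDBA and smoothed ODBA: a centred running mean over
#' `window_s` seconds with shrinking edges.
#'
#' @param x numeric series.
#' @param window_s window in seconds.
#' @param sample_rate_hz sampling frequency.
#' @return smoothed series, same length.
#' @export
smooth_series <- function(x, window_s, sample_rate_hz) {
  running_mean(x, max(1L, floor(round(window_s * sample_rate_hz) / 2)))
}

#' Posture angles from static acceleration
#'
#' Pitch is the arcsine of the normalised static surge (x) component and
#' roll the arcsine of the normalised static sway (y) component, both in
#' degrees within \[-90, 90\].
#'
#' @param static n x 3 static acceleration matrix.
#' @return list with numeric vectors `pitch_deg` and `roll_deg`.
#' @export
posture_angles <- function(static) {
  static <- as.matrix(static)
  stopifnot(ncol(static) == 3)
  nrm <- sqrt(rowSums(static^2))
  if (any(nrm <= 0)) stop("zero-norm static vector: orientation undefined")
  clamp <- function(v) pmin(1, pmax(-1, v))
  list(pitch_deg = asin(clamp(static[, 1] / nrm)) * 180 / pi,
       roll_deg = asin(clamp(static[, 2] / nrm)) * 180 / pi)
}

# dominant non-zero-frequency DFT amplitude per column of a windowed matrix
window_psd_amp <- function(mat) {
  n <- nrow(mat)
  if (n < 2) stop("oscillation amplitude needs at least 2 samples per window")
  centred <- sweep(mat, 2, colMeans(mat))
  a <- Mod(mvfft(centred))
  bins <- 2:(floor(n / 2) + 1L)
  2 * apply(a[bins, , drop = FALSE], 2, max) / n
}

#' Maximum oscillation amplitude per window
#'
#' Amplitude of the dominant non-zero-frequency periodogram component of
#' the mean-removed series within each non-overlapping window of
#' `window_s` seconds (the PSD1 family of variables: for a pure sinusoid
#' of amplitude A whose period divides the window, the value is A).
#' Trailing samples not filling a whole window are dropped.
#'
#' @param x numeric series (typically one dynamic-acceleration axis).
#' @param window_s window length, seconds.
#' @param sample_rate_hz sampling frequency.
#' @return one amplitude per complete window.
#' @export
oscillation_amplitude <- function(x, window_s, sample_rate_hz) {
  n_per <- round(window_s * sample_rate_hz)
  if (n_per < 2) stop("window shorter than 2 samples")
  m <- floor(length(x) / n_per)
  if (m < 1) stop("series shorter than one window")
  window_psd_amp(matrix(x[seq_len(m * n_per)], n_per, m))
}

#' Windowed magnetometry variables
#'
#' Five per-window summaries of the tri-axial magnetometer signal: the
#' windowed standard deviation of each axis, the windowed standard
#' deviation of the field-vector norm, and the mean angular change per
#' sample of the normalised field vector (a full-body-rotation proxy; for
#' a field rotating at constant rate omega about the vertical it equals
#' omega / sample rate).
#'
#' @param mag n x 3 magnetometer matrix.
#' @param window_s window length, seconds.
#' @param sample_rate_hz sampling frequency.
#' @return data.frame with one row per complete window: `mag_sd_x`,
#'   `mag_sd_y`, `mag_sd_z`, `mag_norm_sd`, `mag_angular_change`
#'   (degrees per sample).
#' @export
magnetometry_features <- function(mag, window_s, sample_rate_hz) {
  mag <- as.matrix(mag)
  stopifnot(ncol(mag) == 3)
  nrm <- sqrt(rowSums(mag^2))
  if (any(nrm <= 0)) stop("zero-norm magnetometer sample: degenerate field")
  ang <- mag_angular_change(mag)
  n_per <- round(window_s * sample_rate_hz)
  if (n_per < 2) stop("window shorter than 2 samples")
  m <- floor(nrow(mag) / n_per)
  if (m < 1) stop("series shorter than one window")
  win <- rep(seq_len(m), each = n_per)
  keep <- seq_len(m * n_per)
  wsd <- function(v) tapply(v[keep], win, sd)
  data.frame(mag_sd_x = as.numeric(wsd(mag[, 1])),
             mag_sd_y = as.numeric(wsd(mag[, 2])),
             mag_sd_z = as.numeric(wsd(mag[, 3])),
             mag_norm_sd = as.numeric(wsd(nrm)),
             mag_angular_change = as.numeric(tapply(ang[keep], win, mean)))
}

# per-sample angular change (degrees) of the normalised field vector;
# first sample copies the second so the series has full length
mag_angular_change <- function(mag) {
  u <- mag / sqrt(rowSums(mag^2))
  n <- nrow(u)
  if (n < 2) return(rep(0, n))
  d <- rowSums(u[-1, , drop = FALSE] * u[-n, , drop = FALSE])
  ang <- acos(pmin(1, pmax(-1, d))) * 180 / pi
  c(ang[1], ang)
}

#' Decimate a sensor stream to a lower sampling frequency
#'
#' Keeps every `sample_rate_hz / target_hz`-th sample starting at the
#' first. The target must divide the current rate. Decimation happens
#' before static/dynamic decomposition in the pipeline.
#'
#' @param stream [sensor_stream()].
#' @param target_hz target sampling frequency.
#' @return decimated [sensor_stream()].
#' @export
subsample_stream <- function(stream, target_hz) {
  stopifnot(inherits(stream, "sensor_stream"), target_hz > 0)
  step <- stream$sample_rate_hz / target_hz
  if (abs(step - round(step)) > 1e-9)
    stop("target_hz must divide sample_rate_hz")
  step <- as.integer(round(step))
  if (step == 1L) return(stream)
  idx <- seq(1L, length(stream$time_s), by = step)
  sensor_stream(stream$individual_id, stream$species, stream$sex,
                target_hz, stream$time_s[idx],
                stream$acc[idx, , drop = FALSE],
                stream$mag[idx, , drop = FALSE])
}

#' The windowed feature registry
#'
#' The candidate variable set derived per non-overlapping window from the
#' raw tri-axial acceleration and magnetometry: per-axis static mean and
#' sd, per-axis dynamic mean/sd/min/max/range, posture angles (pitch,
#' roll: mean and sd), VeDBA (mean, sd, max), smoothed VeDBA, ODBA and
#' smoothed ODBA, the per-axis dominant oscillation amplitudes
#' (PSD1X/Y/Z), and five magnetometry variables. With magnetometry the
#' registry holds 39 named variables; without it, 34.
#'
#' @param magnetometry include the five magnetometry variables.
#' @return data.frame with columns `name`, `kind`, `description`.
#' @export
feature_registry <- function(magnetometry = TRUE) {
  ax <- c("x", "y", "z")
  axl <- c("surge (x)", "sway (y)", "heave (z)")
  reg <- rbind(
    data.frame(name = paste0("static_mean_", ax), kind = "static",
               description = paste("windowed mean static acceleration,", axl)),
    data.frame(name = paste0("static_sd_", ax), kind = "static",
               description = paste("windowed sd of static acceleration,", axl)),
    data.frame(name = paste0("dyn_mean_", ax), kind = "dynamic",
               description = paste("windowed mean dynamic acceleration,", axl)),
    data.frame(name = paste0("dyn_sd_", ax), kind = "dynamic",
               description = paste("windowed sd of dynamic acceleration,", axl)),
    data.frame(name = paste0("dyn_min_", ax), kind = "dynamic",
               description = paste("windowed min dynamic acceleration,", axl)),
    data.frame(name = paste0("dyn_max_", ax), kind = "dynamic",
               description = paste("windowed max dynamic acceleration,", axl)),
    data.frame(name = paste0("dyn_range_", ax), kind = "dynamic",
               description = paste("windowed dynamic range,", axl)),
    data.frame(name = c("pitch_mean", "pitch_sd", "roll_mean", "roll_sd"),
               kind = "posture",
               description = c("windowed mean pitch (deg)",
                               "windowed sd of pitch (deg)",
                               "windowed mean roll (deg)",
                               "windowed sd of roll (deg)")),
    data.frame(name = c("vedba_mean", "vedba_sd", "vedba_max",
                        "smvedba_mean", "odba_mean", "smodba_mean"),
               kind = "energy",
               description = c("windowed mean VeDBA (g)",
                               "windowed sd of VeDBA (g)",
                               "windowed max VeDBA (g)",
                               "windowed mean smoothed VeDBA (g)",
                               "windowed mean ODBA (g)",
                               "windowed mean smoothed ODBA (g)")),
    data.frame(name = paste0("psd1_", ax), kind = "dynamic",
               description = paste("dominant oscillation amplitude,", axl))
  )
  if (magnetometry) {
    reg <- rbind(reg, data.frame(
      name = c("mag_sd_x", "mag_sd_y", "mag_sd_z", "mag_norm_sd",
               "mag_angular_change"),
      kind = "magnetometry",
      description = c(paste("windowed sd of magnetometer", axl),
                      "windowed sd of field-vector norm",
                      "mean angular change of field vector (deg/sample)")))
  }
  rownames(reg) <- NULL
  reg
}

#' Compute the labelled windowed feature table for one stream
#'
#' Cuts the stream into consecutive non-overlapping windows of `window_s`
#' seconds, labels each window by the behaviour interval containing its
#' midpoint, drops windows that straddle an interval boundary (mixed
#' behaviour) or fall outside any labelled interval, and evaluates every
#' registry variable per retained window.
#'
#' @param stream [sensor_stream()].
#' @param intervals data.frame of labelled intervals for this individual
#'   (`start_s`, `end_s`, `behaviour`, optional `slope`), half-open,
#'   non-overlapping.
#' @param registry from [feature_registry()]; its `name` column defines
#'   the feature columns (and their order).
#' @param window_s feature window, seconds (default 2).
#' @param static_window_s smoothing window for the static component.
#' @return data.frame with columns `window_start_s`, `individual_id`,
#'   `species`, `sex`, `behaviour`, `slope`, then one column per registry
#'   variable. Attributes `sampling_frequency_hz` and `window_s` record
#'   the provenance.
#' @export
compute_feature_table <- function(stream, intervals,
                                  registry = feature_registry(),
                                  window_s = 2, static_window_s = 2) {
  stopifnot(inherits(stream, "sensor_stream"), nrow(registry) > 0)
  fs <- stream$sample_rate_hz
  n_per <- round(window_s * fs)
  if (n_per < 2) stop("window must span at least 2 samples")
  n <- length(stream$time_s)
  m <- floor(n / n_per)
  if (m < 1) stop("stream shorter than one window")
  keep <- seq_len(m * n_per)
  win <- rep(seq_len(m), each = n_per)

  need_mag <- any(registry$kind == "magnetometry")
  dec <- decompose_static_dynamic(stream, window_s = static_window_s)
  dyn <- dec$dynamic; static <- dec$static
  pa <- posture_angles(static)
  vb <- vedba(dyn)
  ob <- rowSums(abs(dyn))
  smv <- smooth_series(vb, window_s, fs)
  smo <- smooth_series(ob, window_s, fs)

  dt <- data.table(win = win,
                   sx = static[keep, 1], sy = static[keep, 2],
                   sz = static[keep, 3],
                   dx = dyn[keep, 1], dy = dyn[keep, 2], dz = dyn[keep, 3],
                   pitch = pa$pitch_deg[keep], roll = pa$roll_deg[keep],
                   vb = vb[keep], ob = ob[keep], smv = smv[keep],
                   smo = smo[keep])
  agg <- dt[, .(
    static_mean_x = mean(sx), static_mean_y = mean(sy),
    static_mean_z = mean(sz),
    static_sd_x = sd(sx), static_sd_y = sd(sy), static_sd_z = sd(sz),
    dyn_mean_x = mean(dx), dyn_mean_y = mean(dy), dyn_mean_z = mean(dz),
    dyn_sd_x = sd(dx), dyn_sd_y = sd(dy), dyn_sd_z = sd(dz),
    dyn_min_x = min(dx), dyn_min_y = min(dy), dyn_min_z = min(dz),
    dyn_max_x = max(dx), dyn_max_y = max(dy), dyn_max_z = max(dz),
    dyn_range_x = max(dx) - min(dx), dyn_range_y = max(dy) - min(dy),
    dyn_range_z = max(dz) - min(dz),
    pitch_mean = mean(pitch), pitch_sd = sd(pitch),
    roll_mean = mean(roll), roll_sd = sd(roll),
    vedba_mean = mean(vb), vedba_sd = sd(vb), vedba_max = max(vb),
    smvedba_mean = mean(smv), odba_mean = mean(ob), smodba_mean = mean(smo)
  ), by = win]
  setorder(agg, win)

  agg[, `:=`(psd1_x = window_psd_amp(matrix(dyn[keep, 1], n_per, m)),
             psd1_y = window_psd_amp(matrix(dyn[keep, 2], n_per, m)),
             psd1_z = window_psd_amp(matrix(dyn[keep, 3], n_per, m)))]
  if (need_mag) {
    mg <- magnetometry_features(stream$mag[keep, , drop = FALSE],
                                window_s, fs)
    agg <- cbind(agg, mg)
  }

  missing <- setdiff(registry$name, names(agg))
  if (length(missing))
    stop("registry variables not computable: ", paste(missing, collapse = ", "))

  t0 <- stream$time_s[1]
  win_start <- t0 + (seq_len(m) - 1L) * window_s
  win_end_sample <- win_start + (n_per - 1L) / fs
  mid <- win_start + window_s / 2

  iv <- intervals[order(intervals$start_s), , drop = FALSE]
  locate <- function(tt) {
    j <- findInterval(tt, iv$start_s)
    j[j >= 1 & tt >= iv$end_s[pmax(j, 1)]] <- 0L  # past the interval's end
    j
  }
  j_mid <- locate(mid); j_lo <- locate(win_start); j_hi <- locate(win_end_sample)
  ok <- j_mid > 0 & j_lo == j_mid & j_hi == j_mid
  if (!any(ok)) {
    warning("no window fits inside a single labelled interval")
  }
  dropped <- sum(j_mid > 0 & !ok)
  if (dropped) attr(ok, "dropped_straddling") <- dropped

  out <- data.frame(
    window_start_s = win_start[ok],
    individual_id = stream$individual_id, species = stream$species,
    sex = stream$sex,
    behaviour = iv$behaviour[j_mid[ok]],
    slope = if ("slope" %in% names(iv)) iv$slope[j_mid[ok]]
            else NA_character_,
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(agg[ok, registry$name, with = FALSE]))
  attr(out, "sampling_frequency_hz") <- fs
  attr(out, "window_s") <- window_s
  attr(out, "n_dropped_straddling") <- dropped
  out
}

#' Feature table for a whole cohort
#'
#' Applies [compute_feature_table()] to every stream of a cohort (after
#' optional decimation) and row-binds the results.
#'
#' @param cohort [generate_cohort()] output, or a list with `streams` and
#'   `intervals`.
#' @param target_hz optional decimation frequency applied before feature
#'   extraction.
#' @inheritParams compute_feature_table
#' @return feature table data.frame (see [compute_feature_table()]).
#' @export
cohort_features <- function(cohort, registry = feature_registry(),
                            window_s = 2, static_window_s = 2,
                            target_hz = NULL) {
  parts <- lapply(cohort$streams, function(s) {
    if (!is.null(target_hz)) s <- subsample_stream(s, target_hz)
    iv <- cohort$intervals[cohort$intervals$individual_id ==
                             s$individual_id, , drop = FALSE]
    compute_feature_table(s, iv, registry, window_s, static_window_s)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "sampling_frequency_hz") <-
    if (is.null(target_hz)) cohort$config$sample_rate_hz else target_hz
  attr(out, "window_s") <- window_s
  out
}

#' Classification labels from a feature table
#'
#' Plain behaviour labels, or behaviour with slope-subdivided locomotion
#' (`walking_uphill`, ...) when `include_slope = TRUE`.
#'
#' @param feature_table a feature table.
#' @param include_slope subdivide locomotion classes by slope category.
#' @return factor of labels, one per row.
#' @export
behaviour_labels <- function(feature_table, include_slope = FALSE) {
  lab <- feature_table$behaviour
  if (include_slope) {
    sl <- feature_table$slope
    lab <- ifelse(!is.na(sl), paste(lab, sl, sep = "_"), lab)
  }
  factor(lab)
}
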