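#' Cuff-occlusion protocol specification
#'
#' Describes the timing and cuff pressures of the reactive-hyperemia
#' acquisition protocol: a baseline recording phase with the wrist cuff
#' inflated to a low sensing pressure, an occlusion phase with the upper-arm
#' cuff at supra-systolic pressure, and a hyperemic phase after cuff release.
#' Defaults follow the standard 17-minute protocol (5 min baseline, 3 min
#' occlusion, 9 min hyperemia; wrist cuff 40 mmHg, occlusion cuff 200 mmHg).
#'
#' @param baseline_s Baseline phase duration in seconds.
#' @param occlusion_s Occlusion phase duration in seconds.
#' @param hyperemia_s Hyperemic phase duration in seconds.
#' @param wrist_pressure_mmHg Wrist (sensing) cuff pressure, mmHg.
#' @param occlusion_pressure_mmHg Upper-arm occlusion cuff pressure, mmHg.
#' @return An object of class `protocol_spec`.
#' @export
#' @examples
#' p <- protocol_spec()
#' protocol_duration(p)  # 1020 s
protocol_spec <- function(baseline_s = 300, occlusion_s = 180, hyperemia_s = 540,
                          wrist_pressure_mmHg = 40, occlusion_pressure_mmHg = 200) {
  stopifnot(is.numeric(baseline_s), is.numeric(occlusion_s), is.numeric(hyperemia_s))
  if (baseline_s <= 0 || occlusion_s <= 0 || hyperemia_s <= 0)
    stop("all protocol phase durations must be > 0")
  if (occlusion_pressure_mmHg <= wrist_pressure_mmHg)
    stop("occlusion pressure must exceed wrist cuff pressure")
  structure(list(baseline_s = baseline_s, occlusion_s = occlusion_s,
                 hyperemia_s = hyperemia_s,
                 wrist_pressure_mmHg = wrist_pressure_mmHg,
                 occlusion_pressure_mmHg = occlusion_pressure_mmHg),
            class = "protocol_spec")
}

#' @rdname protocol_spec
#' @param x A `protocol_spec`.
#' @export
protocol_duration <- function(x) {
  stopifnot(inherits(x, "protocol_spec"))
  x$baseline_s + x$occlusion_s + x$hyperemia_s
}

#' Read protocol overrides from a YAML or JSON config file
#'
#' The file may define any subset of the `protocol_spec()` fields; missing
#' fields keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` key-value file.
#' @return A `protocol_spec`.
#' @export
read_protocol_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- names(formals(protocol_spec))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) stop("unknown protocol config keys: ", paste(unknown, collapse = ", "))
  do.call(protocol_spec, cfg)
}

#' Construct a pulse recording
#'
#' A single-channel pressure-sensor time series (arbitrary device units)
#' sampled at a fixed rate under a [protocol_spec()]. Recordings within 1 s of
#' the nominal protocol length are accepted; longer recordings are truncated
#' to the nominal length, shorter ones (within tolerance) are kept as-is and
#' never extrapolated.
#'
#' @param samples Numeric vector of sensor values.
#' @param fs_hz Sampling rate in Hz (protocol standard: 500).
#' @param protocol A [protocol_spec()].
#' @param meta Optional named list of subject annotations (group label, age,
#'   HbA1c, ...).
#' @return An object of class `pulse_recording`.
#' @export
pulse_recording <- function(samples, fs_hz = 500, protocol = protocol_spec(),
                            meta = list()) {
  stopifnot(is.numeric(samples), length(fs_hz) == 1, inherits(protocol, "protocol_spec"))
  if (fs_hz <= 0) stop("fs_hz must be > 0")
  bad <- which(!is.finite(samples))
  if (length(bad))
    stop("non-finite sample value at position ", bad[1])
  nominal <- round(fs_hz * protocol_duration(protocol))
  tol <- round(fs_hz)  # +- 1 s
  if (length(samples) < nominal - tol)
    stop("recording too short: ", length(samples), " samples, protocol requires ",
         nominal, " (shortfall ", nominal - length(samples), ")")
  if (length(samples) > nominal) samples <- samples[seq_len(nominal)]
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz,
                 protocol = protocol, meta = meta),
            class = "pulse_recording")
}

#' @export
print.pulse_recording <- function(x, ...) {
  cat(sprintf("<pulse_recording> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs_hz, length(x$samples) / x$fs_hz))
  cat(sprintf("  protocol: %g/%g/%g s (baseline/occlusion/hyperemia)\n",
              x$protocol$baseline_s, x$protocol$occlusion_s, x$protocol$hyperemia_s))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a pulse recording from CSV
#'
#' Accepts a one-column CSV (`value`) or a two-column CSV (`time,value`), with
#' or without a header row. When a time column is present its median sampling
#' interval must agree with `fs_hz` to within 1%.
#'
#' @param path CSV file path.
#' @inheritParams pulse_recording
#' @return A `pulse_recording`.
#' @export
read_recording <- function(path, fs_hz = 500, protocol = protocol_spec(),
                           meta = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[-+0-9.eE,\\s]+$", first)
  df <- utils::read.csv(path, header = has_header,
                        colClasses = "character", strip.white = TRUE)
  if (ncol(df) > 2) stop("expected 1 or 2 columns, found ", ncol(df))
  vals <- suppressWarnings(as.numeric(df[[ncol(df)]]))
  bad <- which(!is.finite(vals))
  if (length(bad)) {
    row_no <- bad[1] + as.integer(has_header)
    stop("malformed or non-finite value at row ", row_no, " of ", path)
  }
  if (ncol(df) == 2) {
    tm <- suppressWarnings(as.numeric(df[[1]]))
    badt <- which(!is.finite(tm))
    if (length(badt))
      stop("malformed time value at row ", badt[1] + as.integer(has_header), " of ", path)
    dt <- stats::median(diff(tm))
    if (!isTRUE(abs(dt - 1 / fs_hz) <= 0.01 / fs_hz))
      stop("time column implies fs = ", signif(1 / dt, 6), " Hz, not ", fs_hz, " Hz")
  }
  pulse_recording(vals, fs_hz = fs_hz, protocol = protocol, meta = meta)
}

#' Write a pulse recording to CSV
#'
#' Emits a one-column `value` CSV readable by [read_recording()]; the
#' round-trip reproduces the samples exactly (values are printed at full
#' double precision).
#'
#' @param rec A `pulse_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pulse_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("value", con)
  writeLines(sprintf("%.17g", rec$samples), con)
  invisible(path)
}

#' Partition a recording into protocol phases
#'
#' Returns the sample-index ranges (1-based, inclusive) of the baseline,
#' occlusion and hyperemic phases. The ranges are contiguous, non-overlapping
#' and cover the recording exactly; a recording slightly shorter than nominal
#' has its hyperemic range shortened accordingly.
#'
#' @param rec A `pulse_recording`.
#' @return A list with elements `baseline`, `occlusion`, `hyperemia`, each an
#'   integer vector `c(first, last)`.
#' @export
#' @examples
#' rec <- pulse_recording(sin(seq_len(510000) / 40), 500)
#' segment_phases(rec)
segment_phases <- function(rec) {
  stopifnot(inherits(rec, "pulse_recording"))
  p <- rec$protocol
  fs <- rec$fs_hz
  n <- length(rec$samples)
  b_end <- round(p$baseline_s * fs)
  o_end <- round((p$baseline_s + p$occlusion_s) * fs)
  if (n <= o_end)
    stop("recording (", n, " samples) does not reach the hyperemic phase")
  list(baseline = c(1L, as.integer(b_end)),
       occlusion = c(as.integer(b_end + 1L), as.integer(o_end)),
       hyperemia = c(as.integer(o_end + 1L), as.integer(n)))
}

#' Per-beat footpoint/peak annotations
#'
#' @param footpoint_idx Integer sample indices of beat onsets (footpoints).
#' @param peak_idx Integer sample indices of systolic peaks; each peak must
#'   follow its footpoint, and both sequences must be strictly increasing.
#' @param amplitude Per-beat peak-to-footpoint amplitudes (device units, > 0).
#' @param fs_hz Sampling rate the indices refer to.
#' @return An object of class `beat_set`.
#' @export
beat_set <- function(footpoint_idx, peak_idx, amplitude, fs_hz) {
  footpoint_idx <- as.integer(footpoint_idx)
  peak_idx <- as.integer(peak_idx)
  n <- length(peak_idx)
  stopifnot(length(footpoint_idx) == n, length(amplitude) == n)
  if (n > 0) {
    if (any(footpoint_idx >= peak_idx))
      stop("each footpoint index must precede its paired peak index")
    if (any(diff(peak_idx) <= 0) || any(diff(footpoint_idx) <= 0))
      stop("beat indices must be strictly increasing")
    if (any(!is.finite(amplitude)) || any(amplitude <= 0))
      stop("all beat amplitudes must be finite and > 0")
  }
  structure(list(footpoint_idx = footpoint_idx, peak_idx = peak_idx,
                 amplitude = as.numeric(amplitude), fs_hz = fs_hz),
            class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d beats @ %g Hz", length(x$peak_idx), x$fs_hz))
  if (length(x$peak_idx) > 1) {
    rr <- diff(x$peak_idx) / x$fs_hz
    cat(sprintf(", median HR %.1f bpm", 60 / stats::median(rr)))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.beat_set <- function(x, ...) {
  data.frame(beat_index = seq_along(x$peak_idx),
             footpoint_idx = x$footpoint_idx,
             peak_idx = x$peak_idx,
             amplitude = x$amplitude,
             peak_time_s = (x$peak_idx - 1) / x$fs_hz)
}

#' Number of beats in a beat set
#' @param x A `beat_set`.
#' @export
n_beats <- function(x) length(x$peak_idx)

#' Concatenated beat-amplitude series
#'
#' The per-beat amplitude sequence X_i (baseline beats followed by hyperemic
#' beats, occlusion excluded) analysed by the entropy pipeline. `phase_split`
#' is the 1-based index of the first hyperemic beat.
#'
#' @param values Numeric beat amplitudes, finite and > 0.
#' @param phase_split Index of the first hyperemic beat (1..N).
#' @param beat_times_s Time of each beat (seconds from recording start).
#' @return An object of class `amplitude_series`.
#' @export
amplitude_series <- function(values, phase_split, beat_times_s) {
  stopifnot(is.numeric(values), length(beat_times_s) == length(values))
  n <- length(values)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("amplitude values must be finite and > 0")
  if (phase_split < 1 || phase_split > n)
    stop("phase_split must lie in 1..", n)
  if (n > 1 && any(diff(beat_times_s) <= 0))
    stop("beat times must be strictly increasing")
  structure(list(values = as.numeric(values),
                 phase_split = as.integer(phase_split),
                 beat_times_s = as.numeric(beat_times_s)),
            class = "amplitude_series")
}

#' @export
print.amplitude_series <- function(x, ...) {
  cat(sprintf("<amplitude_series> N = %d beats (%d baseline + %d hyperemic)\n",
              length(x$values), x$phase_split - 1L,
              length(x$values) - x$phase_split + 1L))
  invisible(x)
}

#' @export
as.data.frame.amplitude_series <- function(x, ...) {
  data.frame(beat = seq_along(x$values),
             time_s = x$beat_times_s,
             amplitude = x$values,
             phase = ifelse(seq_along(x$values) < x$phase_split,
                            "baseline", "hyperemia"))
}

#' Export an amplitude series to CSV
#' @param series An `amplitude_series`.
#' @param path Output path.
#' @export
write_amplitude_series <- function(series, path) {
  stopifnot(inherits(series, "amplitude_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Detrended amplitude series
#'
#' Holds the residual fluctuation series after trend removal; `values + trend`
#' reconstructs the source amplitudes to within 1e-9 relative tolerance.
#'
#' @param values Detrended values X'_i.
#' @param trend The removed trend component.
#' @param source The `amplitude_series` the trend was removed from.
#' @return An object of class `detrended_series`.
#' @export
detrended_series <- function(values, trend, source) {
  stopifnot(inherits(source, "amplitude_series"),
            length(values) == length(source$values),
            length(trend) == length(source$values))
  rel_err <- max(abs(values + trend - source$values)) /
    max(abs(source$values), .Machine$double.eps)
  if (rel_err > 1e-9)
    stop("values + trend does not reconstruct the source series (relative error ",
         signif(rel_err, 3), ")")
  structure(list(values = as.numeric(values), trend = as.numeric(trend),
                 source = source),
            class = "detrended_series")
}

#' @export
print.detrended_series <- function(x, ...) {
  cat(sprintf("<detrended_series> N = %d, SD = %.4g, mean = %.3g\n",
              length(x$values), stats::sd(x$values), mean(x$values)))
  invisible(x)
}

# ---- JSON result documents ---------------------------------------------------

result_payload <- function(x) {
  num_or_null <- function(v) {
    # non-finite S_E values are serialized as null; flags carry the reason
    lapply(as.list(v), function(e) if (is.finite(e)) e else NULL)
  }
  if (inherits(x, "mse_curve")) {
    list(type = "mse_curve", tau = x$tau, s_e = num_or_null(x$s_e),
         n_tau = x$n_tau, flags = x$flags, r_used = x$r_used,
         config = unclass(x$config))
  } else if (inherits(x, "mei_result")) {
    list(type = "mei_result",
         mei_ss = if (is.finite(x$mei_ss)) x$mei_ss else NULL,
         mei_ls = if (is.finite(x$mei_ls)) x$mei_ls else NULL,
         flags = x$flags, curve = result_payload(x$curve))
  } else if (inherits(x, "di_result")) {
    list(type = "di_result", amp_baseline = x$amp_baseline, amp_rh = x$amp_rh,
         di_percent = x$di_percent, windows = x$windows)
  } else if (inherits(x, "mei_analysis")) {
    list(type = "mei_analysis",
         di = result_payload(x$di), mei = result_payload(x$mei),
         n_beats = x$n_beats, phase_split = x$phase_split,
         r_used = x$r_used, provenance = x$provenance)
  } else stop("unsupported result type: ", paste(class(x), collapse = "/"))
}

#' Write an analysis result to JSON
#'
#' Serializes `di_result`, `mse_curve`, `mei_result` or `mei_analysis` objects
#' to a JSON document at full double precision, with provenance (configuration
#' and its hash, seed) where the object carries it. Non-finite entropy values
#' are written as `null` and marked in the per-scale flags, so the round-trip
#' through [read_result()] is lossless.
#'
#' @param x The result object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_result <- function(x, path) {
  payload <- result_payload(x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

restore_se <- function(lst) {
  vapply(lst, function(e) if (is.null(e)) NaN else as.numeric(e), numeric(1))
}

#' Read a JSON analysis result written by [write_result()]
#'
#' @param path JSON path.
#' @return The reconstructed result object.
#' @export
read_result <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  rebuild <- function(p) {
    switch(p$type,
      mse_curve = {
        cfg <- do.call(mse_config, p$config)
        structure(list(tau = unlist(p$tau), s_e = restore_se(p$s_e),
                       n_tau = unlist(p$n_tau), flags = unlist(p$flags),
                       r_used = p$r_used, config = cfg),
                  class = "mse_curve")
      },
      mei_result = {
        structure(list(mei_ss = if (is.null(p$mei_ss)) NaN else p$mei_ss,
                       mei_ls = if (is.null(p$mei_ls)) NaN else p$mei_ls,
                       flags = unlist(p$flags), curve = rebuild(p$curve)),
                  class = "mei_result")
      },
      di_result = {
        structure(list(amp_baseline = p$amp_baseline, amp_rh = p$amp_rh,
                       di_percent = p$di_percent,
                       windows = lapply(p$windows, unlist)),
                  class = "di_result")
      },
      mei_analysis = {
        structure(list(di = rebuild(p$di), mei = rebuild(p$mei),
                       n_beats = unlist(p$n_beats),
                       phase_split = p$phase_split,
                       r_used = p$r_used, provenance = p$provenance),
                  class = "mei_analysis")
      },
      stop("unknown result type in ", path))
  }
  rebuild(p)
}

# Stable hash of a configuration list (md5 of its canonical JSON form).
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
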