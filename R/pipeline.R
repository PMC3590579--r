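# End-to-end analysis: segment -> detect beats -> amplitude series ->
# EMD detrend -> MSE -> MEI, plus the dilatation index.

#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its default: heart-rate bounds
#' for beat detection, the optional strict beat count, the number of slow
#' IMFs folded into the removed trend, the MSE parameters, and the DI window
#' policy.
#'
#' @param min_hr_bpm,max_hr_bpm Beat-detection heart-rate bounds.
#' @param n_beats Optional strict total beat count (see
#'   [build_amplitude_series()]).
#' @param trend_imfs Trend definition for [emd_detrend()]: an integer count
#'   of slow IMFs, or `"auto"` (pipeline default) for period-based
#'   selection, which reliably removes the occlusion-release envelope.
#' @param m,r_value,r_mode,tau_max,r_fixed_across_scales See [mse_config()].
#' @param rh_policy DI hyperemic-window policy, `"max"` or `"fixed"`.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(min_hr_bpm = 40, max_hr_bpm = 150, n_beats = NULL,
                            trend_imfs = "auto", m = 2, r_value = 0.15,
                            r_mode = "fraction_of_sd", tau_max = 10,
                            r_fixed_across_scales = TRUE,
                            rh_policy = c("max", "fixed")) {
  rh_policy <- match.arg(rh_policy)
  structure(list(min_hr_bpm = min_hr_bpm, max_hr_bpm = max_hr_bpm,
                 n_beats = n_beats, trend_imfs = trend_imfs,
                 m = m, r_value = r_value, r_mode = r_mode, tau_max = tau_max,
                 r_fixed_across_scales = r_fixed_across_scales,
                 rh_policy = rh_policy),
            class = "analysis_config")
}

#' Run the full analysis on a pulse recording
#'
#' Segments the recording into protocol phases, detects beats in the
#' baseline and hyperemic phases, builds the concatenated amplitude series,
#' computes the dilatation index from the phase windows, detrends the series
#' by EMD, and computes the multiscale entropy curve and the MEI indices.
#'
#' @param rec A [pulse_recording()] or a CSV path readable by
#'   [read_recording()].
#' @param config An [analysis_config()].
#' @param verbose Print stage-by-stage progress.
#' @return An object of class `mei_analysis`: `di` (a `di_result`), `mei`
#'   (a `mei_result` with the `mse_curve`), `series`, `detrended`, beat
#'   counts, `phase_split`, `r_used`, and `provenance` (config and its
#'   hash).
#' @export
analyze_recording <- function(rec, config = analysis_config(), verbose = FALSE) {
  if (is.character(rec)) rec <- read_recording(rec)
  stopifnot(inherits(rec, "pulse_recording"), inherits(config, "analysis_config"))
  say <- function(...) if (verbose) message(...)
  phases <- segment_phases(rec)
  say("phases: baseline ", phases$baseline[2], " samples, hyperemia ",
      phases$hyperemia[2] - phases$hyperemia[1] + 1, " samples")
  bb <- detect_beats(rec, phases$baseline, config$min_hr_bpm, config$max_hr_bpm)
  hb <- detect_beats(rec, phases$hyperemia, config$min_hr_bpm, config$max_hr_bpm)
  say("beats: ", n_beats(bb), " baseline + ", n_beats(hb), " hyperemic")
  series <- build_amplitude_series(bb, hb, n_beats = config$n_beats)
  di <- compute_di(series, rec$protocol, policy = config$rh_policy)
  say(sprintf("DI = %.1f%%", di$di_percent))
  det <- emd_detrend(series, trend_imfs = config$trend_imfs)
  cfg <- mse_config(m = config$m, r_mode = config$r_mode,
                    r_value = config$r_value, tau_max = config$tau_max,
                    r_fixed_across_scales = config$r_fixed_across_scales)
  curve <- mse_curve(det, cfg)
  idx <- mei(curve)
  flagged <- curve$tau[curve$flags != "ok"]
  if (length(flagged)) say("flagged scales: ", paste(flagged, collapse = ", "))
  say(sprintf("MEI_SS = %.3f, MEI_LS = %.3f (r = %.4g)",
              idx$mei_ss, idx$mei_ls, curve$r_used[1]))
  structure(list(di = di, mei = idx, series = series, detrended = det,
                 n_beats = c(baseline = n_beats(bb), hyperemia = n_beats(hb)),
                 phase_split = series$phase_split,
                 r_used = curve$r_used[1],
                 provenance = list(config = unclass(config),
                                   config_hash = config_hash(unclass(config)))),
            class = "mei_analysis")
}

#' @export
print.mei_analysis <- function(x, ...) {
  cat("<mei_analysis>\n")
  cat(sprintf("  beats: %d baseline + %d hyperemic (split at %d)\n",
              x$n_beats["baseline"], x$n_beats["hyperemia"], x$phase_split))
  cat(sprintf("  DI = %.2f%%\n", x$di$di_percent))
  cat(sprintf("  MEI_SS = %.4f, MEI_LS = %.4f (r = %.4g)\n",
              x$mei$mei_ss, x$mei$mei_ls, x$r_used))
  if (any(x$mei$flags != "ok")) cat("  degenerate entropy scales present\n")
  invisible(x)
}

#' Analyze every subject of a simulated cohort
#'
#' Renders each subject's waveform on the fly (discarding it afterwards to
#' keep memory flat), runs [analyze_recording()], and collects per-subject
#' DI and MEI results together with the subject metadata into one data
#' frame suitable for [cohort_report()].
#'
#' @param cohort An `mei_cohort` from [simulate_cohort()], or `NULL` to
#'   simulate one from `group_sizes`/`master_seed`.
#' @param config An [analysis_config()].
#' @param group_sizes,master_seed Used when `cohort` is `NULL`.
#' @param verbose Print per-subject progress.
#' @param ... Passed to [simulate_cohort()] when simulating.
#' @return Data frame with one row per subject: `id`, `group`, `di_percent`,
#'   `mei_ss`, `mei_ls`, metadata columns, and `n_beats`.
#' @export
analyze_cohort <- function(cohort = NULL, config = analysis_config(),
                           group_sizes = c(30, 40, 40, 30), master_seed = 1,
                           verbose = FALSE, ...) {
  if (is.null(cohort))
    cohort <- simulate_cohort(group_sizes, master_seed, render = FALSE, ...)
  stopifnot(inherits(cohort, "mei_cohort"))
  rows <- lapply(cohort$subjects, function(subj) {
    rec <- if (!is.null(subj$recording)) subj$recording
           else render_waveform(subj$series, subj$params, seed = subj$seed,
                                protocol = cohort$protocol)$recording
    res <- analyze_recording(rec, config)
    if (verbose)
      message(subj$id, ": DI = ", round(res$di$di_percent, 1),
              "%, MEI_LS = ", round(res$mei$mei_ls, 3))
    meta <- subj$meta[setdiff(names(subj$meta), "group")]
    cbind(data.frame(id = subj$id, group = subj$group,
                     di_percent = res$di$di_percent,
                     mei_ss = res$mei$mei_ss, mei_ls = res$mei$mei_ls,
                     n_beats = sum(res$n_beats)),
          as.data.frame(meta))
  })
  do.call(rbind, rows)
}
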