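# Dilatation index: ratio of mean beat amplitude in a one-minute hyperemic
# window to that in a one-minute baseline window, expressed in percent.

#' Mean beat amplitude within a time window
#'
#' @param series An [amplitude_series()].
#' @param window Numeric `c(start_s, end_s)`, half-open `[start, end)`,
#'   seconds from recording start.
#' @return Arithmetic mean of the amplitudes whose beat time falls in the
#'   window. At least 5 beats must fall inside.
#' @export
window_mean_amplitude <- function(series, window) {
  stopifnot(inherits(series, "amplitude_series"), length(window) == 2)
  inw <- series$beat_times_s >= window[1] & series$beat_times_s < window[2]
  if (sum(inw) < 5)
    stop("window [", window[1], ", ", window[2], ") contains only ",
         sum(inw), " beats (need >= 5)")
  mean(series$values[inw])
}

#' Select the baseline and hyperemic one-minute windows
#'
#' Default (`policy = "max"`): the baseline window is the last 60 s of the
#' baseline phase, and the hyperemic window is the 60-s window (sliding in
#' 10-s steps over the first `rh_search_s` seconds of hyperemia) that
#' maximizes the mean beat amplitude — the hyperemic response peaks early
#' after cuff release, so the maximizing window captures it regardless of the
#' subject's decay rate. `policy = "fixed"` places the hyperemic window at
#' the start of the hyperemic phase. Explicit `baseline_window`/`rh_window`
#' override the policy.
#'
#' @param series An [amplitude_series()] with beat times in recording
#'   seconds.
#' @param protocol The [protocol_spec()] the recording followed.
#' @param policy `"max"` (default) or `"fixed"`.
#' @param window_s Window length in seconds (default 60).
#' @param step_s Sliding step for the `"max"` policy (default 10).
#' @param rh_search_s Search span after hyperemia onset (default 180).
#' @param baseline_window,rh_window Optional explicit windows
#'   `c(start_s, end_s)`.
#' @return List with `baseline` and `rh` windows, each `c(start_s, end_s)`.
#' @export
select_windows <- function(series, protocol = protocol_spec(),
                           policy = c("max", "fixed"),
                           window_s = 60, step_s = 10, rh_search_s = 180,
                           baseline_window = NULL, rh_window = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(series, "amplitude_series"), inherits(protocol, "protocol_spec"))
  if (protocol$baseline_s < window_s || protocol$hyperemia_s < window_s)
    stop("phase shorter than the ", window_s, "-s window")
  if (is.null(baseline_window))
    baseline_window <- c(protocol$baseline_s - window_s, protocol$baseline_s)
  rh_onset <- protocol$baseline_s + protocol$occlusion_s
  if (is.null(rh_window)) {
    if (policy == "fixed") {
      rh_window <- c(rh_onset, rh_onset + window_s)
    } else {
      span <- min(rh_search_s, protocol$hyperemia_s)
      starts <- seq(rh_onset, rh_onset + span - window_s, by = step_s)
      means <- vapply(starts, function(s0) {
        inw <- series$beat_times_s >= s0 & series$beat_times_s < s0 + window_s
        if (sum(inw) < 5) -Inf else mean(series$values[inw])
      }, numeric(1))
      if (all(!is.finite(means)))
        stop("no hyperemic window contains >= 5 beats")
      s0 <- starts[which.max(means)]  # ties resolve to the earliest window
      rh_window <- c(s0, s0 + window_s)
    }
  }
  list(baseline = baseline_window, rh = rh_window)
}

#' Dilatation index
#'
#' DI = Amp_RH / Amp_Baseline x 100 (percent): the hyperemic gain of the mean
#' pulse amplitude relative to baseline, the standard cuff-occlusion index of
#' endothelium-mediated dilatation.
#'
#' @param amp_baseline Mean baseline amplitude (> 0, device units).
#' @param amp_rh Mean hyperemic amplitude (> 0, same units).
#' @param windows Optional list of the windows used (echoed for audit).
#' @return An object of class `di_result` with `amp_baseline`, `amp_rh`,
#'   `di_percent`, `windows`.
#' @export
#' @examples
#' dilatation_index(1.0, 1.5)$di_percent  # 150
dilatation_index <- function(amp_baseline, amp_rh, windows = NULL) {
  if (!is.finite(amp_baseline) || amp_baseline <= 0 ||
      !is.finite(amp_rh) || amp_rh <= 0)
    stop("amplitudes must be finite and > 0")
  structure(list(amp_baseline = amp_baseline, amp_rh = amp_rh,
                 di_percent = amp_rh / amp_baseline * 100,
                 windows = windows),
            class = "di_result")
}

#' @export
print.di_result <- function(x, ...) {
  cat(sprintf("<di_result> DI = %.2f%% (Amp_Baseline = %.4g, Amp_RH = %.4g)\n",
              x$di_percent, x$amp_baseline, x$amp_rh))
  if (!is.null(x$windows))
    cat(sprintf("  windows: baseline [%g, %g) s, RH [%g, %g) s\n",
                x$windows$baseline[1], x$windows$baseline[2],
                x$windows$rh[1], x$windows$rh[2]))
  invisible(x)
}

#' Compute the dilatation index of an amplitude series
#'
#' Convenience wrapper: selects the phase windows via [select_windows()],
#' averages the beat amplitudes in each, and forms the DI.
#'
#' @inheritParams select_windows
#' @param ... Passed to [select_windows()].
#' @return A `di_result`.
#' @export
compute_di <- function(series, protocol = protocol_spec(), ...) {
  w <- select_windows(series, protocol, ...)
  dilatation_index(window_mean_amplitude(series, w$baseline),
                   window_mean_amplitude(series, w$rh),
                   windows = w)
}
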