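# Beat detection on arterial pulse waveforms: zero-phase band-pass, local
# maxima with an adaptive prominence threshold and a refractory period, then
# footpoint marking between consecutive peaks on the raw signal.

#' Detect per-beat footpoints and systolic peaks
#'
#' The signal is band-pass filtered (0.5-10 Hz, 2nd-order Butterworth applied
#' forward-backward for zero phase), candidate peaks are taken as local maxima
#' whose local prominence exceeds 0.3 times the rolling median prominence, and
#' peaks closer than the refractory period 60/`max_hr_bpm` s keep only the
#' larger. Each accepted peak is snapped to the raw-signal maximum within
#' +-0.1 s, and its footpoint is the raw-signal minimum between the previous
#' peak and the current peak (for the first beat: within the preceding 0.5 s).
#' The beat amplitude is the raw peak value minus the raw footpoint value.
#'
#' @param rec A [pulse_recording()].
#' @param phase Optional sample-index range `c(first, last)` (1-based,
#'   inclusive), e.g. one element of [segment_phases()]; default is the whole
#'   recording.
#' @param min_hr_bpm,max_hr_bpm Plausible heart-rate bounds (defaults 40 and
#'   150 bpm); `max_hr_bpm` sets the refractory period.
#' @return A [beat_set()] with indices referring to the full recording.
#' @export
detect_beats <- function(rec, phase = NULL, min_hr_bpm = 40, max_hr_bpm = 150) {
  stopifnot(inherits(rec, "pulse_recording"))
  if (min_hr_bpm <= 0 || max_hr_bpm <= min_hr_bpm)
    stop("heart-rate bounds must satisfy 0 < min_hr_bpm < max_hr_bpm")
  fs <- rec$fs_hz
  if (is.null(phase)) phase <- c(1L, length(rec$samples))
  if (phase[2] - phase[1] + 1 < 3 * fs * 60 / min_hr_bpm)
    stop("phase too short: need at least 3 expected beat periods")
  if (stats::sd(rec$samples[phase[1]:phase[2]]) == 0)
    stop("no pulsatile activity (flat signal)")

  # filter the whole recording so that phase boundaries carry signal context
  # on both sides and filtfilt edge transients stay at the recording ends
  seg <- rec$samples
  n <- length(seg)
  bf <- signal::butter(2, c(0.5, 10) / (fs / 2), type = "pass")
  # reflect-pad so filtfilt start-up transients stay outside the recording
  pad <- min(n - 1L, as.integer(round(5 * fs)))
  padded <- c(rev(seg[seq_len(pad) + 1L]), seg, rev(seg[n - seq_len(pad)]))
  filt <- as.numeric(signal::filtfilt(bf, padded))[pad + seq_len(n)]

  # local maxima of the filtered signal above its midline, within the phase
  is_peak <- c(FALSE, diff(filt[-n]) > 0 & diff(filt[-1]) <= 0, FALSE) & filt > 0
  cand <- which(is_peak)
  cand <- cand[cand >= phase[1] & cand <= phase[2]]
  if (length(cand) < 3) stop("no pulsatile activity (fewer than 3 beats)")

  # prominence proxy: height above the minimum in the preceding half second
  half_s <- round(0.5 * fs)
  prom <- vapply(cand, function(i) {
    filt[i] - min(filt[max(1, i - half_s):i])
  }, numeric(1))
  kmed <- min(length(prom), 31L)
  if (kmed %% 2 == 0) kmed <- kmed - 1L
  roll_med <- if (kmed >= 3) stats::runmed(prom, kmed, endrule = "median")
              else rep(stats::median(prom), length(prom))
  keep <- prom >= 0.3 * roll_med
  cand <- cand[keep]
  if (length(cand) < 3) stop("no pulsatile activity (fewer than 3 beats)")

  # refractory period: among peaks closer than 60/max_hr s keep the larger
  refr <- round(60 / max_hr_bpm * fs)
  acc <- integer(0)
  for (i in cand) {
    if (length(acc) && i - acc[length(acc)] < refr) {
      if (filt[i] > filt[acc[length(acc)]]) acc[length(acc)] <- i
    } else acc <- c(acc, i)
  }

  # snap to the raw-signal maximum near each filtered peak
  snap <- round(0.1 * fs)
  peaks <- vapply(acc, function(i) {
    lo <- max(1L, i - snap); hi <- min(n, i + snap)
    as.integer(lo + which.max(seg[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))

  # footpoints: raw minimum between consecutive peaks (first: preceding 0.5 s)
  feet <- integer(length(peaks))
  amp <- numeric(length(peaks))
  for (b in seq_along(peaks)) {
    lo <- if (b == 1) max(1, peaks[1] - half_s) else peaks[b - 1]
    hi <- peaks[b] - 1L
    if (hi < lo) { feet[b] <- NA_integer_; next }
    feet[b] <- lo + which.min(seg[lo:hi]) - 1L
    amp[b] <- seg[peaks[b]] - seg[feet[b]]
  }
  ok <- !is.na(feet) & amp > 0 & feet < peaks
  peaks <- peaks[ok]; feet <- feet[ok]; amp <- amp[ok]
  # screen residual artefacts: a real beat's amplitude tracks its neighbours
  if (length(amp) >= 3) {
    kmed2 <- min(length(amp), 31L); if (kmed2 %% 2 == 0) kmed2 <- kmed2 - 1L
    amed <- if (kmed2 >= 3) stats::runmed(amp, kmed2, endrule = "median")
            else rep(stats::median(amp), length(amp))
    ok <- amp >= 0.3 * amed
    peaks <- peaks[ok]; feet <- feet[ok]; amp <- amp[ok]
  }
  # enforce strictly increasing footpoints (ties can arise at snapped peaks)
  if (length(peaks) > 1) {
    ok2 <- c(TRUE, diff(feet) > 0)
    peaks <- peaks[ok2]; feet <- feet[ok2]; amp <- amp[ok2]
  }
  if (length(peaks) < 3) stop("no pulsatile activity (fewer than 3 beats)")

  beat_set(feet, peaks, amp, fs_hz = fs)
}

#' Build the concatenated baseline + hyperemia amplitude series
#'
#' Concatenates baseline beat amplitudes followed by hyperemic beat
#' amplitudes (the occlusion phase carries no usable beats and is excluded by
#' construction). The phase split is the 1-based index of the first hyperemic
#' beat; beat times are carried through from the peak sample indices.
#'
#' @param baseline_beats,hyperemia_beats [beat_set()]s from the two analysed
#'   phases of the same recording.
#' @param n_beats Optional total length for strict protocol fidelity: the
#'   series is truncated to `n_beats` by dropping beats from the end of each
#'   phase proportionally. `NULL` (default) keeps every detected beat.
#' @return An [amplitude_series()].
#' @export
build_amplitude_series <- function(baseline_beats, hyperemia_beats,
                                   n_beats = NULL) {
  stopifnot(inherits(baseline_beats, "beat_set"),
            inherits(hyperemia_beats, "beat_set"))
  if (!n_beats(baseline_beats) || !n_beats(hyperemia_beats))
    stop("both beat sets must be non-empty")
  if (baseline_beats$fs_hz != hyperemia_beats$fs_hz)
    stop("beat sets have different sampling rates")
  fs <- baseline_beats$fs_hz
  nb <- n_beats(baseline_beats)
  nh <- n_beats(hyperemia_beats)
  if (!is.null(n_beats)) {
    tot <- nb + nh
    if (n_beats < 2 || n_beats > tot)
      stop("n_beats must lie in 2..", tot)
    nb_keep <- max(1L, round(n_beats * nb / tot))
    nh_keep <- n_beats - nb_keep
    nb <- min(nb, nb_keep); nh <- min(nh, nh_keep)
  }
  values <- c(baseline_beats$amplitude[seq_len(nb)],
              hyperemia_beats$amplitude[seq_len(nh)])
  times <- (c(baseline_beats$peak_idx[seq_len(nb)],
              hyperemia_beats$peak_idx[seq_len(nh)]) - 1) / fs
  amplitude_series(values, phase_split = nb + 1L, beat_times_s = times)
}
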