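# Empirical mode decomposition by Huang-style sifting with cubic-spline
# envelopes. Written for 1-D beat-amplitude series of ~1000 points; fully
# deterministic (no ensemble noise injection).

# Indices of local maxima and minima. Plateaus are collapsed to their
# midpoint by carrying the last nonzero slope sign forward.
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  d <- sign(diff(x))
  # carry previous sign across flat segments
  for (i in seq_along(d)) if (d[i] == 0 && i > 1) d[i] <- d[i - 1]
  chg <- which(d[-1] != d[-length(d)]) + 1L
  mx <- chg[d[chg - 1] > 0 & d[chg] < 0]
  mn <- chg[d[chg - 1] < 0 & d[chg] > 0]
  list(max = mx, min = mn)
}

n_extrema <- function(x) {
  e <- find_extrema(x)
  length(e$max) + length(e$min)
}

# Cubic-spline envelope through the given extrema, with mirror extension of
# up to 2 extrema beyond each end to tame boundary swings. A series endpoint
# lying outside the envelope (e.g. on a trended segment) is treated as an
# extremum before mirroring, so envelopes track drift at the boundaries
# instead of plateauing.
spline_envelope <- function(idx, val, n, end_left, end_right, upper = TRUE) {
  cmp <- if (upper) `>` else `<`
  if (cmp(end_left, val[1])) { idx <- c(1L, idx); val <- c(end_left, val) }
  k <- length(idx)
  if (cmp(end_right, val[k])) { idx <- c(idx, n); val <- c(val, end_right); k <- k + 1L }
  nm <- min(2L, k)
  # left: reflect the first nm extrema about sample 1; right: about sample n
  xs <- c(2 - idx[nm:1], idx, 2 * n - idx[k:(k - nm + 1L)])
  ys <- c(val[nm:1], val, val[k:(k - nm + 1L)])
  keep <- !duplicated(xs)
  stats::spline(xs[keep], ys[keep], xout = seq_len(n), method = "fmm")$y
}

# One sifting pass: subtract the mean of the upper and lower envelopes.
sift_once <- function(h) {
  e <- find_extrema(h)
  if (length(e$max) < 2 || length(e$min) < 2) return(NULL)
  n <- length(h)
  upper <- spline_envelope(e$max, h[e$max], n, h[1], h[n], upper = TRUE)
  lower <- spline_envelope(e$min, h[e$min], n, h[1], h[n], upper = FALSE)
  h - (upper + lower) / 2
}

#' Empirical mode decomposition
#'
#' Decomposes a series into intrinsic mode functions (IMFs, fastest first)
#' plus a non-oscillatory residue by iterative sifting: each candidate mode is
#' refined by subtracting the mean of its cubic-spline extrema envelopes
#' (mirror extension of 2 extrema at each end) until the Cauchy criterion
#' between successive sifts falls below `sift_sd_threshold`. Decomposition
#' stops when the residue has fewer than 4 extrema. The sum of all IMFs and
#' the residue reconstructs the input to floating-point accuracy, and the
#' procedure is deterministic for a fixed input and configuration.
#'
#' A monotonic input yields zero IMFs with residue equal to the input.
#'
#' @param x Numeric series (length >= 8, finite).
#' @param sift_sd_threshold Cauchy stopping threshold between successive
#'   sifts (default 0.2).
#' @param max_sifts Maximum sifting iterations per IMF (default 100).
#' @param max_imfs Safety cap on the number of IMFs.
#' @return An object of class `imf_set`: `imfs` (matrix, one column per IMF),
#'   `residue`, `n_sifts`.
#' @export
emd <- function(x, sift_sd_threshold = 0.2, max_sifts = 100, max_imfs = 20) {
  stopifnot(is.numeric(x))
  if (!all(is.finite(x))) stop("input contains non-finite values")
  if (length(x) < 8) stop("series too short for EMD (need >= 8 points)")
  n <- length(x)
  residue <- as.numeric(x)
  imfs <- list()
  n_sifts <- integer(0)
  while (length(imfs) < max_imfs && n_extrema(residue) >= 4) {
    h <- residue
    k <- 0L
    repeat {
      h_new <- sift_once(h)
      if (is.null(h_new)) break
      k <- k + 1L
      denom <- sum(h^2)
      sd_c <- if (denom > 0) sum((h - h_new)^2) / denom else 0
      h <- h_new
      # Cauchy criterion only: enforcing the extrema/zero-crossing balance
      # exactly leads to over-sifting, which drains the amplitude modulation
      # that the multiscale analysis feeds on
      if (sd_c < sift_sd_threshold || k >= max_sifts) break
    }
    if (k == 0L) break  # could not sift further
    imfs[[length(imfs) + 1L]] <- h
    n_sifts <- c(n_sifts, k)
    residue <- residue - h
  }
  imf_mat <- if (length(imfs)) do.call(cbind, imfs) else
    matrix(numeric(0), nrow = n, ncol = 0)
  colnames(imf_mat) <- if (ncol(imf_mat)) paste0("imf", seq_len(ncol(imf_mat))) else NULL
  structure(list(imfs = imf_mat, residue = residue, n_sifts = n_sifts),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s) + residue (N = %d)\n",
              ncol(x$imfs), length(x$residue)))
  invisible(x)
}

#' Reconstruct the input of an EMD
#' @param x An `imf_set`.
#' @return Numeric vector: rowSums of the IMFs plus the residue.
#' @export
emd_reconstruct <- function(x) {
  stopifnot(inherits(x, "imf_set"))
  if (ncol(x$imfs)) rowSums(x$imfs) + x$residue else x$residue
}

#' Export an EMD to CSV (one column per IMF plus the residue)
#' @param x An `imf_set`.
#' @param path Output path.
#' @export
write_imf_set <- function(x, path) {
  stopifnot(inherits(x, "imf_set"))
  df <- as.data.frame(cbind(x$imfs, residue = x$residue))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Detrend an amplitude series by EMD
#'
#' Removes the nonstationary trend from a beat-amplitude series before
#' entropy analysis. The trend is the EMD residue plus, optionally, slow
#' IMFs: `trend_imfs` may be an integer k (fold the k slowest IMFs into the
#' trend; default 0, residue only) or `"auto"`, which folds in every IMF
#' whose mean oscillation period exceeds `min_trend_period` beats, stopping
#' at the first faster one. The automatic mode targets the occlusion-release
#' envelope, whose step and decay often leak from the residue into the
#' slowest IMFs; components slower than an order of magnitude beyond the
#' largest analysed entropy scale carry no information the multiscale
#' analysis can use. The detrended values plus the trend reconstruct the
#' input exactly.
#'
#' @param series An [amplitude_series()] (or plain numeric vector, which is
#'   wrapped with trivial metadata).
#' @param trend_imfs Number of slowest IMFs to fold into the trend
#'   (default 0: residue only), or `"auto"` for period-based selection.
#' @param min_trend_period Period threshold in beats for `"auto"`
#'   (default 100).
#' @param ... Passed to [emd()].
#' @return A [detrended_series()] with an `imf_set` attached as attribute
#'   `"decomposition"`.
#' @export
emd_detrend <- function(series, trend_imfs = 0, min_trend_period = 100, ...) {
  if (is.numeric(series) && !inherits(series, "amplitude_series")) {
    series <- amplitude_series(series, phase_split = 1L,
                               beat_times_s = seq_along(series))
  }
  stopifnot(inherits(series, "amplitude_series"))
  x <- series$values
  if (stats::sd(x) == 0) {
    # constant series: the whole signal is trend
    out <- detrended_series(rep(0, length(x)), x, series)
    attr(out, "decomposition") <- structure(
      list(imfs = matrix(numeric(0), nrow = length(x), ncol = 0),
           residue = x, n_sifts = integer(0)), class = "imf_set")
    return(out)
  }
  dec <- emd(x, ...)
  trend <- dec$residue
  if (identical(trend_imfs, "auto")) {
    for (j in rev(seq_len(ncol(dec$imfs)))) {
      imf <- dec$imfs[, j]
      z <- sum(diff(sign(imf)) != 0)
      if (2 * length(x) / max(z, 1) > min_trend_period)
        trend <- trend + imf
      else break
    }
  } else {
    k <- min(trend_imfs, ncol(dec$imfs))
    if (k > 0) {
      slow <- ncol(dec$imfs) - seq_len(k) + 1L
      trend <- trend + rowSums(dec$imfs[, slow, drop = FALSE])
    }
  }
  out <- detrended_series(x - trend, trend, series)
  attr(out, "decomposition") <- dec
  out
}
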