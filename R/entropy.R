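#' Multiscale entropy configuration
#'
#' Parameters of the multiscale sample-entropy computation. Defaults follow
#' the Costa convention: template length m = 2, tolerance r = 0.15 times the
#' standard deviation of the scale-1 series, held fixed across scales, over
#' scale factors 1..10.
#'
#' @param m Template length (>= 1).
#' @param r_mode `"fraction_of_sd"` (r_value is a multiple of the series SD)
#'   or `"absolute"` (r_value is in the units of the series).
#' @param r_value Tolerance value (> 0), interpreted per `r_mode`.
#' @param tau_max Largest scale factor (>= 1).
#' @param r_fixed_across_scales If `TRUE` (default) the tolerance is computed
#'   once from the scale-1 series SD; if `FALSE` it is recomputed from each
#'   coarse-grained series.
#' @return An object of class `mse_config`.
#' @export
mse_config <- function(m = 2, r_mode = c("fraction_of_sd", "absolute"),
                       r_value = 0.15, tau_max = 10,
                       r_fixed_across_scales = TRUE) {
  r_mode <- match.arg(r_mode)
  stopifnot(m >= 1, r_value > 0, tau_max >= 1)
  structure(list(m = as.integer(m), r_mode = r_mode, r_value = r_value,
                 tau_max = as.integer(tau_max),
                 r_fixed_across_scales = isTRUE(r_fixed_across_scales)),
            class = "mse_config")
}

#' Coarse-grain a series at scale factor tau
#'
#' Non-overlapping block averaging: y_j = mean(x[(j-1)*tau + 1 .. j*tau]) for
#' j = 1..floor(N/tau). Trailing remainder samples are discarded. At tau = 1
#' the coarse-grained series is the original series.
#'
#' @param x Numeric series.
#' @param tau Scale factor (integer >= 1, <= length(x)).
#' @return Numeric vector of length `floor(length(x)/tau)`.
#' @export
#' @examples
#' coarse_grain(1:6, 2)  # 1.5 3.5 5.5
coarse_grain <- function(x, tau) {
  stopifnot(is.numeric(x), length(tau) == 1, tau >= 1)
  tau <- as.integer(tau)
  if (tau > length(x)) stop("tau (", tau, ") exceeds series length (", length(x), ")")
  if (tau == 1L) return(as.numeric(x))
  k <- length(x) %/% tau
  colMeans(matrix(x[seq_len(k * tau)], nrow = tau))
}

#' Sample entropy of a series
#'
#' Richman-Moorman sample entropy: S_E = -ln(A/B), where B counts pairs of
#' m-length templates within Chebyshev tolerance r and A counts the same pairs
#' whose (m+1)-length extensions also match, both over template start points
#' i < j <= N - m; self-matches are excluded. When no m-template pairs match
#' (B = 0) the value is undefined and `NaN` is returned with attribute
#' `flag = "undefined"`; when B > 0 but A = 0 the value is `Inf` with
#' `flag = "infinite"`.
#'
#' @param x Numeric series (length > m + 1).
#' @param m Template length.
#' @param r Tolerance in the units of `x` (> 0).
#' @return The sample entropy, with attributes `A`, `B` (pair counts) and
#'   `flag` (`"ok"`, `"undefined"` or `"infinite"`).
#' @export
sample_entropy <- function(x, m = 2, r) {
  stopifnot(is.numeric(x), length(m) == 1, length(r) == 1)
  if (!all(is.finite(x))) stop("series contains non-finite values")
  if (length(x) <= m + 1) stop("series length must exceed m + 1")
  if (!is.finite(r) || r <= 0) stop("degenerate tolerance: r must be > 0")
  cnt <- sampen_counts_cpp(as.numeric(x), as.integer(m), as.numeric(r))
  B <- cnt[1]; A <- cnt[2]
  if (B == 0) {
    se <- NaN; flag <- "undefined"
  } else if (A == 0) {
    se <- Inf; flag <- "infinite"
  } else {
    se <- -log(A / B); flag <- "ok"
  }
  structure(se, A = A, B = B, flag = flag)
}

#' Multiscale entropy curve
#'
#' Computes S_E(tau) = sample entropy of the coarse-grained series at each
#' scale factor tau = 1..tau_max. With the default configuration the
#' tolerance r is computed once from the SD of the scale-1 series and held
#' fixed across scales. Degenerate scales (no template matches) are flagged
#' in the curve rather than raising an error.
#'
#' @param x Numeric series or `detrended_series`.
#' @param config An [mse_config()].
#' @return An object of class `mse_curve` with fields `tau`, `s_e`, `n_tau`,
#'   `flags`, `r_used` and `config`.
#' @export
mse_curve <- function(x, config = mse_config()) {
  stopifnot(inherits(config, "mse_config"))
  if (inherits(x, "detrended_series")) x <- x$values
  stopifnot(is.numeric(x))
  m <- config$m
  if (length(x) < config$tau_max * (m + 2))
    stop("series too short (", length(x), ") for tau_max = ", config$tau_max)
  sd1 <- stats::sd(x)
  r_of <- function(y) {
    if (config$r_mode == "absolute") return(config$r_value)
    s <- if (config$r_fixed_across_scales) sd1 else stats::sd(y)
    if (!is.finite(s) || s <= 0)
      stop("degenerate tolerance: series SD is zero under fraction_of_sd mode")
    config$r_value * s
  }
  taus <- seq_len(config$tau_max)
  s_e <- numeric(length(taus))
  n_tau <- integer(length(taus))
  flags <- character(length(taus))
  r_used <- numeric(length(taus))
  for (tau in taus) {
    y <- coarse_grain(x, tau)
    n_tau[tau] <- length(y)
    r <- r_of(y)
    r_used[tau] <- r
    se <- sample_entropy(y, m = m, r = r)
    s_e[tau] <- as.numeric(se)
    flags[tau] <- attr(se, "flag")
  }
  structure(list(tau = taus, s_e = s_e, n_tau = n_tau, flags = flags,
                 r_used = r_used, config = config),
            class = "mse_curve")
}

#' @export
print.mse_curve <- function(x, ...) {
  cat(sprintf("<mse_curve> m = %d, r = %s, scales 1..%d\n",
              x$config$m,
              if (x$config$r_mode == "absolute") sprintf("%g", x$r_used[1])
              else sprintf("%g x SD", x$config$r_value),
              max(x$tau)))
  print(data.frame(tau = x$tau, s_e = round(x$s_e, 4), n = x$n_tau,
                   flag = x$flags), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.mse_curve <- function(x, ...) {
  data.frame(tau = x$tau, s_e = x$s_e, n = x$n_tau, flag = x$flags)
}

#' Small-scale and large-scale multiscale entropy indices
#'
#' MEI_SS is the sum of S_E(tau) over scales 1..5 and MEI_LS the sum over
#' scales 6..10. If any scale in a band is degenerate (undefined or infinite
#' sample entropy) the corresponding index is `NaN` and flagged; it is never
#' silently zeroed.
#'
#' @param curve An [mse_curve()] computed with `tau_max >= 10`.
#' @return An object of class `mei_result` with fields `mei_ss`, `mei_ls`,
#'   `flags` and the input `curve`.
#' @export
mei <- function(curve) {
  stopifnot(inherits(curve, "mse_curve"))
  if (max(curve$tau) < 10)
    stop("MEI requires scales 1..10; curve has tau_max = ", max(curve$tau))
  band <- function(idx) {
    v <- curve$s_e[idx]
    if (all(is.finite(v))) sum(v) else NaN
  }
  ss <- band(1:5)
  ls <- band(6:10)
  flags <- c(mei_ss = if (is.finite(ss)) "ok" else "degenerate",
             mei_ls = if (is.finite(ls)) "ok" else "degenerate")
  structure(list(mei_ss = ss, mei_ls = ls, flags = flags, curve = curve),
            class = "mei_result")
}

#' @export
print.mei_result <- function(x, ...) {
  cat(sprintf("<mei_result> MEI_SS = %.4f, MEI_LS = %.4f\n", x$mei_ss, x$mei_ls))
  if (any(x$flags != "ok"))
    cat("  flags:", paste(names(x$flags), x$flags, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
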