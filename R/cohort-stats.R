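# Group comparison and correlation reporting. Engines are stats::t.test and
# stats::cor.test; summary_t computes the two-sample t from printed summary
# statistics (mean, SD, n), which t.test cannot do.

#' Independent two-sample t-test
#'
#' Welch (unequal-variance) by default; set `welch = FALSE` for the pooled
#' (Student) test. Two-sided p-values.
#'
#' @param sample_a,sample_b Numeric samples (n >= 2 each, nonzero variance in
#'   at least one).
#' @param welch Use the Welch test (default `TRUE`).
#' @return List with `t`, `df`, `p`.
#' @export
independent_t <- function(sample_a, sample_b, welch = TRUE) {
  stopifnot(is.numeric(sample_a), is.numeric(sample_b))
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("each sample needs n >= 2")
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0)
    stop("degenerate samples: both variances are zero")
  tt <- stats::t.test(sample_a, sample_b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Two-sample t-test from summary statistics
#'
#' Computes the independent t statistic from printed group summaries
#' (mean, SD, n), with the Welch-Satterthwaite degrees of freedom when
#' `welch = TRUE` and pooled-variance df otherwise. Enables consistency
#' checks against published mean +- SD tables.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries (SDs >= 0,
#'   n >= 2).
#' @param welch Use the Welch test (default `TRUE`).
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
#' @examples
#' summary_t(4.22, 1.41, 30, 3.53, 0.99, 40)$p  # about 0.025
summary_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b, welch = TRUE) {
  stopifnot(sd_a >= 0, sd_b >= 0, n_a >= 2, n_b >= 2)
  if (sd_a == 0 && sd_b == 0) stop("degenerate summaries: both SDs are zero")
  va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
  if (welch) {
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  }
  t <- (mean_a - mean_b) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors (n >= 3, both nonconstant).
#' @return List with `r`, `p` (two-sided, t transform with n - 2 df) and `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = unname(ct$p.value), n = length(x))
}

fmt_mean_sd <- function(m, s) {
  if (is.na(s)) sprintf("%.2f", m) else sprintf("%.2f \u00b1 %.2f", m, s)
}

sig_mark <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "**" else if (p < 0.05) "*" else ""
}

#' Cohort comparison and correlation report
#'
#' Builds the two standard report tables from per-subject results:
#' a group-comparison table (mean +- SD of each variable per group, with
#' two-sided p-values for the adjacent-group comparisons 1-vs-2, 2-vs-3 and
#' 3-vs-4, marked `*` at p < 0.05 and `**` at p < 0.001), and a correlation
#' table of DI and MEI_LS against the numeric metadata columns. No
#' multiple-testing correction is applied; the report notes this.
#'
#' @param results Data frame with columns `group` (1..4), the outcome
#'   columns `di_percent`, `mei_ss`, `mei_ls`, and any further numeric
#'   metadata columns (age, HbA1c, ...).
#' @param welch Use Welch t-tests (default `TRUE`).
#' @return List of class `cohort_report`: `table1` (group comparison),
#'   `table2` (correlations), `note`.
#' @export
cohort_report <- function(results, welch = TRUE) {
  stopifnot(is.data.frame(results), "group" %in% names(results))
  groups_present <- sort(unique(results$group))
  missing_g <- setdiff(1:4, groups_present)
  if (length(missing_g))
    warning("missing group(s): ", paste(missing_g, collapse = ", "),
            "; omitted from the report")
  vars <- setdiff(names(results)[vapply(results, is.numeric, logical(1))],
                  "group")
  t1 <- data.frame(variable = vars, stringsAsFactors = FALSE)
  for (g in groups_present) {
    sub <- results[results$group == g, , drop = FALSE]
    t1[[paste0("group", g)]] <- vapply(vars, function(v) {
      m <- mean(sub[[v]], na.rm = TRUE)
      s <- if (nrow(sub) > 1) stats::sd(sub[[v]], na.rm = TRUE) else NA_real_
      fmt_mean_sd(m, s)
    }, character(1))
  }
  for (pair in list(c(1, 2), c(2, 3), c(3, 4))) {
    if (!all(pair %in% groups_present)) next
    a <- results[results$group == pair[1], , drop = FALSE]
    b <- results[results$group == pair[2], , drop = FALSE]
    lab <- paste0("p_g", pair[1], "_vs_g", pair[2])
    t1[[lab]] <- vapply(vars, function(v) {
      xa <- a[[v]][is.finite(a[[v]])]; xb <- b[[v]][is.finite(b[[v]])]
      if (length(xa) < 2 || length(xb) < 2) return(NA_real_)
      if (stats::var(xa) == 0 && stats::var(xb) == 0) return(NA_real_)
      independent_t(xa, xb, welch = welch)$p
    }, numeric(1))
    t1[[paste0("sig_g", pair[1], "_vs_g", pair[2])]] <-
      vapply(t1[[lab]], sig_mark, character(1))
  }
  corr_vars <- setdiff(vars, c("di_percent", "mei_ss", "mei_ls"))
  t2 <- NULL
  if (length(corr_vars)) {
    t2 <- do.call(rbind, lapply(corr_vars, function(v) {
      row <- data.frame(variable = v)
      for (outcome in c("di_percent", "mei_ls")) {
        ok <- is.finite(results[[v]]) & is.finite(results[[outcome]])
        pr <- if (sum(ok) >= 3 && stats::sd(results[[v]][ok]) > 0 &&
                  stats::sd(results[[outcome]][ok]) > 0)
          pearson(results[[v]][ok], results[[outcome]][ok])
        else list(r = NA_real_, p = NA_real_)
        row[[paste0(outcome, "_r")]] <- pr$r
        row[[paste0(outcome, "_p")]] <- pr$p
      }
      row
    }))
  }
  structure(list(table1 = t1, table2 = t2,
                 note = "Two-sided p-values; no multiple-testing correction applied."),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Group comparison (mean \u00b1 SD; * p<0.05, ** p<0.001):\n")
  print(x$table1, row.names = FALSE, digits = 3)
  if (!is.null(x$table2)) {
    cat("\nCorrelations with DI and MEI_LS:\n")
    print(x$table2, row.names = FALSE, digits = 3)
  }
  cat("\n", x$note, "\n", sep = "")
  invisible(x)
}
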