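#' Contrast sustained against terminating epochs
#'
#' Compares two groups of per-epoch summaries on the rate constants, the
#' birth-death spectrum, and the mean count. Each metric is tested for
#' between-group difference with Student's t-test when both groups pass the
#' Shapiro-Wilk normality screen (alpha = 0.05), otherwise the Mann-Whitney
#' U test; the choice is recorded. Group means are reported with normal 95%
#' CIs. No multiple-testing correction is applied (single planned contrast
#' per metric); noted in the output.
#'
#' @param group_a,group_b lists of epoch summaries (e.g. from [run_epoch] or
#'   [summarize_epoch_events]) — each a list containing `lambda_f`,
#'   `lambda_d`, `slem`, `spectral_gap`, `mixing_rate`, `mean_count`.
#'   At least 2 epochs per group.
#' @param labels names of the two groups.
#' @return A data frame with one row per metric: group means, CIs, the test
#'   used, and the two-sided p-value.
#' @export
termination_contrast <- function(group_a, group_b,
                                 labels = c("group_a", "group_b")) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("need at least 2 epochs per group")
  metrics <- c("lambda_f", "lambda_d", "slem", "spectral_gap",
               "mixing_rate", "mean_count")
  pull <- function(group, m) vapply(group, function(e) as.numeric(e[[m]]), 1)
  rows <- lapply(metrics, function(m) {
    a <- pull(group_a, m); b <- pull(group_b, m)
    ci <- function(x) mean(x) + c(-1.96, 1.96) * stats::sd(x) / sqrt(length(x))
    normal <- function(x) {
      if (length(unique(x)) < 3L) return(FALSE)
      stats::shapiro.test(x)$p.value > 0.05
    }
    use_t <- normal(a) && normal(b)
    p <- if (stats::sd(c(a, b)) < 1e-14) 1
         else if (use_t) stats::t.test(a, b)$p.value
         else suppressWarnings(stats::wilcox.test(a, b)$p.value)
    ca <- ci(a); cb <- ci(b)
    data.frame(metric = m,
               mean_a = mean(a), ci_lo_a = ca[1], ci_hi_a = ca[2],
               mean_b = mean(b), ci_lo_b = cb[1], ci_hi_b = cb[2],
               test = if (use_t) "t" else "mann_whitney",
               p_value = p, significant = p < 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "labels") <- labels
  attr(out, "note") <- "alpha = 0.05 two-tailed; no multiple-testing correction"
  out
}

#' Summarize an event table into the per-epoch metrics used by the contrast
#'
#' Fits the formation and destruction rates, builds the running count at
#' `dt_ms`, and estimates the birth-death spectrum.
#'
#' @param events an [event_table].
#' @param kind entity kind to summarize.
#' @param dt_ms running-count frame interval in ms.
#' @return A list with `lambda_f`, `lambda_d`, `fit_f`, `fit_d`, `slem`,
#'   `spectral_gap`, `mixing_rate`, `mean_count`, `series`, `spectrum`.
#' @export
summarize_epoch_events <- function(events, kind = "PS", dt_ms = 1) {
  iv <- extract_intervals(events, kind)
  fit_f <- fit_exponential(iv$interformation, gof = FALSE)
  fit_d <- fit_exponential(iv$lifetime, gof = FALSE)
  series <- population_series(events, dt_ms, kind = kind)
  spec <- estimate_bd_matrix(series)
  list(lambda_f = fit_f$lambda_per_ms, lambda_d = fit_d$lambda_per_ms,
       fit_f = fit_f, fit_d = fit_d,
       slem = spec$slem, spectral_gap = spec$spectral_gap,
       mixing_rate = spec$mixing_rate,
       mean_count = mean(series$counts),
       series = series, spectrum = spec)
}
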