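#' Extract inter-formation times and lifetimes from an event table
#'
#' Inter-formation times are the successive differences of the sorted onset
#' times, pooled over all entities of the requested kind (the formation
#' process is population-level arrivals). Lifetimes are `offset - onset` for
#' entities whose offset is not right-censored; censored entities are
#' excluded from the lifetime sample and counted.
#'
#' @param events an [event_table].
#' @param kind `"PS"` or `"wavelet"`; only matching rows are used.
#' @return A list with `interformation` and `lifetime`, each an
#'   `interval_sample`: a list of `values` (ms), `kind`, `source`, and
#'   `n_censored_excluded`.
#' @export
extract_intervals <- function(events, kind = c("PS", "wavelet")) {
  kind <- match.arg(kind)
  ev <- events[events$kind == kind, , drop = FALSE]
  if (!nrow(ev)) stop("empty event table for kind ", kind)
  onsets <- sort(ev$onset_ms)
  interformation <- if (length(onsets) >= 2L) diff(onsets) else numeric()
  unc <- !ev$censored_right
  list(
    interformation = interval_sample(interformation, "interformation", kind, 0L),
    lifetime = interval_sample(ev$offset_ms[unc] - ev$onset_ms[unc],
                               "lifetime", kind, sum(!unc))
  )
}

interval_sample <- function(values, kind, source, n_censored_excluded = 0L) {
  structure(list(values = as.numeric(values), kind = kind, source = source,
                 n_censored_excluded = as.integer(n_censored_excluded)),
            class = "interval_sample")
}

#' Exponential renewal-rate fit by maximum likelihood
#'
#' The exponential MLE is the reciprocal sample mean. The 95% CI is exact,
#' from the gamma distribution of the summed intervals (for n exponential
#' intervals with total S, `lambda` has the distribution of
#' `Gamma(n, S)`), with a normal approximation used above `n = 500` (where
#' the two coincide to well under a percent); the `ci_method` field records
#' which was used. A chi-squared goodness-of-fit summary is attached when
#' the sample is large enough.
#'
#' @param sample an `interval_sample` (or bare numeric vector of durations
#'   in ms) with at least 2 positive-mean values.
#' @param gof also run [chi2_gof] when `n >= 20`.
#' @return An object of class `rate_fit`: `lambda_per_ms`, `ci95`, `n`,
#'   `ci_method`, and (when computed) `chi2_stat`, `chi2_p`.
#' @export
fit_exponential <- function(sample, gof = TRUE) {
  values <- if (inherits(sample, "interval_sample")) sample$values else sample
  n <- length(values)
  if (n < 2L) stop("need at least 2 intervals to fit a rate")
  m <- mean(values)
  if (m <= 0) stop("interval mean must be positive")
  lambda <- 1 / m
  S <- sum(values)
  if (n <= 500L) {
    ci <- stats::qgamma(c(0.025, 0.975), shape = n, rate = S)
    ci_method <- "exact_gamma"
  } else {
    se <- lambda / sqrt(n)
    ci <- lambda + c(-1.96, 1.96) * se
    ci_method <- "normal_approx"
  }
  fit <- structure(list(lambda_per_ms = lambda, ci95 = ci, n = n,
                        ci_method = ci_method,
                        chi2_stat = NA_real_, chi2_p = NA_real_,
                        kind = if (inherits(sample, "interval_sample"))
                          sample$kind else NA_character_),
                   class = "rate_fit")
  if (gof && n >= 20L) {
    g <- chi2_gof(values, fit)
    fit$chi2_stat <- g$stat
    fit$chi2_p <- g$p
  }
  fit
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("rate_fit: lambda = %.5g /ms (95%% CI %.5g-%.5g, %s), n = %d",
              x$lambda_per_ms, x$ci95[1], x$ci95[2], x$ci_method, x$n))
  if (!is.na(x$chi2_p))
    cat(sprintf("; exponential GOF chi2 = %.3g, p = %.3g", x$chi2_stat, x$chi2_p))
  cat("\n")
  invisible(x)
}

#' Chi-squared goodness of fit of intervals to a fitted exponential
#'
#' Bins are equal-probability under the fitted exponential, pooled from the
#' right until every expected count is at least 5 (deterministic given `n`).
#' Degrees of freedom are `bins - 2`, charging one for the estimated rate.
#'
#' @param sample an `interval_sample` or numeric vector (n >= 20).
#' @param fit a `rate_fit` (or a bare rate in /ms).
#' @param n_bins initial number of equal-probability bins; default
#'   `max(4, floor(n / 10))` capped at 20.
#' @return A list with `stat`, `p`, `df`, `bins`.
#' @export
chi2_gof <- function(sample, fit, n_bins = NULL) {
  values <- if (inherits(sample, "interval_sample")) sample$values else sample
  lambda <- if (inherits(fit, "rate_fit")) fit$lambda_per_ms else fit
  n <- length(values)
  if (n < 20L) stop("chi-squared GOF needs at least 20 intervals")
  if (is.null(n_bins)) n_bins <- min(20L, max(4L, floor(n / 10)))
  # equal-probability bin edges under Exp(lambda), pooled so expected >= 5
  while (n / n_bins < 5 && n_bins > 2L) n_bins <- n_bins - 1L
  if (n_bins < 3L) stop("too few usable bins for a GOF test")
  edges <- stats::qexp(seq(0, 1, length.out = n_bins + 1L), rate = lambda)
  edges[length(edges)] <- Inf
  obs <- as.vector(table(cut(values, edges, include.lowest = TRUE)))
  expected <- n / n_bins
  stat <- sum((obs - expected)^2 / expected)
  df <- n_bins - 2L
  list(stat = stat, p = stats::pchisq(stat, df, lower.tail = FALSE),
       df = df, bins = n_bins)
}

#' Stationarity diagnostics for the formation process
#'
#' Two checks of the quasi-stationarity assumption behind the renewal-rate
#' estimates: (a) the autocorrelation of the inter-formation sequence at
#' lags 1..`max_lag`, with the white-noise 95% band +/- 1.96 / sqrt(n); and
#' (b) formation-rate estimates from random sub-windows of the epoch
#' compared (in standard errors) with the full-epoch estimate.
#'
#' @param events an [event_table].
#' @param kind entity kind.
#' @param max_lag maximum autocorrelation lag.
#' @param n_windows number of random sub-windows.
#' @param window_frac each window's length as a fraction of the epoch.
#' @param seed RNG seed for the window placement.
#' @return A list: `acf` (lag, value, band), `degenerate` (constant-interval
#'   flag), `windows` (per-window lambda), `full_lambda`, `max_abs_z`
#'   (largest window deviation in SE units), `stationary` (no acf excursions
#'   beyond the band in more than 5% of lags and `max_abs_z` <= 3).
#' @export
stationarity_check <- function(events, kind = "PS", max_lag = 20L,
                               n_windows = 10L, window_frac = 0.1,
                               seed = NULL) {
  iv <- extract_intervals(events, kind)$interformation$values
  if (length(iv) < 50L) stop("need at least 50 inter-formation intervals")
  epoch <- attr(events, "epoch_ms")
  if (stats::sd(iv) < 1e-12) {
    return(list(degenerate = TRUE, acf = NULL, windows = NULL,
                full_lambda = 1 / mean(iv), stationary = NA))
  }
  ac <- stats::acf(iv, lag.max = max_lag, plot = FALSE)$acf[-1]
  band <- 1.96 / sqrt(length(iv))
  full <- fit_exponential(iv, gof = FALSE)
  onsets <- sort(events$onset_ms[events$kind == kind])
  win_len <- window_frac * epoch
  wins <- with_seed(seed, stats::runif(n_windows, 0, epoch - win_len))
  win_lambda <- vapply(wins, function(w0) {
    o <- onsets[onsets >= w0 & onsets < w0 + win_len]
    if (length(o) < 3L) return(NA_real_)
    1 / mean(diff(o))
  }, numeric(1))
  se <- function(l, k) l / sqrt(k)
  z <- (win_lambda - full$lambda_per_ms) /
    se(full$lambda_per_ms, pmax(1, win_len * full$lambda_per_ms))
  max_abs_z <- max(abs(z), na.rm = TRUE)
  list(degenerate = FALSE,
       acf = data.frame(lag = seq_along(ac), value = ac,
                        band = band),
       windows = data.frame(start_ms = wins, lambda = win_lambda, z = z),
       full_lambda = full$lambda_per_ms,
       max_abs_z = max_abs_z,
       stationary = mean(abs(ac) > band) <= 0.05 + 1e-9 && max_abs_z <= 3)
}
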