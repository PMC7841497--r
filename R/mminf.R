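#' Steady-state M/M/infinity mean count
#'
#' The average number of concurrent entities in an M/M/infinity birth-death
#' process is the offered load `N = lambda_f / lambda_d`.
#'
#' @param lambda_f formation rate (per ms).
#' @param lambda_d destruction rate (per ms, > 0).
#' @return The predicted mean count.
#' @export
#' @examples
#' predict_mean(0.27, 0.05)  # 5.4
#' predict_mean(0.37, 0.11)  # 3.36...
predict_mean <- function(lambda_f, lambda_d) {
  if (!is.numeric(lambda_d) || lambda_d <= 0) stop("lambda_d must be positive")
  if (!is.numeric(lambda_f) || lambda_f < 0) stop("lambda_f must be non-negative")
  lambda_f / lambda_d
}

#' Steady-state M/M/infinity count distribution
#'
#' The stationary count is Poisson with mean `rho = lambda_f / lambda_d`:
#' `P_n = rho^n e^(-rho) / n!`.
#'
#' @inheritParams predict_mean
#' @param n_max largest count evaluated (>= 1).
#' @return A list of class `mminf_prediction`: `rho`, `mean_n` (= `rho`),
#'   and `pmf` (`P_0 .. P_nmax`; the Poisson tail above `n_max` carries the
#'   remaining mass).
#' @export
predict_pmf <- function(lambda_f, lambda_d, n_max = 30L) {
  rho <- predict_mean(lambda_f, lambda_d)
  if (n_max < 1L) stop("n_max must be >= 1")
  structure(list(rho = rho, mean_n = rho,
                 pmf = stats::dpois(0:n_max, rho), n_max = n_max),
            class = "mminf_prediction")
}

#' Running count of concurrent entities
#'
#' Counts, for each frame, the entities alive at the frame start under the
#' half-open convention: entity `[onset, offset)` is counted at frame time
#' `t` iff `onset <= t < offset`, `t = (k - 1) * dt_ms`.
#'
#' @param events an [event_table].
#' @param dt_ms frame interval (> 0).
#' @param epoch_ms epoch length; defaults to the table's attribute.
#' @param kind optional filter on entity kind.
#' @return A list of class `population_series`: integer `counts`, `dt_ms`,
#'   `kind`.
#' @export
population_series <- function(events, dt_ms, epoch_ms = attr(events, "epoch_ms"),
                              kind = NULL) {
  if (dt_ms <= 0) stop("dt_ms must be positive")
  if (is.null(epoch_ms) || is.na(epoch_ms))
    epoch_ms <- if (nrow(events)) max(events$offset_ms) else dt_ms
  ev <- if (is.null(kind)) events else events[events$kind == kind, , drop = FALSE]
  n_frames <- max(1L, floor(epoch_ms / dt_ms + 1e-9))
  delta <- integer(n_frames + 1L)
  if (nrow(ev)) {
    # entity counted at frames k with (k-1)*dt in [onset, offset)
    first <- pmax(1L, ceiling(ev$onset_ms / dt_ms - 1e-9) + 1L)
    last <- pmin(n_frames, ceiling(ev$offset_ms / dt_ms - 1e-9))
    keep <- first <= last
    for (i in which(keep)) {
      delta[first[i]] <- delta[first[i]] + 1L
      delta[last[i] + 1L] <- delta[last[i] + 1L] - 1L
    }
  }
  counts <- cumsum(delta[seq_len(n_frames)])
  structure(list(counts = as.integer(counts), dt_ms = dt_ms,
                 kind = if (is.null(kind)) unique(events$kind) else kind),
            class = "population_series")
}

#' Compare observed counts with the M/M/infinity prediction
#'
#' Bins the empirical count histogram against the predicted Poisson pmf
#' (bins pooled from the top until every expected count is at least 5) and
#' reports the chi-squared statistic and p-value alongside the observed and
#' predicted means. Consecutive frame counts are serially correlated over
#' roughly `1 / lambda_d`; `every` thins the series to near-independent
#' samples before the test (1 = use all frames).
#'
#' @param pred an `mminf_prediction`.
#' @param series a `population_series` of at least 100 frames.
#' @param every thinning stride in frames.
#' @return A list: `chi2_stat`, `chi2_p`, `df`, `observed_mean`,
#'   `predicted_mean`, `n_used`.
#' @export
compare_to_observed <- function(pred, series, every = 1L) {
  counts <- series$counts[seq(1L, length(series$counts), by = every)]
  if (length(counts) < 100L) stop("need at least 100 frames for comparison")
  if (length(unique(counts)) < 2L) stop("degenerate (constant) count histogram")
  n <- length(counts)
  nmax <- max(counts, pred$n_max)
  p <- stats::dpois(0:nmax, pred$rho)
  obs <- tabulate(counts + 1L, nbins = nmax + 1L)
  # pool the upper tail so every expected count is >= 5
  exp_counts <- p * n
  k <- nmax + 1L
  while (k > 2L && (exp_counts[k] < 5 || sum(exp_counts[k:(nmax + 1L)]) < 5)) k <- k - 1L
  pool <- function(v) c(v[seq_len(k - 1L)], sum(v[k:(nmax + 1L)]))
  obs_p <- pool(obs); exp_p <- pool(exp_counts)
  # drop leading cells with tiny expectation (small-rho epochs)
  keep <- exp_p >= 5
  keep[k] <- TRUE
  obs_p <- c(sum(obs_p[!keep]), obs_p[keep])
  exp_p <- c(sum(exp_p[!keep]), exp_p[keep])
  if (exp_p[1] == 0) { obs_p <- obs_p[-1]; exp_p <- exp_p[-1] }
  exp_p <- exp_p * sum(obs_p) / sum(exp_p)
  stat <- sum((obs_p - exp_p)^2 / exp_p)
  df <- max(1L, length(obs_p) - 1L)
  list(chi2_stat = stat,
       chi2_p = stats::pchisq(stat, df, lower.tail = FALSE),
       df = df, observed_mean = mean(counts),
       predicted_mean = pred$mean_n, n_used = n)
}
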