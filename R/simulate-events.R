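#' Simulate an M/M/infinity event stream of phase singularities or wavelets
#'
#' Draws a homogeneous Poisson process of entity formations at rate
#' `lambda_f` on `[0, duration_ms)` and gives each entity an independent
#' exponential lifetime at rate `lambda_d` — the M/M/infinity abstraction in
#' which every entity present is immediately "in service" and eligible for
#' destruction. The stationary concurrent count is Poisson with mean
#' `rho = lambda_f / lambda_d`.
#'
#' Entities still alive at `duration_ms` are kept with their offset clipped
#' to the epoch end and `censored_right = TRUE`; whether to exclude censored
#' lifetimes is a downstream (rate-estimation) decision.
#'
#' @param lambda_f formation rate, events per ms (>= 0).
#' @param lambda_d destruction rate per entity, per ms (> 0).
#' @param duration_ms epoch length in ms (> 0).
#' @param kind `"PS"` or `"wavelet"`.
#' @param seed optional integer seed; when given, a private RNG stream is
#'   used so the call is reproducible and does not disturb the global RNG.
#'
#' @return An [event_table] with `x = y = NA` (the abstraction is spatially
#'   unresolved) and random chirality for PS.
#' @export
#' @examples
#' ev <- simulate_mminf_events(0.27, 0.05, 1e4, seed = 1)
#' mean_concurrent_count(ev)  # near 0.27 / 0.05 = 5.4
simulate_mminf_events <- function(lambda_f, lambda_d, duration_ms,
                                  kind = c("PS", "wavelet"), seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(lambda_f) || lambda_f < 0)
    stop("lambda_f must be a non-negative rate (per ms)")
  if (!is.numeric(lambda_d) || lambda_d <= 0)
    stop("lambda_d must be a positive rate (per ms)")
  if (!is.numeric(duration_ms) || duration_ms <= 0)
    stop("duration_ms must be positive")

  draw <- function() {
    n <- stats::rpois(1L, lambda_f * duration_ms)
    if (n == 0L)
      return(event_table(epoch_ms = duration_ms))
    onsets <- sort(stats::runif(n, 0, duration_ms))
    lifetimes <- stats::rexp(n, rate = lambda_d)
    offsets <- onsets + lifetimes
    censored <- offsets >= duration_ms
    offsets[censored] <- duration_ms
    chir <- if (kind == "PS") sample(c(-1, 1), n, replace = TRUE) else NA_real_
    event_table(seq_len(n), kind, onsets, offsets,
                x = NA_real_, y = NA_real_, chirality = chir,
                censored_left = FALSE, censored_right = censored,
                epoch_ms = duration_ms)
  }
  with_seed(seed, draw())
}

#' Time-averaged concurrent entity count of an event table
#'
#' The exact time average of the running count over the epoch:
#' total entity-alive time divided by the epoch length (intervals are
#' half-open, and censored offsets are already clipped to the epoch end).
#'
#' @param events an [event_table] with an `epoch_ms` attribute (or supply
#'   `epoch_ms`).
#' @param epoch_ms epoch length override in ms.
#' @return The mean concurrent count (a single number).
#' @export
mean_concurrent_count <- function(events, epoch_ms = attr(events, "epoch_ms")) {
  if (is.null(epoch_ms) || is.na(epoch_ms))
    stop("epoch_ms is required (attribute absent from the event table)")
  if (!nrow(events)) return(0)
  sum(pmin(events$offset_ms, epoch_ms) - pmax(events$onset_ms, 0)) / epoch_ms
}

# Run expr under a private RNG stream when seed is non-NULL.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
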