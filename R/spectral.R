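#' Empirical birth-death transition matrix and its spectrum
#'
#' Estimates the one-frame-lag transition matrix of the running count on
#' states `0..max(counts)` (the maximum number of tracked states), row
#' normalizes it, and summarizes its eigenvalue spectrum: the second largest
#' eigenvalue modulus (SLEM), the spectral gap `1 - SLEM`, and the mixing
#' rate (identified with the spectral gap — the speed at which the chain
#' approaches its quasi-stationary distribution). States never visited as a
#' transition origin get an absorbing self-loop, are flagged, and are
#' excluded from the quoted state count. Because the gap scales with the
#' sampling interval, `dt_ms` is carried in the result.
#'
#' @param series a `population_series` visiting at least 2 distinct states.
#' @return An object of class `bd_spectrum`: `states`, `matrix`
#'   (row-stochastic), `eigen_moduli` (sorted descending), `slem`,
#'   `spectral_gap`, `mixing_rate`, `dt_ms`, `unvisited_states`,
#'   `n_states_observed`.
#' @export
estimate_bd_matrix <- function(series) {
  counts <- series$counts
  if (length(unique(counts)) < 2L)
    stop("degenerate chain: the count series is constant")
  n_max <- max(counts)
  k <- n_max + 1L
  from <- counts[-length(counts)] + 1L
  to <- counts[-1L] + 1L
  C <- matrix(0, k, k)
  for (i in seq_along(from)) C[from[i], to[i]] <- C[from[i], to[i]] + 1
  rs <- rowSums(C)
  unvisited <- which(rs == 0)
  if (length(unvisited)) {
    warning(length(unvisited), " state(s) never visited; given absorbing self-loops")
    C[cbind(unvisited, unvisited)] <- 1
    rs[unvisited] <- 1
  }
  P <- C / rs
  ev <- sort(Mod(eigen(P, only.values = TRUE)$values), decreasing = TRUE)
  slem <- ev[2]
  structure(list(states = 0:n_max, matrix = P, eigen_moduli = ev,
                 slem = slem, spectral_gap = 1 - slem,
                 mixing_rate = 1 - slem, dt_ms = series$dt_ms,
                 unvisited_states = unvisited - 1L,
                 n_states_observed = k - length(unvisited)),
            class = "bd_spectrum")
}

#' @export
print.bd_spectrum <- function(x, ...) {
  cat(sprintf("bd_spectrum: %d states, SLEM = %.4f, spectral gap = %.4f (dt = %g ms)\n",
              x$n_states_observed, x$slem, x$spectral_gap, x$dt_ms))
  invisible(x)
}

#' Analytic M/M/infinity generator (truncated)
#'
#' The tridiagonal continuous-time generator on states `0..n_max`: up-rate
#' `lambda_f`, down-rate `n * lambda_d`, diagonal the negated row sum. Its
#' stationary vector approaches the truncated Poisson(rho), and its nonzero
#' eigenvalues approach `-k * lambda_d`, so the eigenvalue nearest zero is
#' `-lambda_d` — the analytic oracle behind the empirical spectral-gap
#' estimates (the one-step matrix `I + Q dt` then has SLEM
#' `1 - lambda_d dt`).
#'
#' @inheritParams predict_mean
#' @param n_max truncation state (>= 2).
#' @return The `(n_max + 1) x (n_max + 1)` generator matrix (rows sum to 0).
#' @export
analytic_generator <- function(lambda_f, lambda_d, n_max) {
  if (n_max < 2L) stop("n_max must be >= 2")
  if (lambda_d <= 0) stop("lambda_d must be positive")
  if (lambda_f < 0) stop("lambda_f must be non-negative")
  k <- n_max + 1L
  Q <- matrix(0, k, k)
  for (n in 0:n_max) {
    i <- n + 1L
    if (n < n_max) Q[i, i + 1L] <- lambda_f
    if (n > 0) Q[i, i - 1L] <- n * lambda_d
    Q[i, i] <- -sum(Q[i, -i])
  }
  Q
}

#' Discretize a generator into a one-step transition matrix
#'
#' `P = I + Q * dt`. Rows always sum to 1; entries are non-negative (a true
#' probability matrix) only while `dt < 1 / max(|diag(Q)|)` — beyond that a
#' warning is issued, though the eigenvalue shift `1 + mu * dt` still holds.
#'
#' @param Q generator matrix.
#' @param dt_ms time step in ms.
#' @return The one-step matrix.
#' @export
discretize_generator <- function(Q, dt_ms) {
  if (dt_ms * max(abs(diag(Q))) >= 1)
    warning("dt exceeds 1/max|diag(Q)|: I + Q dt has negative entries")
  diag(nrow(Q)) + Q * dt_ms
}

#' Stationary distribution of a generator
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` by a bordered linear system.
#'
#' @param Q generator matrix.
#' @return Probability vector over the states.
#' @export
generator_stationary <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(numeric(k), 1)
  pi <- qr.solve(A, b)
  pi / sum(pi)
}
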