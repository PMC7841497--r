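#' Simulate a two-variable excitable medium
#'
#' A desk-scale Aliev-Panfilov reaction-diffusion medium used as the
#' voltage-movie generator for exercising the phase-mapping chain: an S1
#' stimulus launches a planar wave, and an S1-S2 cross-shock delivered in
#' the vulnerable window breaks the S1 wave back and initiates spiral
#' re-entry (an opposite-chirality rotor pair on a closed domain).
#'
#' The model is
#' \deqn{du/dt = D \nabla^2 u + k u (u - a)(1 - u) - u v}
#' \deqn{dv/dt = \epsilon(u, v) (-v - k u (u - a - 1))}
#' with \eqn{\epsilon(u, v) = \epsilon_0 + \mu_1 v / (u + \mu_2)}, integrated
#' by explicit Euler with a five-point Laplacian and no-flux boundaries.
#' `u` is the dimensionless transmembrane voltage. One model time unit is
#' mapped to `ms_per_unit` ms when frames are stamped.
#'
#' @param shape `c(H, W)` grid, default 60 x 60.
#' @param protocol `"none"`, `"S1"` or `"S1S2"`.
#' @param n_units simulated duration in model time units.
#' @param dt integration step in time units; the stability (CFL) bound
#'   `dt <= h^2 / (4 D)` is enforced.
#' @param save_every store every k-th step as a frame.
#' @param params named list overriding `a`, `k`, `eps0`, `mu1`, `mu2`, `D`,
#'   `h` (grid spacing).
#' @param s2_time S2 delivery time in time units (the vulnerable window for
#'   the defaults — just behind the S1 wave-back; tuned empirically and
#'   fixed).
#' @param s2_rows row indices of the S2 strip; a horizontal strip whose two
#'   edges meet the S1 wave-back produces a figure-of-eight pair of
#'   counter-rotating spirals. Default: rows `H/2 .. 3H/4`.
#' @param ms_per_unit ms per model time unit for the output `dt_ms`.
#' @return A list with `voltage` (T x H x W array), `dt_ms`, and the echoed
#'   parameters.
#' @export
simulate_excitable_tissue <- function(shape = c(60, 60),
                                      protocol = c("S1S2", "S1", "none"),
                                      n_units = 150, dt = 0.05,
                                      save_every = 8L,
                                      params = list(), s2_time = 50,
                                      s2_rows = NULL,
                                      ms_per_unit = 10) {
  protocol <- match.arg(protocol)
  p <- utils::modifyList(list(a = 0.1, k = 8, eps0 = 0.002, mu1 = 0.2,
                              mu2 = 0.3, D = 1, h = 1), params)
  if (dt > p$h^2 / (4 * p$D))
    stop(sprintf("integration step violates the stability bound dt <= %g",
                 p$h^2 / (4 * p$D)))
  H <- shape[1]; W <- shape[2]
  u <- matrix(0, H, W); v <- matrix(0, H, W)
  if (protocol != "none") u[, 1:3] <- 1          # S1: left-edge planar wave
  n_steps <- ceiling(n_units / dt)
  frames <- seq(1L, n_steps, by = save_every)
  voltage <- array(0, c(length(frames), H, W))
  fi <- 1L
  s2_step <- round(s2_time / dt)
  lap <- function(m) {
    up <- m[c(1, seq_len(H - 1)), ]; down <- m[c(seq_len(H - 1) + 1, H), ]
    left <- m[, c(1, seq_len(W - 1))]; right <- m[, c(seq_len(W - 1) + 1, W)]
    (up + down + left + right - 4 * m) / p$h^2
  }
  for (s in seq_len(n_steps)) {
    du <- p$D * lap(u) + p$k * u * (u - p$a) * (1 - u) - u * v
    dv <- (p$eps0 + p$mu1 * v / (u + p$mu2)) * (-v - p$k * u * (u - p$a - 1))
    u <- u + dt * du
    v <- v + dt * dv
    if (protocol == "S1S2" && s == s2_step) {
      rows <- if (is.null(s2_rows)) (H %/% 2):(3 * H %/% 4) else s2_rows
      u[rows, ] <- pmax(u[rows, ], 1)    # cross-shock strip
    }
    if (fi <= length(frames) && s == frames[fi]) {
      voltage[fi, , ] <- u
      fi <- fi + 1L
    }
  }
  list(voltage = voltage, dt_ms = dt * save_every * ms_per_unit,
       params = p, protocol = protocol, s2_time = s2_time)
}
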