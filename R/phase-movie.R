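#' Phase movies
#'
#' A `phase_movie` is a T x H x W array of instantaneous phase in radians,
#' wrapped to (-pi, pi], with a frame interval `dt_ms`, a pixel spacing
#' `pixel_mm`, and a logical H x W `mask` of valid pixels. It is the
#' substrate on which phase singularities and wavefronts are detected.
#'
#' @param values numeric array, dim `c(T, H, W)`, radians.
#' @param dt_ms frame interval in ms (> 0).
#' @param pixel_mm pixel spacing in mm.
#' @param mask logical H x W matrix of valid pixels; default all valid.
#' @param metadata named list of provenance information.
#' @return An object of class `phase_movie`.
#' @export
phase_movie <- function(values, dt_ms, pixel_mm = 1, mask = NULL,
                        metadata = list()) {
  if (length(dim(values)) != 3L) stop("values must be a T x H x W array")
  if (!is.numeric(dt_ms) || dt_ms <= 0) stop("dt_ms must be positive")
  d <- dim(values)
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  if (!identical(dim(mask), d[2:3])) stop("mask shape must match frame shape")
  values <- wrap_phase(values)
  structure(list(values = values, dt_ms = dt_ms, pixel_mm = pixel_mm,
                 mask = mask, metadata = metadata),
            class = "phase_movie")
}

#' @export
print.phase_movie <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("phase_movie: %d frames of %d x %d, dt = %g ms, pixel = %g mm (%d masked px)\n",
              d[1], d[2], d[3], x$dt_ms, x$pixel_mm, sum(!x$mask)))
  invisible(x)
}

#' @export
dim.phase_movie <- function(x) dim(x$values)

#' Wrap angles to (-pi, pi]
#'
#' @param phi angles in radians.
#' @return Wrapped angles; pi maps to pi, -pi maps to pi.
#' @export
wrap_phase <- function(phi) {
  w <- phi - 2 * pi * ceiling((phi - pi) / (2 * pi))
  # ceiling keeps the interval half-open at -pi: wrap(-pi) = +pi
  w
}

#' Voltage movie to phase movie via the Hilbert transform
#'
#' De-means each pixel's time series and takes the angle of its analytic
#' signal, mirroring the optical-mapping / simulated-voltage branch of the
#' preprocessing chain (electrogram data instead go through
#' [egm_to_phase_movie]).
#'
#' @param voltage T x H x W numeric array of transmembrane voltage.
#' @param dt_ms frame interval in ms.
#' @param pixel_mm pixel spacing in mm.
#' @param mask optional valid-pixel mask; pixels with (near-)constant traces
#'   are masked automatically since their phase is undefined.
#' @return A [phase_movie].
#' @export
voltage_to_phase_movie <- function(voltage, dt_ms, pixel_mm = 1, mask = NULL) {
  d <- dim(voltage)
  if (length(d) != 3L) stop("voltage must be a T x H x W array")
  X <- matrix(voltage, nrow = d[1])            # pixels as columns
  X <- sweep(X, 2, colMeans(X))
  sds <- sqrt(colMeans(X^2))
  flat <- sds < 1e-12 | !is.finite(sds)
  A <- analytic_signal_matrix(X)
  ph <- atan2(Im(A), Re(A))
  ph[, flat] <- 0
  m <- if (is.null(mask)) matrix(TRUE, d[2], d[3]) else mask
  m[matrix(flat, d[2], d[3])] <- FALSE
  phase_movie(array(ph, d), dt_ms = dt_ms, pixel_mm = pixel_mm, mask = m)
}

# Analytic signal of each column of a real matrix, by the standard FFT
# construction (double positive frequencies, zero negative ones).
analytic_signal_matrix <- function(X) {
  n <- nrow(X)
  F <- stats::mvfft(X)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(F * h, inverse = TRUE) / n
}
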