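#' Band-pass filter specification
#'
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz < fs/2`
#'   (checked against the sampling rate at application time).
#' @param order Butterworth order (per pass; forward-reverse doubles the
#'   effective order).
#' @param zero_phase apply forward and reverse (`signal::filtfilt`) for zero
#'   net phase shift.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 1, high_hz = 500, order = 3,
                        zero_phase = TRUE) {
  if (low_hz <= 0 || high_hz <= low_hz)
    stop("need 0 < low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 zero_phase = zero_phase), class = "filter_spec")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass in forward and reverse direction
#' (`signal::filtfilt`), giving zero net phase shift and squared magnitude
#' response. Band edges at or above Nyquist are rejected.
#'
#' @param x numeric signal vector.
#' @param fs_hz sampling rate in Hz.
#' @param spec a [filter_spec].
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, fs_hz, spec = filter_spec()) {
  nyq <- fs_hz / 2
  if (spec$high_hz >= nyq) stop("high band edge must be below Nyquist (", nyq, " Hz)")
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                       type = "pass")
  if (spec$zero_phase) signal::filtfilt(bf, x)
  else as.numeric(signal::filter(bf, x))
}

#' QRS subtraction by template averaging
#'
#' Removes far-field ventricular (QRS) artifacts from atrial electrograms:
#' for each channel, the average beat in a window around the supplied
#' R-times is computed and subtracted at every R-time. R-times closer than
#' half a window to the record edge are skipped with a warning. At least 3
#' R-times are required for a stable template; an empty R-time list returns
#' the input untouched.
#'
#' @param egm an [egm_set].
#' @param r_times_ms R-wave instants in ms (defaults to the planted times
#'   stored in the set, if any).
#' @param window_ms template window length in ms, centred on each R-time.
#' @return An [egm_set] with the template subtracted.
#' @export
qrs_subtract <- function(egm, r_times_ms = egm$r_times_ms, window_ms = 120) {
  if (is.null(r_times_ms) || !length(r_times_ms)) return(egm)
  if (length(r_times_ms) < 3L)
    stop("need at least 3 R-times for template averaging")
  fs <- egm$fs_hz
  half <- round(window_ms / 2 * fs / 1000)
  n <- ncol(egm$signals)
  centers <- round(r_times_ms * fs / 1000) + 1L
  usable <- centers - half >= 1L & centers + half <= n
  if (any(!usable))
    warning(sum(!usable), " R-time(s) within half a window of the record edge; skipped")
  centers <- centers[usable]
  if (length(centers) < 3L)
    stop("fewer than 3 usable R-times after edge exclusion")
  offs <- -half:half
  out <- egm$signals
  for (ch in seq_len(nrow(out))) {
    seg <- vapply(centers, function(c0) out[ch, c0 + offs], numeric(length(offs)))
    template <- rowMeans(seg)
    for (c0 in centers) out[ch, c0 + offs] <- out[ch, c0 + offs] - template
  }
  egm$signals <- out
  egm
}

#' Dominant frequency of a signal
#'
#' The in-band peak of the raw periodogram. Its reciprocal (the dominant
#' period) sets the wavelet length for [sinusoidal_recompose].
#' `power_fraction` — the peak bin's share of total in-band power — is
#' returned as a reliability indicator; broadband noise yields a small
#' value.
#'
#' @param x signal vector, at least 2 s long.
#' @param fs_hz sampling rate in Hz.
#' @param band numeric `c(lo, hi)` search band in Hz.
#' @return A list with `df_hz`, `period_ms` (= 1000 / `df_hz`) and
#'   `power_fraction`.
#' @export
dominant_frequency <- function(x, fs_hz, band = c(3, 20)) {
  if (length(x) < 2 * fs_hz) stop("need at least 2 s of signal")
  if (stats::sd(x) < 1e-14) stop("constant signal has no spectral peak")
  x <- x - mean(x)
  n <- length(x)
  spec <- Mod(stats::fft(x)[seq_len(floor(n / 2) + 1)])^2
  freq <- (seq_along(spec) - 1) * fs_hz / n
  in_band <- freq >= band[1] & freq <= band[2]
  if (!any(in_band)) stop("no frequency bins inside the search band")
  k <- which(in_band)[which.max(spec[in_band])]
  df_hz <- freq[k]
  list(df_hz = df_hz, period_ms = 1000 / df_hz,
       power_fraction = spec[k] / sum(spec[in_band]))
}

#' Sinusoidal recomposition
#'
#' Rebuilds a signal as a sum of single-cycle sinusoidal wavelets of period
#' `period_ms`, one centred at every sample, each with amplitude equal to
#' the clipped negative slope of the input there (positive slopes contribute
#' nothing). Sharp downstrokes — the atrial activations — thus become clean
#' sinusoid cycles at the dominant period, giving the signal a well-defined
#' analytic phase.
#'
#' @param x signal vector.
#' @param fs_hz sampling rate in Hz.
#' @param period_ms wavelet (dominant) period in ms; must not exceed the
#'   record duration.
#' @return Recomposed signal, same length as `x`.
#' @export
sinusoidal_recompose <- function(x, fs_hz, period_ms) {
  if (period_ms <= 0) stop("period_ms must be positive")
  n <- length(x)
  if (period_ms > n / fs_hz * 1000) stop("period longer than the record")
  slope <- c(0, diff(x)) * fs_hz            # per second
  amp <- pmax(-slope, 0)
  half <- round(period_ms / 2 * fs_hz / 1000)
  tt <- (-half):half
  wavelet <- cos(2 * pi * tt / (2 * half + 1))
  y <- stats::convolve(amp, rev(wavelet), type = "open")
  y[(half + 1):(half + n)]
}

#' Instantaneous phase via the Hilbert transform
#'
#' De-means the signal and returns the angle of its analytic signal,
#' wrapped to (-pi, pi].
#'
#' @param x signal vector (non-constant).
#' @return Phase series in radians.
#' @export
hilbert_phase <- function(x) {
  x <- x - mean(x)
  if (stats::sd(x) < 1e-14) stop("phase of a constant signal is undefined")
  a <- analytic_signal_matrix(matrix(x, ncol = 1))
  atan2(Im(a[, 1]), Re(a[, 1]))
}

#' Spatial Gaussian low-pass filtering of a movie
#'
#' Convolves each frame with a normalized 2-D Gaussian kernel (default
#' sigma = 4 pixels, the optical-mapping setting). Constant frames pass
#' unchanged and a unit impulse integrates to 1.
#'
#' @param movie T x H x W numeric array (voltage or any per-frame field).
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return Filtered array of the same shape.
#' @export
gaussian_spatiotemporal_filter <- function(movie, sigma = 4) {
  if (sigma <= 0) stop("sigma must be positive")
  d <- dim(movie)
  if (length(d) != 3L) stop("movie must be a T x H x W array")
  size <- 2L * ceiling(3 * sigma) + 1L
  size <- min(size, 2L * floor((min(d[2], d[3]) - 1L) / 2L) + 1L)
  brush <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
  brush <- brush / sum(brush)
  out <- movie
  for (t in seq_len(d[1]))
    out[t, , ] <- EBImage::filter2(movie[t, , ], brush, boundary = "replicate")
  out
}
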