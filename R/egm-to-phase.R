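#' Interpolate a wrapped phase field on the unit phasor
#'
#' Wrapped angles cannot be interpolated linearly across the +/- pi branch
#' cut; instead the unit phasor `exp(i * phi)` is interpolated bilinearly
#' (real and imaginary parts separately) and the angle of the result taken.
#'
#' @param frame H x W matrix of wrapped phase.
#' @param target_shape `c(H2, W2)` output shape; the target grid spans the
#'   same physical extent as the input.
#' @return H2 x W2 matrix of wrapped phase.
#' @export
interp_phase_frame <- function(frame, target_shape) {
  H <- nrow(frame); W <- ncol(frame)
  H2 <- target_shape[1]; W2 <- target_shape[2]
  if (H2 == H && W2 == W) return(frame)
  xs <- seq(0, W - 1); ys <- seq(0, H - 1)
  xt <- seq(0, W - 1, length.out = W2)
  yt <- seq(0, H - 1, length.out = H2)
  xp <- rep(xt, each = H2); yp <- rep(yt, W2)
  re <- pracma::interp2(xs, ys, cos(frame), xp, yp, method = "linear")
  im <- pracma::interp2(xs, ys, sin(frame), xp, yp, method = "linear")
  matrix(atan2(im, re), H2, W2)
}

# Precomputed bilinear stencil mapping an H x W grid onto the uniform
# H2 x W2 target covering the same extent: four column-major corner indices
# and weights per target pixel. Lets a whole movie be interpolated with
# four matrix gathers per frame set instead of per-frame interp2 calls.
bilinear_grid <- function(H, W, H2, W2) {
  xp <- rep(seq(0, W - 1, length.out = W2), each = H2)
  yp <- rep(seq(0, H - 1, length.out = H2), times = W2)
  j0 <- pmin(floor(xp), W - 2); i0 <- pmin(floor(yp), H - 2)
  tx <- xp - j0; ty <- yp - i0
  id <- function(i, j) i + j * H + 1L           # column-major linear index
  list(idx = cbind(id(i0, j0), id(i0 + 1, j0),
                   id(i0, j0 + 1), id(i0 + 1, j0 + 1)),
       w = cbind((1 - tx) * (1 - ty), (1 - tx) * ty,
                 tx * (1 - ty), tx * ty))
}

# Phasor-interpolate every frame at once. `flat` is a T x (H * W) matrix of
# column-major flattened frames; returns T x (H2 * W2).
interp_phasor_flat <- function(flat, g) {
  re <- cos(flat); im <- sin(flat)
  gather <- function(M) M[, g$idx[, 1], drop = FALSE] * rep(g$w[, 1], each = nrow(M)) +
    M[, g$idx[, 2], drop = FALSE] * rep(g$w[, 2], each = nrow(M)) +
    M[, g$idx[, 3], drop = FALSE] * rep(g$w[, 3], each = nrow(M)) +
    M[, g$idx[, 4], drop = FALSE] * rep(g$w[, 4], each = nrow(M))
  atan2(gather(im), gather(re))
}

#' Build a phase movie from an electrogram set
#'
#' The full preprocessing chain: optional QRS subtraction, zero-phase
#' Butterworth band-pass, dominant-frequency estimation, sinusoidal
#' recomposition at the dominant period, Hilbert phase, then arrangement of
#' the channel phases on the electrode grid with optional phasor
#' interpolation to a finer analysis resolution (the clinical chain
#' interpolates an 8 x 8 basket to 29 x 29).
#'
#' Channels with (near-)zero variance after filtering are masked out. If the
#' masked fraction exceeds `max_missing`, the coverage is considered
#' insufficient and an error is raised.
#'
#' @param egm an [egm_set] whose channels fill a `grid_shape` rectangle
#'   row by row (channel 1 = top-left, row-major).
#' @param grid_shape `c(H, W)` electrode layout; `H * W` must equal the
#'   channel count.
#' @param config list of chain settings: `qrs` (logical, default `TRUE` when
#'   R-times are present), `filter` (a [filter_spec]), `df_band` (Hz),
#'   `interp_shape` (target `c(H2, W2)` or `NULL`), `max_missing` (fraction,
#'   default 0.25).
#' @param pixel_mm electrode spacing in mm (after interpolation the spacing
#'   is rescaled accordingly).
#' @return A [phase_movie] with `dt_ms = 1000 / fs_hz`.
#' @export
egm_to_phase_movie <- function(egm, grid_shape, config = list(), pixel_mm = 1) {
  H <- grid_shape[1]; W <- grid_shape[2]
  if (H * W != nrow(egm$signals))
    stop("grid_shape does not match the channel count")
  cfg <- utils::modifyList(list(
    qrs = !is.null(egm$r_times_ms),
    filter = filter_spec(1, min(500, egm$fs_hz / 2 * 0.98)),
    df_band = c(3, 20),
    interp_shape = NULL,
    max_missing = 0.25), config)
  if (cfg$qrs) egm <- qrs_subtract(egm)
  n <- ncol(egm$signals)
  nch <- nrow(egm$signals)
  phases <- matrix(0, n, nch)
  good <- logical(nch)
  for (ch in seq_len(nch)) {
    x <- bandpass_zero_phase(egm$signals[ch, ], egm$fs_hz, cfg$filter)
    if (stats::sd(x) < 1e-10) next
    df <- tryCatch(dominant_frequency(x, egm$fs_hz, cfg$df_band),
                   error = function(e) NULL)
    if (is.null(df)) next
    y <- sinusoidal_recompose(x, egm$fs_hz, df$period_ms)
    if (stats::sd(y) < 1e-12) next
    phases[, ch] <- hilbert_phase(y)
    good[ch] <- TRUE
  }
  if (mean(!good) > cfg$max_missing)
    stop(sprintf("coverage error: %.0f%% of channels unusable",
                 100 * mean(!good)))
  # channel k sits at row (k-1) %/% W + 1, column (k-1) %% W + 1
  mask <- matrix(FALSE, H, W)
  values <- array(0, c(n, H, W))
  for (ch in seq_len(nch)) {
    r <- (ch - 1L) %/% W + 1L; c <- (ch - 1L) %% W + 1L
    mask[r, c] <- good[ch]
    values[, r, c] <- phases[, ch]
  }
  movie <- phase_movie(values, dt_ms = 1000 / egm$fs_hz, pixel_mm = pixel_mm,
                       mask = mask,
                       metadata = list(chain = "qrs|bandpass|df|recompose|hilbert"))
  if (!is.null(cfg$interp_shape))
    movie <- interpolate_movie(movie, cfg$interp_shape)
  movie
}

#' Phasor-interpolate a phase movie to a new resolution
#'
#' @param movie a [phase_movie].
#' @param target_shape `c(H2, W2)`.
#' @return A [phase_movie] at the target resolution; the mask is
#'   nearest-neighbour resampled and `pixel_mm` rescaled to preserve the
#'   physical extent.
#' @export
interpolate_movie <- function(movie, target_shape) {
  d <- dim(movie)
  H2 <- target_shape[1]; W2 <- target_shape[2]
  if (H2 == d[2] && W2 == d[3]) {
    values <- movie$values
  } else {
    g <- bilinear_grid(d[2], d[3], H2, W2)
    flat <- matrix(movie$values, nrow = d[1])    # T x (H * W), column-major
    values <- array(interp_phasor_flat(flat, g), c(d[1], H2, W2))
  }
  ri <- round(seq(1, d[2], length.out = H2))
  ci <- round(seq(1, d[3], length.out = W2))
  mask2 <- movie$mask[ri, ci, drop = FALSE]
  phase_movie(values, dt_ms = movie$dt_ms,
              pixel_mm = movie$pixel_mm * (d[3] - 1) / max(W2 - 1, 1),
              mask = mask2, metadata = movie$metadata)
}
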