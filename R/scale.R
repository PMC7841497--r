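#' Coarse-grain a phase movie and interpolate back
#'
#' Emulates mapping at a lower electrode density: keeps a spatially uniform
#' `keep_shape` subgrid of pixels, then phasor-interpolates back to an
#' analysis resolution (default: the original shape). Masked pixels stay
#' masked.
#'
#' @param movie a [phase_movie].
#' @param keep_shape `c(h, w)` retained grid, at least 2 x 2 and no larger
#'   than the movie.
#' @param analysis_shape target shape after re-interpolation; default the
#'   original shape. When `keep_shape` equals the movie shape the movie is
#'   returned unchanged.
#' @return A [phase_movie].
#' @export
decimate_and_interpolate <- function(movie, keep_shape,
                                     analysis_shape = dim(movie)[2:3]) {
  d <- dim(movie)
  if (any(keep_shape < 2L)) stop("keep_shape must be at least 2 x 2")
  if (any(keep_shape > d[2:3])) stop("keep_shape exceeds the movie shape")
  if (all(keep_shape == d[2:3]) && all(analysis_shape == d[2:3])) return(movie)
  ri <- round(seq(1, d[2], length.out = keep_shape[1]))
  ci <- round(seq(1, d[3], length.out = keep_shape[2]))
  values <- movie$values[, ri, ci, drop = FALSE]
  sub <- phase_movie(values, dt_ms = movie$dt_ms,
                     pixel_mm = movie$pixel_mm * (d[3] - 1) / max(keep_shape[2] - 1, 1),
                     mask = movie$mask[ri, ci, drop = FALSE],
                     metadata = movie$metadata)
  interpolate_movie(sub, analysis_shape)
}

#' Crop a phase movie to a sub-window
#'
#' Restricts the mapped field of view: entities whose trajectories leave
#' the window appear downstream as boundary deaths, which is how a smaller
#' mapped area inflates apparent destruction rates.
#'
#' @param movie a [phase_movie].
#' @param window list or vector `c(row0, row1, col0, col1)` (1-based,
#'   inclusive) inside the grid.
#' @return The restricted [phase_movie].
#' @export
crop_field <- function(movie, window) {
  d <- dim(movie)
  w <- as.integer(unlist(window))
  if (length(w) != 4L) stop("window must be c(row0, row1, col0, col1)")
  if (w[1] < 1L || w[3] < 1L || w[2] > d[2] || w[4] > d[3] ||
      w[2] < w[1] || w[4] < w[3])
    stop("window must be a non-empty region inside the grid")
  phase_movie(movie$values[, w[1]:w[2], w[3]:w[4], drop = FALSE],
              dt_ms = movie$dt_ms, pixel_mm = movie$pixel_mm,
              mask = movie$mask[w[1]:w[2], w[3]:w[4], drop = FALSE],
              metadata = movie$metadata)
}
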