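#' Multichannel unipolar electrogram sets
#'
#' An `egm_set` holds channels x samples unipolar electrograms with the
#' sampling rate, electrode coordinates, and (for synthetic fixtures) the
#' planted R-wave instants and ground-truth atrial component.
#'
#' @param signals channels x samples numeric matrix.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param coords_mm channels x 2 matrix of electrode x, y positions in mm.
#' @param r_times_ms optional planted QRS instants in ms.
#' @param metadata named list (e.g. ground-truth components).
#' @return An object of class `egm_set`.
#' @export
egm_set <- function(signals, fs_hz, coords_mm = NULL, r_times_ms = NULL,
                    metadata = list()) {
  signals <- as.matrix(signals)
  if (fs_hz <= 0) stop("fs_hz must be positive")
  if (!is.null(coords_mm) && nrow(as.matrix(coords_mm)) != nrow(signals))
    stop("coords_mm must have one row per channel")
  structure(list(signals = signals, fs_hz = fs_hz,
                 coords_mm = if (is.null(coords_mm)) NULL else as.matrix(coords_mm),
                 r_times_ms = r_times_ms, metadata = metadata),
            class = "egm_set")
}

#' @export
print.egm_set <- function(x, ...) {
  cat(sprintf("egm_set: %d channels x %d samples at %g Hz (%.2f s)\n",
              nrow(x$signals), ncol(x$signals), x$fs_hz,
              ncol(x$signals) / x$fs_hz))
  invisible(x)
}

#' Synthetic electrograms with a planted QRS-like far-field artifact
#'
#' Builds channels of a known atrial component and inserts a shared QRS-like
#' template at the given R-times, producing the fixture on which
#' [qrs_subtract] is validated: the true atrial component is retained in
#' `metadata$atrial`.
#'
#' @param atrial channels x samples matrix: the ground-truth atrial
#'   component.
#' @param fs_hz sampling rate in Hz.
#' @param r_times_ms R-wave instants in ms; template insertions must not
#'   overlap.
#' @param qrs_template numeric vector added (centred) at each R-time on
#'   every channel; default a biphasic artifact. Must be shorter than the
#'   minimum R-R interval.
#' @param coords_mm optional electrode coordinates.
#' @return An [egm_set] with `r_times_ms` and `metadata$atrial` set.
#' @export
make_synthetic_egm <- function(atrial, fs_hz, r_times_ms = numeric(),
                               qrs_template = default_qrs_template(fs_hz),
                               coords_mm = NULL) {
  atrial <- as.matrix(atrial)
  n <- ncol(atrial)
  signals <- atrial
  L <- length(qrs_template)
  if (length(r_times_ms) > 1L) {
    rr <- min(diff(sort(r_times_ms)))
    if (L / fs_hz * 1000 >= rr)
      stop("QRS template insertions overlap (template longer than min R-R)")
  }
  half <- floor(L / 2)
  for (r in r_times_ms) {
    c0 <- round(r * fs_hz / 1000) + 1L
    idx <- (c0 - half):(c0 - half + L - 1L)
    if (idx[1] < 1L || idx[length(idx)] > n)
      stop("R-time too close to the record edge for the template")
    signals[, idx] <- signals[, idx] +
      matrix(qrs_template, nrow(atrial), L, byrow = TRUE)
  }
  egm_set(signals, fs_hz, coords_mm = coords_mm,
          r_times_ms = if (length(r_times_ms)) r_times_ms else NULL,
          metadata = list(atrial = atrial))
}

#' @rdname make_synthetic_egm
#' @export
default_qrs_template <- function(fs_hz, width_ms = 80, amplitude = 3) {
  tt <- seq(-width_ms / 2, width_ms / 2, by = 1000 / fs_hz)
  w <- width_ms / 6
  amplitude * (exp(-(tt - w)^2 / (2 * w^2)) - exp(-(tt + w)^2 / (2 * w^2)))
}

#' Read / write an electrogram set as CSV plus JSON sidecar
#'
#' `signals.csv` holds one row per channel; the JSON sidecar carries
#' `fs_hz`, `coords_mm`, and `r_times_ms`.
#'
#' @param egm an [egm_set].
#' @param path base path; writes `<path>.csv` and `<path>.json`.
#' @return `read_egm_csv` returns an [egm_set]; the writer returns `path`
#'   invisibly.
#' @export
write_egm_csv <- function(egm, path) {
  utils::write.table(egm$signals, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(fs_hz = egm$fs_hz,
         coords_mm = egm$coords_mm,
         r_times_ms = egm$r_times_ms),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_egm_csv
#' @export
read_egm_csv <- function(path) {
  signals <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  dimnames(signals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  egm_set(signals, fs_hz = meta$fs_hz,
          coords_mm = meta$coords_mm,
          r_times_ms = meta$r_times_ms)
}
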