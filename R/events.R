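#' Event tables of tracked phase singularities and wavelets
#'
#' An `event_table` is a data frame with one row per tracked entity (a phase
#' singularity or a wavelet), the "look-up table" produced by detection and
#' tracking: onset and offset times, location, chirality, and censoring flags
#' marking lifetimes truncated by the epoch boundaries.
#'
#' Columns (exact, in order): `id`, `kind`, `onset_ms`, `offset_ms`, `x`, `y`,
#' `chirality`, `censored_left`, `censored_right`.
#'
#' Time intervals are half-open `[onset, offset)`; an entity's lifetime is
#' `offset_ms - onset_ms`, so a single-frame entity has lifetime equal to the
#' frame interval. `chirality` is +1 or -1 for phase singularities and `NA`
#' for wavelets.
#'
#' @param id integer entity ids (unique).
#' @param kind `"PS"` or `"wavelet"` (recycled).
#' @param onset_ms,offset_ms onset and offset times in ms, `offset_ms >=
#'   onset_ms`.
#' @param x,y representative location (pixel or mm; unit carried by the
#'   caller's metadata).
#' @param chirality +1, -1 or `NA`.
#' @param censored_left,censored_right logical; `TRUE` when the onset
#'   (offset) coincides with the epoch start (end) so the true lifetime is
#'   longer than observed.
#' @param epoch_ms epoch length in ms, attached as the `epoch_ms` attribute.
#'
#' @return A data frame of class `event_table`.
#' @export
event_table <- function(id = integer(), kind = character(),
                        onset_ms = numeric(), offset_ms = numeric(),
                        x = numeric(), y = numeric(),
                        chirality = numeric(),
                        censored_left = logical(),
                        censored_right = logical(),
                        epoch_ms = NA_real_) {
  n <- length(id)
  df <- data.frame(
    id = as.integer(id),
    kind = rep_len(as.character(kind), n),
    onset_ms = as.numeric(onset_ms),
    offset_ms = as.numeric(offset_ms),
    x = rep_len(as.numeric(x), n),
    y = rep_len(as.numeric(y), n),
    chirality = rep_len(as.numeric(chirality), n),
    censored_left = rep_len(as.logical(censored_left), n),
    censored_right = rep_len(as.logical(censored_right), n),
    stringsAsFactors = FALSE
  )
  validate_event_table(df)
  attr(df, "epoch_ms") <- epoch_ms
  class(df) <- c("event_table", "data.frame")
  df
}

validate_event_table <- function(df) {
  if (nrow(df)) {
    if (anyDuplicated(df$id)) stop("event_table: ids must be unique")
    if (any(df$offset_ms < df$onset_ms))
      stop("event_table: offset_ms must be >= onset_ms")
    bad <- !(df$chirality %in% c(-1, 1) | is.na(df$chirality))
    if (any(bad)) stop("event_table: chirality must be +1, -1 or NA")
  }
  invisible(df)
}

#' @export
print.event_table <- function(x, n = 10L, ...) {
  cat(sprintf("event_table: %d entities (%s), epoch %s ms\n", nrow(x),
              paste(unique(x$kind), collapse = "/"),
              format(attr(x, "epoch_ms"))))
  print.data.frame(utils::head(as.data.frame(x), n), ...)
  if (nrow(x) > n) cat(sprintf("... %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Read / write an event table as CSV
#'
#' The CSV has exactly the columns `id, kind, onset_ms, offset_ms, x, y,
#' chirality, censored_left, censored_right`. The epoch length, if known, is
#' stored in a `# epoch_ms:` comment header line and restored on read.
#'
#' @param events an `event_table`.
#' @param path file path.
#' @return `write_event_table` returns `path` invisibly; `read_event_table`
#'   returns an `event_table`.
#' @export
write_event_table <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ep <- attr(events, "epoch_ms")
  if (!is.null(ep) && !is.na(ep)) writeLines(sprintf("# epoch_ms: %.10g", ep), con)
  utils::write.csv(as.data.frame(events)[, EVENT_COLUMNS], con, row.names = FALSE)
  invisible(path)
}

EVENT_COLUMNS <- c("id", "kind", "onset_ms", "offset_ms", "x", "y",
                   "chirality", "censored_left", "censored_right")

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  first <- readLines(path, n = 1L)
  epoch_ms <- NA_real_
  if (startsWith(first, "# epoch_ms:"))
    epoch_ms <- as.numeric(sub("# epoch_ms:", "", first))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(EVENT_COLUMNS, names(df))
  if (length(missing))
    stop("event table CSV missing columns: ", paste(missing, collapse = ", "))
  event_table(df$id, df$kind, df$onset_ms, df$offset_ms, df$x, df$y,
              df$chirality, df$censored_left, df$censored_right,
              epoch_ms = epoch_ms)
}
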