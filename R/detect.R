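#' Detect phase singularities by the convolutional kernel method
#'
#' Computes the discrete line integral of wrapped phase differences around
#' every 2 x 2 plaquette of the frame by convolution-style shifted-array
#' arithmetic. A plaquette whose integral is +/- 2 pi encloses a phase
#' singularity of that topological charge; the PS is reported at the
#' plaquette centre (fractional pixel coordinates, 0-based, x = column,
#' y = row). Plaquettes touching a masked pixel are skipped.
#'
#' @param frame H x W matrix of wrapped phase (radians).
#' @param mask optional logical H x W valid-pixel matrix.
#' @param frame_index frame number stored in the output (default 1).
#' @return A data frame with columns `frame`, `x`, `y`, `chirality`,
#'   `method`; zero rows when nothing is found (a fully masked frame is not
#'   an error).
#' @export
detect_ps_kernel <- function(frame, mask = NULL, frame_index = 1L) {
  H <- nrow(frame); W <- ncol(frame)
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  empty <- ps_detections()
  if (H < 2L || W < 2L) return(empty)
  p00 <- frame[-H, -W]; p01 <- frame[-H, -1]
  p11 <- frame[-1, -1]; p10 <- frame[-1, -W]
  # counter-clockwise circulation (x right, y down the row index):
  # (x,y) -> (x+1,y) -> (x+1,y+1) -> (x,y+1) -> close
  winding <- wrap_phase(p01 - p00) + wrap_phase(p11 - p01) +
             wrap_phase(p10 - p11) + wrap_phase(p00 - p10)
  ok <- mask[-H, -W] & mask[-H, -1] & mask[-1, -1] & mask[-1, -W]
  charge <- round(winding / (2 * pi))
  charge[!ok] <- 0L
  hits <- which(charge != 0, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  ps_detections(frame = frame_index,
                x = hits[, 2] - 1 + 0.5, y = hits[, 1] - 1 + 0.5,
                chirality = charge[hits], method = "kernel")
}

ps_detections <- function(frame = integer(), x = numeric(), y = numeric(),
                          chirality = numeric(), method = character()) {
  n <- length(x)
  data.frame(frame = rep_len(as.integer(frame), n), x = as.numeric(x),
             y = as.numeric(y), chirality = as.numeric(chirality),
             method = rep_len(as.character(method), n),
             stringsAsFactors = FALSE)
}

# ring offsets (dx, dy), counter-clockwise
RING1 <- cbind(c(1, 1, 0, -1, -1, -1, 0, 1), c(0, 1, 1, 1, 0, -1, -1, -1))
RING2 <- cbind(c(2, 2, 2, 1, 0, -1, -2, -2, -2, -2, -2, -1, 0, 1, 2, 2),
               c(0, 1, 2, 2, 2, 2, 2, 1, 0, -1, -2, -2, -2, -2, -2, -1))

#' Detect phase singularities by the double ring method
#'
#' A pixel is a PS candidate when the phase winding number around both of
#' two concentric integration rings (radius 1 and radius 2 pixels) equals
#' the same +/- 1. Because neighbouring rings can enclose the same defect,
#' 8-connected candidate clusters of equal charge are merged and reported at
#' their centroid. Pixels within 2 pixels of the boundary (or of masked
#' pixels) cannot complete the outer ring and are never reported.
#'
#' @inheritParams detect_ps_kernel
#' @return A data frame as in [detect_ps_kernel] with `method =
#'   "double_ring"`.
#' @export
detect_ps_double_ring <- function(frame, mask = NULL, frame_index = 1L) {
  H <- nrow(frame); W <- ncol(frame)
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  empty <- ps_detections()
  if (H < 5L || W < 5L) return(empty)
  w1 <- ring_winding(frame, mask, RING1)
  w2 <- ring_winding(frame, mask, RING2)
  charge <- ifelse(!is.na(w1) & !is.na(w2) & w1 == w2, w1, 0L)
  charge[is.na(charge)] <- 0L
  hits <- which(charge != 0)
  if (!length(hits)) return(empty)
  lab <- EBImage::bwlabel(matrix(as.integer(charge != 0), H, W))
  out <- lapply(sort(unique(lab[hits])), function(l) {
    idx <- which(lab == l & charge != 0, arr.ind = TRUE)
    q <- charge[cbind(idx[, 1], idx[, 2])]
    # a cluster mixing signs would be two unresolvable defects; split by sign
    lapply(unique(q), function(s) {
      sub <- idx[q == s, , drop = FALSE]
      ps_detections(frame_index, mean(sub[, 2]) - 1, mean(sub[, 1]) - 1,
                    s, "double_ring")
    })
  })
  do.call(rbind, unlist(out, recursive = FALSE))
}

# winding number (in units of 2*pi) around a ring of given offsets at every
# pixel; NA where the ring leaves the grid or touches a masked pixel
ring_winding <- function(frame, mask, ring) {
  H <- nrow(frame); W <- ncol(frame)
  r <- max(abs(ring))
  total <- matrix(0, H, W)
  valid <- matrix(TRUE, H, W)
  nr <- nrow(ring)
  shifted <- function(k) {
    dx <- ring[k, 1]; dy <- ring[k, 2]
    out <- matrix(NA_real_, H, W)
    rows <- seq_len(H) + dy; cols <- seq_len(W) + dx
    okr <- rows >= 1 & rows <= H; okc <- cols >= 1 & cols <= W
    out[okr, okc] <- frame[rows[okr], cols[okc]]
    mv <- matrix(FALSE, H, W)
    mv[okr, okc] <- mask[rows[okr], cols[okc]]
    list(phase = out, valid = mv)
  }
  prev <- shifted(nr)                     # close the loop: last -> first
  for (k in seq_len(nr)) {
    cur <- shifted(k)
    total <- total + wrap_phase(cur$phase - prev$phase)
    valid <- valid & cur$valid
    prev <- cur
  }
  w <- round(total / (2 * pi))
  w[!valid | is.na(w)] <- NA
  w
}

#' Detect phase singularities in every frame of a movie
#'
#' @param movie a [phase_movie].
#' @param method `"kernel"` or `"double_ring"`.
#' @return A data frame of per-frame detections (`frame`, `x`, `y`,
#'   `chirality`, `method`), frames numbered from 1.
#' @export
detect_ps <- function(movie, method = c("kernel", "double_ring")) {
  method <- match.arg(method)
  fun <- switch(method, kernel = detect_ps_kernel,
                double_ring = detect_ps_double_ring)
  n <- dim(movie)[1]
  out <- vector("list", n)
  for (t in seq_len(n))
    out[[t]] <- fun(movie$values[t, , ], movie$mask, frame_index = t)
  do.call(rbind, out)
}
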