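#' Tracking configuration
#'
#' Parameters of frame-to-frame association: detections within radius `r` of
#' an existing entity continue it; anything farther opens a new entity; an
#' entity unmatched in a frame closes; entities living less than `tau_ms`
#' are discarded. Primary-analysis defaults follow the human basket mapping
#' settings (tau = 10 ms, r = 4 mm; `r_unit` declares whether `r` is in mm
#' or pixels).
#'
#' @param r association radius (> 0).
#' @param r_unit `"px"` or `"mm"`; mm is converted using the movie's
#'   `pixel_mm` at tracking time.
#' @param tau_ms minimum lifetime in ms (>= 0).
#' @param match_chirality require equal chirality for PS association
#'   (default `TRUE`; a defect cannot change its topological charge).
#' @param assignment `"optimal"` (minimal-total-distance bipartite
#'   assignment, default) or `"greedy"` (nearest pair first).
#' @return An object of class `track_config`.
#' @export
track_config <- function(r = 4, r_unit = c("mm", "px"), tau_ms = 10,
                         match_chirality = TRUE,
                         assignment = c("optimal", "greedy")) {
  r_unit <- match.arg(r_unit)
  assignment <- match.arg(assignment)
  if (r <= 0) stop("association radius r must be positive")
  if (tau_ms < 0) stop("tau_ms must be >= 0")
  structure(list(r = r, r_unit = r_unit, tau_ms = tau_ms,
                 match_chirality = match_chirality, assignment = assignment),
            class = "track_config")
}

BIG_COST <- 1e9

# Minimal-cost assignment (Hungarian algorithm, shortest augmenting paths,
# O(n^3)). cost: n x m matrix, n <= m. Returns integer vector a with a[i]
# the column assigned to row i.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("solve_assignment needs nrow <= ncol")
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)   # index 1 is the virtual column
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, m + 1)
    used <- logical(m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(m) + 1L) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0 + 1L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) { u[p[j] + 1L] <- u[p[j] + 1L] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  a <- integer(n)
  for (j in seq_len(m) + 1L) if (p[j] > 0L) a[p[j]] <- j - 1L
  a
}

# Greedy nearest-pair-first matching; same return convention, 0 = unmatched.
solve_greedy <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  a <- integer(n)
  cost <- cost  # local copy
  repeat {
    k <- which.min(cost)
    if (!length(k) || cost[k] >= BIG_COST / 2) break
    i <- (k - 1L) %% n + 1L; j <- (k - 1L) %/% n + 1L
    a[i] <- j
    cost[i, ] <- Inf; cost[, j] <- Inf
  }
  a
}

# Match rows (existing entities) to columns (new detections) given a cost
# matrix with BIG_COST marking forbidden pairs. Returns a[i] in 0..m.
match_frame <- function(cost, assignment) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(integer(n))
  if (assignment == "greedy") return(solve_greedy(cost))
  # pad with dummy columns so every row can stay unmatched at BIG_COST
  padded <- cbind(cost, matrix(BIG_COST, n, n))
  a <- solve_assignment(padded)
  a[a > m] <- 0L
  # dummy-padded optimum can still route a row through a forbidden column
  for (i in seq_len(n)) if (a[i] > 0L && cost[i, a[i]] >= BIG_COST / 2) a[i] <- 0L
  a
}

#' Track detections through time into an event table
#'
#' Associates per-frame detections into entities by minimal-total-distance
#' bipartite matching within the radius `config$r` (ties broken by lowest
#' entity id through the deterministic assignment), opening new entities for
#' unmatched detections and closing entities that go unmatched. For phase
#' singularities the chirality must match by default. Entities shorter than
#' `config$tau_ms` are discarded. Wavefront input (a per-frame list of
#' polylines from [extract_wavefronts_movie]) is associated by shared-pixel
#' overlap of rasterized polylines instead of point distance.
#'
#' @param detections either a data frame from [detect_ps] (columns `frame`,
#'   `x`, `y`, `chirality`) or a per-frame list of wavefronts.
#' @param config a [track_config].
#' @param dt_ms frame interval in ms.
#' @param n_frames total frames in the movie (defaults to the last frame
#'   carrying a detection); needed to set right-censoring flags.
#' @param pixel_mm pixel spacing used to convert `r` from mm.
#' @param min_overlap_px minimum shared-pixel count for wavefront identity.
#' @return An [event_table]; intervals are half-open so a single-frame
#'   entity has lifetime `dt_ms`. Location is the entity's mean position.
#' @export
track_entities <- function(detections, config = track_config(), dt_ms,
                           n_frames = NULL, pixel_mm = 1, min_overlap_px = 1) {
  if (is.data.frame(detections))
    track_points(detections, config, dt_ms, n_frames, pixel_mm)
  else
    track_fronts(detections, config, dt_ms, n_frames, min_overlap_px)
}

track_points <- function(det, config, dt_ms, n_frames, pixel_mm) {
  if (is.null(n_frames))
    n_frames <- if (nrow(det)) max(det$frame) else 0L
  r_px <- if (config$r_unit == "mm") config$r / pixel_mm else config$r
  kind <- "PS"
  open <- list()    # active entities
  done <- list()
  new_entity <- function(f, x, y, q)
    list(onset = f, last = f, x = x, y = y, chirality = q,
         sx = x, sy = y, nobs = 1L)
  for (t in seq_len(max(n_frames, 1L))) {
    d <- det[det$frame == t, , drop = FALSE]
    nA <- length(open); nB <- nrow(d)
    a <- integer(nA)
    if (nA && nB) {
      cost <- matrix(BIG_COST, nA, nB)
      for (i in seq_len(nA)) {
        e <- open[[i]]
        dist <- sqrt((d$x - e$x)^2 + (d$y - e$y)^2)
        ok <- dist <= r_px
        if (config$match_chirality)
          ok <- ok & (is.na(d$chirality) | is.na(e$chirality) |
                        d$chirality == e$chirality)
        ok[is.na(ok)] <- FALSE
        cost[i, ok] <- dist[ok]
      }
      a <- match_frame(cost, config$assignment)
    }
    matched_det <- a[a > 0L]
    surv <- list()
    for (i in seq_len(nA)) {
      e <- open[[i]]
      if (i <= length(a) && a[i] > 0L) {
        j <- a[i]
        e$last <- t; e$x <- d$x[j]; e$y <- d$y[j]
        e$sx <- e$sx + d$x[j]; e$sy <- e$sy + d$y[j]; e$nobs <- e$nobs + 1L
        surv[[length(surv) + 1L]] <- e
      } else {
        done[[length(done) + 1L]] <- e
      }
    }
    for (j in setdiff(seq_len(nB), matched_det))
      surv[[length(surv) + 1L]] <-
        new_entity(t, d$x[j], d$y[j], d$chirality[j])
    open <- surv
  }
  done <- c(done, open)
  finalize_tracks(done, kind, dt_ms, n_frames, config$tau_ms)
}

track_fronts <- function(frames, config, dt_ms, n_frames, min_overlap_px) {
  if (is.null(n_frames)) n_frames <- length(frames)
  rasterize <- function(front) {
    p <- round(front$polyline)
    unique(paste(p[, 1], p[, 2]))
  }
  open <- list(); done <- list()
  for (t in seq_len(max(n_frames, 1L))) {
    fr <- if (t <= length(frames)) frames[[t]] else list()
    pix <- lapply(fr, rasterize)
    cen <- lapply(fr, function(f) colMeans(f$polyline))
    nA <- length(open); nB <- length(fr)
    a <- integer(nA)
    if (nA && nB) {
      cost <- matrix(BIG_COST, nA, nB)
      for (i in seq_len(nA)) for (j in seq_len(nB)) {
        ov <- length(intersect(open[[i]]$pix, pix[[j]]))
        if (ov >= min_overlap_px) cost[i, j] <- -ov
      }
      a <- match_frame(cost, config$assignment)
    }
    surv <- list()
    for (i in seq_len(nA)) {
      e <- open[[i]]
      if (i <= length(a) && a[i] > 0L) {
        j <- a[i]
        e$last <- t; e$pix <- pix[[j]]
        e$sx <- e$sx + cen[[j]][1]; e$sy <- e$sy + cen[[j]][2]
        e$nobs <- e$nobs + 1L
        surv[[length(surv) + 1L]] <- e
      } else done[[length(done) + 1L]] <- e
    }
    for (j in setdiff(seq_len(nB), a[a > 0L]))
      surv[[length(surv) + 1L]] <-
        list(onset = t, last = t, pix = pix[[j]], chirality = NA_real_,
             sx = cen[[j]][1], sy = cen[[j]][2], nobs = 1L)
    open <- surv
  }
  done <- c(done, open)
  finalize_tracks(done, "wavelet", dt_ms, n_frames, config$tau_ms)
}

finalize_tracks <- function(done, kind, dt_ms, n_frames, tau_ms) {
  if (!length(done))
    return(event_table(epoch_ms = n_frames * dt_ms))
  life <- vapply(done, function(e) (e$last - e$onset + 1L) * dt_ms, 1)
  keep <- life >= tau_ms
  done <- done[keep]
  if (!length(done))
    return(event_table(epoch_ms = n_frames * dt_ms))
  ord <- order(vapply(done, `[[`, 1, "onset"),
               vapply(done, `[[`, 1, "last"))
  done <- done[ord]
  event_table(
    id = seq_along(done), kind = kind,
    onset_ms = vapply(done, function(e) (e$onset - 1L) * dt_ms, 1),
    offset_ms = vapply(done, function(e) e$last * dt_ms, 1),
    x = vapply(done, function(e) e$sx / e$nobs, 1),
    y = vapply(done, function(e) e$sy / e$nobs, 1),
    chirality = vapply(done, function(e)
      if (is.null(e$chirality)) NA_real_ else as.numeric(e$chirality), 1),
    censored_left = vapply(done, function(e) e$onset == 1L, TRUE),
    censored_right = vapply(done, function(e) e$last == n_frames, TRUE),
    epoch_ms = n_frames * dt_ms)
}
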