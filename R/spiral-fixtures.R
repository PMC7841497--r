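#' Scripted spiral-defect phase movies with exact ground truth
#'
#' A `spiral_script` is a declarative list of phase defects — the pivots of
#' rotors — each with a birth frame, death frame, a per-frame path, and a
#' chirality (topological charge) of +1 or -1. [make_spiral_phase_movie]
#' renders the script into a wrapped-phase movie whose winding number around
#' each live defect equals its chirality by construction, together with the
#' exact [event_table] the detector/tracker chain should recover.
#'
#' @param defects a list; each element a list with `birth_frame`,
#'   `death_frame` (1-based, inclusive), `path` (a `death - birth + 1` by 2
#'   matrix of x, y pixel coordinates, 0-based like detections), and
#'   `chirality` (+1 or -1).
#' @param omega uniform background rotation rate in rad per frame.
#' @param pair_mode logical; declares that defects were planted as
#'   opposite-chirality pairs sharing birth and death frames, so the net
#'   planted charge is constant over time (checked).
#' @return An object of class `spiral_script`.
#' @export
spiral_script <- function(defects = list(), omega = 0.2, pair_mode = FALSE) {
  for (d in defects) {
    if (d$death_frame < d$birth_frame) stop("death_frame must be >= birth_frame")
    if (nrow(d$path) != d$death_frame - d$birth_frame + 1L)
      stop("path must have one row per live frame")
    if (!d$chirality %in% c(-1, 1)) stop("chirality must be +1 or -1")
  }
  if (pair_mode && length(defects)) {
    n_frames <- max(vapply(defects, `[[`, 1, "death_frame"))
    q <- vapply(seq_len(n_frames), function(f) {
      sum(vapply(defects, function(d)
        if (f >= d$birth_frame && f <= d$death_frame) d$chirality else 0,
        numeric(1)))
    }, numeric(1))
    if (length(unique(q)) > 1L)
      stop("pair_mode: net planted charge must be constant over frames")
  }
  structure(list(defects = defects, omega = omega, pair_mode = pair_mode),
            class = "spiral_script")
}

#' Render a spiral script into a phase movie
#'
#' The phase at pixel `z = x + iy` and frame `t` is the wrapped angle of
#' `exp(-i * omega * t) * prod_i (z - z_i(t))^(q_i)` over the defects live at
#' `t`: each factor contributes a unit of winding of sign `q_i` around its
#' defect, and the uniform rotation makes an empty script a spatially uniform
#' rotating phase.
#'
#' @param script a [spiral_script].
#' @param shape `c(H, W)` grid shape, at least 8 x 8.
#' @param n_frames number of frames; defaults to the latest death frame.
#' @param dt_ms frame interval in ms.
#' @param pixel_mm pixel spacing in mm.
#' @return A list with `movie` (a [phase_movie]) and `truth` (the exact
#'   ground-truth [event_table]; onset/offset use the half-open convention,
#'   location is the mean path position).
#' @export
make_spiral_phase_movie <- function(script, shape, n_frames = NULL,
                                    dt_ms = 1, pixel_mm = 1) {
  stopifnot(inherits(script, "spiral_script"))
  if (any(shape < 8L)) stop("shape must be at least 8 x 8")
  H <- shape[1]; W <- shape[2]
  if (is.null(n_frames))
    n_frames <- if (length(script$defects))
      max(vapply(script$defects, `[[`, 1, "death_frame")) else 1L
  for (d in script$defects) {
    if (any(d$path[, 1] <= 0 | d$path[, 1] >= W - 1 |
            d$path[, 2] <= 0 | d$path[, 2] >= H - 1))
      stop("defect path must stay in the grid interior")
  }
  z <- outer(0:(H - 1) * 1i, 0:(W - 1), `+`)   # z = x + i*y, row = y, col = x
  values <- array(0, c(n_frames, H, W))
  for (t in seq_len(n_frames)) {
    field <- matrix(complex(real = cos(-script$omega * t),
                            imaginary = sin(-script$omega * t)), H, W)
    for (d in script$defects) {
      if (t < d$birth_frame || t > d$death_frame) next
      p <- d$path[t - d$birth_frame + 1L, ]
      zd <- z - complex(real = p[1], imaginary = p[2])
      field <- field * (if (d$chirality == 1) zd else Conj(zd))
    }
    values[t, , ] <- atan2(Im(field), Re(field))
  }
  movie <- phase_movie(values, dt_ms = dt_ms, pixel_mm = pixel_mm,
                       metadata = list(source = "spiral_script",
                                       pair_mode = script$pair_mode))
  nd <- length(script$defects)
  truth <- if (nd) {
    event_table(
      id = seq_len(nd), kind = "PS",
      onset_ms = vapply(script$defects, function(d) (d$birth_frame - 1) * dt_ms, 1),
      offset_ms = vapply(script$defects, function(d) d$death_frame * dt_ms, 1),
      x = vapply(script$defects, function(d) mean(d$path[, 1]), 1),
      y = vapply(script$defects, function(d) mean(d$path[, 2]), 1),
      chirality = vapply(script$defects, `[[`, 1, "chirality"),
      censored_left = vapply(script$defects, function(d) d$birth_frame == 1L, TRUE),
      censored_right = vapply(script$defects, function(d) d$death_frame == n_frames, TRUE),
      epoch_ms = n_frames * dt_ms)
  } else event_table(epoch_ms = n_frames * dt_ms)
  list(movie = movie, truth = truth)
}

#' Random spiral scripts for detector exercise
#'
#' Plants `n_defects` defects (or `n_pairs` opposite-chirality pairs when
#' `pair_mode`) at interior positions separated by at least `min_sep` pixels,
#' with slow random drift, random chirality, and random birth/death frames.
#'
#' @param n_frames movie length in frames.
#' @param shape `c(H, W)`.
#' @param n_defects number of defects (ignored in pair mode).
#' @param n_pairs number of +/- pairs when `pair_mode`.
#' @param pair_mode plant charge-conserving pairs with shared birth/death.
#' @param min_sep minimum pairwise separation between planted defects (px).
#' @param margin distance from the boundary kept clear (px).
#' @param drift per-frame RMS drift of each defect (px).
#' @param whole_epoch if `TRUE` all defects live for the whole movie.
#' @param seed optional RNG seed.
#' @return A [spiral_script].
#' @export
random_spiral_script <- function(n_frames, shape, n_defects = 2, n_pairs = 1,
                                 pair_mode = FALSE, min_sep = 8, margin = 4,
                                 drift = 0.05, whole_epoch = TRUE,
                                 seed = NULL) {
  H <- shape[1]; W <- shape[2]
  with_seed(seed, {
    n <- if (pair_mode) 2L * n_pairs else n_defects
    # rejection-sample well-separated anchor positions
    pos <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(pos) < n && tries < 2000L) {
      cand <- c(stats::runif(1, margin, W - 1 - margin),
                stats::runif(1, margin, H - 1 - margin))
      if (!nrow(pos) || min(sqrt(colSums((t(pos) - cand)^2))) >= min_sep)
        pos <- rbind(pos, cand)
      tries <- tries + 1L
    }
    if (nrow(pos) < n) stop("could not place defects with the requested separation")
    lives <- if (whole_epoch) {
      cbind(rep(1L, n), rep(n_frames, n))
    } else {
      b <- sample.int(max(1L, n_frames - 2L), n, replace = TRUE)
      d <- pmin(n_frames, b + sample.int(n_frames, n, replace = TRUE))
      cbind(b, d)
    }
    chir <- if (pair_mode) rep(c(1, -1), n_pairs) else sample(c(-1, 1), n, TRUE)
    if (pair_mode) {                      # pairs share birth and death frames
      for (k in seq_len(n_pairs)) lives[2 * k, ] <- lives[2 * k - 1, ]
    }
    defects <- lapply(seq_len(n), function(i) {
      path <- drift_path(pos[i, ], lives[i, 2] - lives[i, 1] + 1L, drift,
                         margin, shape)
      list(birth_frame = lives[i, 1], death_frame = lives[i, 2],
           path = path, chirality = chir[i])
    })
    spiral_script(defects, pair_mode = pair_mode)
  })
}

#' Couple an M/M/infinity event stream to a planted spiral movie
#'
#' Draws an event stream with [simulate_mminf_events], quantizes each
#' entity's life to frames, places it at a random interior anchor kept
#' `min_sep` pixels from concurrently alive defects, and renders the result
#' with [make_spiral_phase_movie]. This is the fixture coupling the
#' population model to the detector/tracker chain: the planted rates are
#' known, so end-to-end rate recovery can be checked. Entities whose
#' lifetime falls between two frame samples are dropped (they are invisible
#' at the movie's frame rate); at `lambda_d * dt_ms << 1` this thinning is
#' a percent-level effect.
#'
#' @inheritParams simulate_mminf_events
#' @param dt_ms frame interval of the rendered movie.
#' @param shape `c(H, W)` grid.
#' @param min_sep minimum separation from concurrently alive defects (px).
#' @param margin interior margin (px).
#' @param drift per-frame RMS drift (px).
#' @return A list with `movie`, `truth` (frame-quantized ground truth) and
#'   `events` (the underlying continuous-time stream).
#' @export
make_mminf_phase_movie <- function(lambda_f, lambda_d, duration_ms, dt_ms,
                                   shape, min_sep = 8, margin = 4,
                                   drift = 0.05, seed = NULL) {
  events <- simulate_mminf_events(lambda_f, lambda_d, duration_ms, seed = seed)
  n_frames <- floor(duration_ms / dt_ms)
  H <- shape[1]; W <- shape[2]
  sub_seed <- if (is.null(seed)) NULL else seed + 1L
  script <- with_seed(sub_seed, {
    defects <- list()
    if (nrow(events)) {
      # frame k samples time (k-1)*dt; entity visible on frames with
      # onset <= t < offset
      first <- ceiling(events$onset_ms / dt_ms - 1e-9) + 1L
      last <- pmin(n_frames, ceiling(events$offset_ms / dt_ms - 1e-9))
      occupied <- function(frame) {
        keep <- vapply(defects, function(d)
          frame >= d$birth_frame && frame <= d$death_frame, TRUE)
        if (!any(keep)) return(matrix(NA_real_, 0, 2))
        do.call(rbind, lapply(defects[keep], function(d)
          d$path[frame - d$birth_frame + 1L, , drop = FALSE]))
      }
      for (i in seq_len(nrow(events))) {
        if (first[i] > last[i] || first[i] > n_frames) next
        occ <- occupied(first[i])
        anchor <- NULL
        for (try in 1:200) {
          cand <- c(stats::runif(1, margin, W - 1 - margin),
                    stats::runif(1, margin, H - 1 - margin))
          if (!nrow(occ) || min(sqrt(colSums((t(occ) - cand)^2))) >= min_sep) {
            anchor <- cand; break
          }
        }
        if (is.null(anchor)) next        # grid saturated; skip this arrival
        path <- drift_path(anchor, last[i] - first[i] + 1L, drift,
                           margin, shape)
        defects[[length(defects) + 1L]] <-
          list(birth_frame = first[i], death_frame = last[i], path = path,
               chirality = sample(c(-1, 1), 1L))
      }
    }
    spiral_script(defects)
  })
  out <- make_spiral_phase_movie(script, shape, n_frames = n_frames,
                                 dt_ms = dt_ms)
  list(movie = out$movie, truth = out$truth, events = events)
}

# random-walk defect path of a given length clamped to the grid interior
drift_path <- function(anchor, len, drift, margin, shape) {
  H <- shape[1]; W <- shape[2]
  if (len == 1L) {
    path <- matrix(anchor, 1, 2)
  } else {
    steps <- matrix(stats::rnorm(2 * len, 0, drift), ncol = 2)
    steps[1, ] <- 0
    path <- sweep(apply(steps, 2, cumsum), 2, anchor, `+`)
  }
  # clamp strictly inside integer coordinates: a defect sitting exactly on
  # a grid node/edge is topologically ambiguous between adjacent plaquettes
  path[, 1] <- pmin(pmax(path[, 1], margin + 0.1), W - 1.1 - margin)
  path[, 2] <- pmin(pmax(path[, 2], margin + 0.1), H - 1.1 - margin)
  path
}
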