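#' Extract wavefronts as zero-phase isolines
#'
#' Wavefronts are the lines where the phase crosses zero. To avoid the
#' +/- pi branch cut the crossing is taken on the unit phasor: a wavefront
#' passes between two adjacent pixels when `sin(phi)` changes sign there and
#' the local `cos(phi)` is positive (so the crossing is at phi = 0, not at
#' +/- pi). Crossing points on cell edges are joined by marching squares
#' into connected polylines; polyline ends that do not touch the grid
#' boundary are recorded as free ends (where phase singularities sit).
#'
#' @param frame H x W matrix of wrapped phase (radians).
#' @param mask optional logical valid-pixel matrix; cells touching masked
#'   pixels are skipped.
#' @param frame_index frame number stored in the output.
#' @return A list of wavefronts; each is a list with `frame`, `polyline`
#'   (n x 2 matrix of 0-based x, y), and `endpoints` (matrix of free-end
#'   coordinates, possibly 0 rows). Constant non-zero phase yields an empty
#'   list; an identically zero frame is a degenerate isoline and errors.
#' @export
extract_wavefronts <- function(frame, mask = NULL, frame_index = 1L) {
  H <- nrow(frame); W <- ncol(frame)
  if (all(abs(frame) < 1e-12)) stop("degenerate isoline: frame is identically zero")
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  s <- sin(frame); cph <- cos(frame)
  segs <- list(); nseg <- 0L
  key <- function(p) sprintf("%.4f_%.4f", p[1], p[2])
  # crossing point on the edge between grid nodes a and b (0-based x,y)
  cross_on <- function(i1, j1, i2, j2) {
    v1 <- s[i1, j1]; v2 <- s[i2, j2]
    t <- v1 / (v1 - v2)
    c((j1 - 1) + t * (j2 - j1), (i1 - 1) + t * (i2 - i1))
  }
  for (i in seq_len(H - 1)) for (j in seq_len(W - 1)) {
    ii <- c(i, i, i + 1, i + 1); jj <- c(j, j + 1, j + 1, j)
    if (!all(mask[cbind(ii, jj)])) next
    if (!all(cph[cbind(ii, jj)] > 0)) next      # stay off the +/- pi branch
    sv <- s[cbind(ii, jj)]
    if (all(sv > 0) || all(sv < 0) || any(sv == 0)) {
      if (all(sv == 0)) stop("degenerate isoline: flat zero cell")
      if (any(sv == 0)) sv[sv == 0] <- 1e-12    # nudge exact zeros off the node
    }
    # edges: 1: (i,j)-(i,j+1) top, 2: (i,j+1)-(i+1,j+1) right,
    #        3: (i+1,j+1)-(i+1,j) bottom, 4: (i+1,j)-(i,j) left
    pts <- list()
    if (sv[1] * sv[2] < 0) pts <- c(pts, list(cross_on(i, j, i, j + 1)))
    if (sv[2] * sv[3] < 0) pts <- c(pts, list(cross_on(i, j + 1, i + 1, j + 1)))
    if (sv[3] * sv[4] < 0) pts <- c(pts, list(cross_on(i + 1, j + 1, i + 1, j)))
    if (sv[4] * sv[1] < 0) pts <- c(pts, list(cross_on(i + 1, j, i, j)))
    if (length(pts) == 2L) {
      nseg <- nseg + 1L; segs[[nseg]] <- list(pts[[1]], pts[[2]])
    } else if (length(pts) == 4L) {
      # saddle: resolve by the cell-centre sign
      ctr <- mean(sv)
      ord <- if (ctr > 0) list(c(1, 2), c(3, 4)) else list(c(1, 4), c(2, 3))
      for (p in ord) {
        nseg <- nseg + 1L; segs[[nseg]] <- list(pts[[p[1]]], pts[[p[2]]])
      }
    }
  }
  if (!nseg) return(list())
  # stitch segments sharing endpoints into polylines: nodes are crossing
  # points, edges are segments; wavefront lines have node degree <= 2
  node_id <- new.env(parent = emptyenv())
  coords <- list()
  id_of <- function(p) {
    kk <- key(p)
    id <- node_id[[kk]]
    if (is.null(id)) {
      id <- length(coords) + 1L
      coords[[id]] <<- p
      node_id[[kk]] <- id
    }
    id
  }
  edges <- matrix(0L, nseg, 2)
  for (k in seq_len(nseg))
    edges[k, ] <- c(id_of(segs[[k]][[1]]), id_of(segs[[k]][[2]]))
  n_nodes <- length(coords)
  incident <- vector("list", n_nodes)
  for (k in seq_len(nseg)) {
    incident[[edges[k, 1]]] <- c(incident[[edges[k, 1]]], k)
    incident[[edges[k, 2]]] <- c(incident[[edges[k, 2]]], k)
  }
  deg <- lengths(incident)
  edge_used <- logical(nseg)
  fronts <- list()
  trace_from <- function(start) {
    path <- start
    cur <- start
    repeat {
      nxt_e <- incident[[cur]][!edge_used[incident[[cur]]]]
      if (!length(nxt_e)) break
      e <- nxt_e[1]
      edge_used[e] <<- TRUE
      cur <- if (edges[e, 1] == cur) edges[e, 2] else edges[e, 1]
      path <- c(path, cur)
    }
    path
  }
  for (start in order(deg)) {             # open lines (degree-1 ends) first
    if (all(edge_used[incident[[start]]])) next
    path <- trace_from(start)
    if (length(path) < 2L) next
    poly <- do.call(rbind, coords[path])
    ends <- poly[c(1, nrow(poly)), , drop = FALSE]
    closed <- path[1] == path[length(path)]
    on_boundary <- ends[, 1] <= 0.01 | ends[, 1] >= W - 1 - 0.01 |
                   ends[, 2] <= 0.01 | ends[, 2] >= H - 1 - 0.01
    if (closed) on_boundary[] <- TRUE     # loops have no free ends
    fronts[[length(fronts) + 1L]] <-
      list(frame = frame_index, polyline = poly,
           endpoints = ends[!on_boundary, , drop = FALSE])
  }
  fronts
}

#' Extract wavefronts from every frame of a phase movie
#'
#' @param movie a [phase_movie].
#' @return A list (one element per frame) of wavefront lists as returned by
#'   [extract_wavefronts].
#' @export
extract_wavefronts_movie <- function(movie) {
  n <- dim(movie)[1]
  lapply(seq_len(n), function(t)
    extract_wavefronts(movie$values[t, , ], movie$mask, frame_index = t))
}
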