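# Independent brute-force oracles used to check the vectorized detectors.

wrap_pi <- function(d) d - 2 * pi * ceiling((d - pi) / (2 * pi))

# plain-loop winding number of each 2x2 plaquette; returns data frame of
# nonzero-charge plaquettes at plaquette-centre coordinates
oracle_plaquette_ps <- function(frame) {
  H <- nrow(frame); W <- ncol(frame)
  out <- list()
  for (i in seq_len(H - 1)) for (j in seq_len(W - 1)) {
    s <- wrap_pi(frame[i, j + 1] - frame[i, j]) +
         wrap_pi(frame[i + 1, j + 1] - frame[i, j + 1]) +
         wrap_pi(frame[i + 1, j] - frame[i + 1, j + 1]) +
         wrap_pi(frame[i, j] - frame[i + 1, j])
    q <- round(s / (2 * pi))
    if (q != 0) out[[length(out) + 1L]] <-
      data.frame(x = j - 1 + 0.5, y = i - 1 + 0.5, chirality = q)
  }
  if (!length(out)) return(data.frame(x = numeric(), y = numeric(),
                                      chirality = numeric()))
  do.call(rbind, out)
}

# plain-loop winding number around a square ring of radius r centred on
# (i, j); NA if the ring leaves the grid
oracle_ring_winding <- function(frame, i, j, r) {
  H <- nrow(frame); W <- ncol(frame)
  if (i - r < 1 || i + r > H || j - r < 1 || j + r > W) return(NA_real_)
  ring <- list()
  for (dx in r:(-r)) ring <- c(ring, list(c(dx, r)))
  for (dy in (r - 1):(-r)) ring <- c(ring, list(c(-r, dy)))
  for (dx in (-r + 1):r) ring <- c(ring, list(c(dx, -r)))
  for (dy in (-r + 1):(r - 1)) ring <- c(ring, list(c(r, dy)))
  vals <- vapply(ring, function(o) frame[i + o[2], j + o[1]], 1)
  vals <- c(vals, vals[1])
  round(sum(wrap_pi(diff(vals))) / (2 * pi))
}

# net brute-force interior charge of a frame (sum over plaquettes)
oracle_total_charge <- function(frame) {
  ps <- oracle_plaquette_ps(frame)
  if (!nrow(ps)) 0 else sum(ps$chirality)
}
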