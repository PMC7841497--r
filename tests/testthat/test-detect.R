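test_that("kernel detector equals the brute-force plaquette winding oracle on random planted frames", {
  set.seed(41)
  n_frames <- 100
  for (k in seq_len(n_frames)) {
    nd <- sample(1:3, 1)
    sc <- random_spiral_script(1, c(24, 24), n_defects = nd, min_sep = 7,
                               seed = 1000 + k)
    fr <- make_spiral_phase_movie(sc, c(24, 24), n_frames = 1)$movie$values[1, , ]
    got <- detect_ps_kernel(fr)
    want <- oracle_plaquette_ps(fr)
    got <- got[order(got$y, got$x), ]
    want <- want[order(want$y, want$x), ]
    expect_equal(got$x, want$x)
    expect_equal(got$y, want$y)
    expect_equal(got$chirality, want$chirality)
  }
})

test_that("kernel detector finds planted defects with their planted chirality", {
  for (k in 1:20) {
    nd <- sample(1:3, 1)
    sc <- random_spiral_script(1, c(24, 24), n_defects = nd, min_sep = 8,
                               seed = 2000 + k)
    out <- make_spiral_phase_movie(sc, c(24, 24), n_frames = 1)
    got <- detect_ps_kernel(out$movie$values[1, , ])
    expect_equal(nrow(got), nrow(out$truth))
    for (i in seq_len(nrow(out$truth))) {
      d <- sqrt((got$x - out$truth$x[i])^2 + (got$y - out$truth$y[i])^2)
      j <- which.min(d)
      expect_lt(d[j], 1.5)
      expect_equal(got$chirality[j], out$truth$chirality[i])
    }
  }
})

test_that("double ring detector matches a plain-loop two-ring winding oracle and the kernel method", {
  for (k in 1:30) {
    nd <- sample(1:2, 1)
    sc <- random_spiral_script(1, c(24, 24), n_defects = nd, min_sep = 9,
                               margin = 5, seed = 3000 + k)
    out <- make_spiral_phase_movie(sc, c(24, 24), n_frames = 1)
    fr <- out$movie$values[1, , ]
    ker <- detect_ps_kernel(fr)
    dr <- detect_ps_double_ring(fr)
    expect_equal(nrow(dr), nrow(ker))
    expect_equal(sum(dr$chirality), sum(ker$chirality))
    for (i in seq_len(nrow(dr))) {
      d <- sqrt((ker$x - dr$x[i])^2 + (ker$y - dr$y[i])^2)
      expect_lt(min(d), 1.5)
      # oracle: both rings around the rounded centre must report the charge
      ci <- round(dr$y[i]) + 1L; cj <- round(dr$x[i]) + 1L
      expect_equal(oracle_ring_winding(fr, ci, cj, 1), dr$chirality[i])
      expect_equal(oracle_ring_winding(fr, ci, cj, 2), dr$chirality[i])
    }
  }
})

test_that("constant and fully masked frames yield no detections", {
  fr <- matrix(1.2, 12, 12)
  expect_equal(nrow(detect_ps_kernel(fr)), 0)
  expect_equal(nrow(detect_ps_double_ring(fr)), 0)
  sc <- random_spiral_script(1, c(12, 12), n_defects = 1, seed = 9)
  fr2 <- make_spiral_phase_movie(sc, c(12, 12), n_frames = 1)$movie$values[1, , ]
  none <- matrix(FALSE, 12, 12)
  expect_equal(nrow(detect_ps_kernel(fr2, mask = none)), 0)
  expect_equal(nrow(detect_ps_double_ring(fr2, mask = none)), 0)
})

test_that("a defect within one pixel of the boundary is skipped by the double ring but found by the kernel", {
  sc <- spiral_script(list(list(birth_frame = 1, death_frame = 1,
                                path = matrix(c(1.4, 6.5), 1), chirality = 1)))
  fr <- make_spiral_phase_movie(sc, c(16, 16), n_frames = 1)$movie$values[1, , ]
  expect_equal(nrow(detect_ps_kernel(fr)), 1)
  dr <- detect_ps_double_ring(fr)
  expect_true(nrow(dr) == 0 || all(dr$x >= 2))
})

test_that("opposite-chirality pairs sum to zero charge and charge is conserved across pair_mode frames", {
  for (k in 1:5) {
    sc <- random_spiral_script(10, c(28, 28), n_pairs = 2, pair_mode = TRUE,
                               min_sep = 8, seed = 4000 + k)
    out <- make_spiral_phase_movie(sc, c(28, 28), n_frames = 10)
    charges <- vapply(1:10, function(t)
      oracle_total_charge(out$movie$values[t, , ]), 1)
    expect_true(all(charges == 0))
    det <- detect_ps(out$movie, "kernel")
    by_frame <- tapply(det$chirality, factor(det$frame, levels = 1:10),
                       function(q) sum(q))
    by_frame[is.na(by_frame)] <- 0
    expect_true(all(by_frame == 0))
  }
})
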