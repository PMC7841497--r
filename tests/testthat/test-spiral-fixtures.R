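test_that("an empty script renders a uniform rotating phase with no defects", {
  out <- make_spiral_phase_movie(spiral_script(), c(10, 10), n_frames = 3)
  for (t in 1:3) {
    fr <- out$movie$values[t, , ]
    expect_lt(diff(range(fr)), 1e-12)
    expect_equal(nrow(detect_ps_kernel(fr)), 0)
  }
  expect_equal(nrow(out$truth), 0)
})

test_that("planted winding numbers equal the scripted chirality by the line-integral oracle", {
  sc <- spiral_script(list(
    list(birth_frame = 1, death_frame = 1, path = matrix(c(5.2, 6.7), 1),
         chirality = 1),
    list(birth_frame = 1, death_frame = 1, path = matrix(c(14.6, 13.1), 1),
         chirality = -1)))
  fr <- make_spiral_phase_movie(sc, c(20, 20), n_frames = 1)$movie$values[1, , ]
  expect_equal(oracle_ring_winding(fr, 8, 6, 2), 1)    # around (y=6.7, x=5.2)
  expect_equal(oracle_ring_winding(fr, 14, 15, 2), -1)
  expect_equal(oracle_total_charge(fr), 0)
})

test_that("scripts validate path lengths, chirality, and interior placement", {
  expect_error(spiral_script(list(list(birth_frame = 1, death_frame = 3,
                                       path = matrix(0.5, 1, 2),
                                       chirality = 1))), "one row per")
  expect_error(spiral_script(list(list(birth_frame = 1, death_frame = 1,
                                       path = matrix(0.5, 1, 2),
                                       chirality = 2))), "chirality")
  sc <- spiral_script(list(list(birth_frame = 1, death_frame = 1,
                                path = matrix(c(0, 5), 1), chirality = 1)))
  expect_error(make_spiral_phase_movie(sc, c(12, 12)), "interior")
})

test_that("pair_mode rejects scripts whose net charge varies over time", {
  bad <- list(
    list(birth_frame = 1, death_frame = 3, path = matrix(5, 3, 2), chirality = 1),
    list(birth_frame = 2, death_frame = 3, path = matrix(10, 2, 2), chirality = -1))
  expect_error(spiral_script(bad, pair_mode = TRUE), "constant")
})

test_that("truth tables carry half-open lifetimes and censor flags", {
  sc <- spiral_script(list(list(birth_frame = 3, death_frame = 7,
                                path = matrix(rep(c(8, 9), each = 5), 5),
                                chirality = -1)))
  out <- make_spiral_phase_movie(sc, c(16, 16), n_frames = 10, dt_ms = 2)
  expect_equal(out$truth$onset_ms, 4)         # (3 - 1) * 2
  expect_equal(out$truth$offset_ms, 14)       # 7 * 2 (half-open)
  expect_false(out$truth$censored_left)
  expect_false(out$truth$censored_right)
  expect_equal(attr(out$truth, "epoch_ms"), 20)
})

test_that("the coupled event-stream movie quantizes the planted stream faithfully", {
  out <- make_mminf_phase_movie(0.02, 0.004, 4000, dt_ms = 10,
                                shape = c(40, 40), seed = 8)
  # every truth entity must come from an event alive at its first frame
  expect_gt(nrow(out$truth), 0)
  expect_lte(nrow(out$truth), nrow(out$events))
  # visibility rule: dropped events are exactly those alive at no frame time
  frames <- seq(0, (dim(out$movie)[1] - 1) * 10, by = 10)
  visible <- vapply(seq_len(nrow(out$events)), function(i)
    any(out$events$onset_ms[i] <= frames & frames < out$events$offset_ms[i]),
    TRUE)
  expect_equal(nrow(out$truth), sum(visible))
  # detection on a few frames sees exactly the planted count
  det_counts <- vapply(c(1, 100, 250), function(t)
    nrow(detect_ps_kernel(out$movie$values[t, , ])), 1)
  series <- population_series(out$truth, 10)
  expect_equal(det_counts, as.numeric(series$counts[c(1, 100, 250)]))
})
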