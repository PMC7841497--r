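make_plane_wave_egm <- function(fs = 250, dur_s = 2.4, H = 6, W = 6,
                                f0 = 6) {
  # activation sweeping left to right: channel phase offset proportional to x
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  sig <- matrix(0, H * W, length(t))
  for (ch in seq_len(H * W)) {
    cx <- (ch - 1) %% W
    sig[ch, ] <- sin(2 * pi * f0 * t - 0.5 * cx)
  }
  make_synthetic_egm(sig, fs)
}

make_rotor_egm <- function(fs = 250, dur_s = 2.4, H = 8, W = 8, f0 = 6) {
  # rotating activation: phase offset equals the angle around the grid centre
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  sig <- matrix(0, H * W, length(t))
  for (ch in seq_len(H * W)) {
    cx <- (ch - 1) %% W; cy <- (ch - 1) %/% W
    theta <- atan2(cy - (H - 1) / 2, cx - (W - 1) / 2)
    sig[ch, ] <- sin(2 * pi * f0 * t - theta)
  }
  make_synthetic_egm(sig, fs)
}

test_that("the preprocessing chain maps a plane wave to a defect-free phase movie", {
  egm <- make_plane_wave_egm()
  movie <- egm_to_phase_movie(egm, c(6, 6),
                              config = list(filter = filter_spec(1, 100)))
  expect_s3_class(movie, "phase_movie")
  expect_equal(dim(movie), c(600, 6, 6))
  expect_equal(movie$dt_ms, 4)
  det <- detect_ps(movie, "kernel")
  core <- det[det$frame > 100 & det$frame < 500, ]
  expect_equal(nrow(core), 0)
})

test_that("the chain maps a rotor to a single persistent central phase singularity", {
  egm <- make_rotor_egm()
  movie <- egm_to_phase_movie(egm, c(8, 8),
                              config = list(filter = filter_spec(1, 100)))
  det <- detect_ps(movie, "kernel")
  core <- det[det$frame > 100 & det$frame < 500, ]
  frames <- unique(det$frame[det$frame > 100 & det$frame < 500])
  expect_equal(length(frames), 399)             # one PS in every core frame
  expect_equal(nrow(core), 399)
  expect_lt(max(abs(core$x - 3.5)), 1)
  expect_lt(max(abs(core$y - 3.5)), 1)
  expect_equal(length(unique(core$chirality)), 1)
})

test_that("phasor interpolation to the analysis grid preserves the rotor", {
  egm <- make_rotor_egm(dur_s = 2.2)
  movie <- egm_to_phase_movie(egm, c(8, 8),
                              config = list(filter = filter_spec(1, 100),
                                            interp_shape = c(29, 29)))
  expect_equal(dim(movie)[2:3], c(29, 29))
  expect_equal(movie$pixel_mm, 7 / 28, tolerance = 1e-9)   # extent preserved
  det <- detect_ps_kernel(movie$values[250, , ], movie$mask)
  expect_equal(nrow(det), 1)
  # the 8x8 centre (3.5, 3.5) maps to the 29x29 centre (14, 14)
  expect_lt(abs(det$x - 14), 1.5)
  expect_lt(abs(det$y - 14), 1.5)
})

test_that("dead channels are masked and excessive missing coverage is an error", {
  egm <- make_plane_wave_egm()
  egm$signals[10, ] <- 0
  movie <- egm_to_phase_movie(egm, c(6, 6),
                              config = list(filter = filter_spec(1, 100)))
  expect_false(movie$mask[2, 4])                # channel 10, row-major 6-wide
  expect_equal(sum(!movie$mask), 1)
  egm$signals[1:15, ] <- 0
  expect_error(egm_to_phase_movie(egm, c(6, 6),
                                  config = list(filter = filter_spec(1, 100))),
               "coverage")
})

test_that("the chain is deterministic and grid shape is validated", {
  egm <- make_plane_wave_egm()
  m1 <- egm_to_phase_movie(egm, c(6, 6),
                           config = list(filter = filter_spec(1, 100)))
  m2 <- egm_to_phase_movie(egm, c(6, 6),
                           config = list(filter = filter_spec(1, 100)))
  expect_identical(m1$values, m2$values)
  expect_error(egm_to_phase_movie(egm, c(5, 6)), "channel count")
})

test_that("synthetic electrograms embed the QRS overlay and forbid overlapping templates", {
  fs <- 500; t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  atrial <- rbind(sin(2 * pi * 7 * t))
  egm <- make_synthetic_egm(atrial, fs, r_times_ms = c(300, 900, 1500))
  expect_gt(max(abs(egm$signals - atrial)), 1)  # overlay present
  expect_identical(egm$metadata$atrial[1, ], atrial[1, ])
  expect_error(make_synthetic_egm(atrial, fs, r_times_ms = c(300, 320, 900)),
               "overlap")
})
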