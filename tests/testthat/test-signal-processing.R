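test_that("the zero-phase band-pass passes in-band tones unattenuated and unshifted", {
  fs <- 1000; t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  y <- bandpass_zero_phase(x, fs, filter_spec(1, 100))
  core <- 500:3500                        # away from filtfilt edge transients
  expect_equal(sd(y[core]) / sd(x[core]), 1, tolerance = 5e-3)
  lag <- which.max(ccf(x[core], y[core], lag.max = 20, plot = FALSE)$acf) - 21
  expect_equal(lag, 0)                    # zero phase distortion
})

test_that("out-of-band components are strongly attenuated", {
  fs <- 1000; t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  hum <- sin(2 * pi * 250 * t)
  y <- bandpass_zero_phase(hum, fs, filter_spec(1, 100))
  expect_lt(sd(y[500:3500]) / sd(hum), 0.02)
  expect_error(bandpass_zero_phase(hum, fs, filter_spec(1, 600)), "Nyquist")
})

test_that("dominant_frequency finds the strongest in-band peak", {
  fs <- 500; t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- 2 * sin(2 * pi * 5 * t) + sin(2 * pi * 12 * t)
  df <- dominant_frequency(x, fs)
  expect_equal(df$df_hz, 5, tolerance = 0.26)
  expect_equal(df$period_ms, 1000 / df$df_hz)
  expect_gt(df$power_fraction, 0.5)
  noise <- with_seed(1, rnorm(4 * fs))
  expect_lt(dominant_frequency(noise, fs)$power_fraction, 0.2)
  expect_error(dominant_frequency(x[1:100], fs), "2 s")
  expect_error(dominant_frequency(rep(1, 4 * fs), fs), "constant")
})

test_that("sinusoidal recomposition turns deflection trains into the dominant rhythm", {
  fs <- 1000
  # sharp downstrokes every 100 ms (10 Hz activation train)
  x <- rep(0, 4000)
  x[seq(100, 3900, by = 100)] <- 1
  x <- stats::filter(x, rep(1, 5), sides = 1); x[is.na(x)] <- 0
  x <- -cumsum(diff(c(0, x)) < 0)          # stepwise drops
  y <- sinusoidal_recompose(as.numeric(x), fs, 100)
  expect_equal(dominant_frequency(y, fs)$df_hz, 10, tolerance = 0.26)
  # a pure rise has no negative slope: output identically zero
  expect_equal(max(abs(sinusoidal_recompose(seq(0, 1, length.out = 500),
                                            fs, 100))), 0)
  expect_error(sinusoidal_recompose(1:10, 1000, 1e6), "longer than")
})

test_that("hilbert_phase advances linearly on a pure tone", {
  fs <- 1000; t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  ph <- hilbert_phase(cos(2 * pi * 5 * t))
  core <- 200:1800
  step <- wrap_phase(diff(ph[core]))
  expect_equal(mean(step), 2 * pi * 5 / fs, tolerance = 1e-3)
  expect_lt(sd(step), 1e-3)
  expect_error(hilbert_phase(rep(2, 100)), "constant")
})

test_that("QRS template subtraction recovers the atrial signal under ventricular overlay", {
  fs <- 1000; t <- seq(0, 3.5 - 1 / fs, by = 1 / fs)
  f0 <- 6.1; T0 <- 1000 / f0
  atrial <- sin(2 * pi * f0 * t)
  # R-times step the atrial phase by 1/10 cycle per beat, so the averaged
  # template contains (to first order) no atrial component
  r_times <- round(150 + (0:9) * (2 * T0 + T0 / 10))
  egm <- make_synthetic_egm(rbind(atrial), fs, r_times_ms = r_times)
  corrupted <- cor(egm$signals[1, ], atrial)
  cleaned <- qrs_subtract(egm)
  recovered <- cor(cleaned$signals[1, ], atrial)
  expect_gt(recovered, 0.95)
  expect_gt(recovered, corrupted)
  # too few R-times is an error; none at all is the identity
  expect_error(qrs_subtract(egm, r_times_ms = c(100, 500)), "at least 3")
  egm0 <- egm; egm0$r_times_ms <- NULL
  expect_identical(qrs_subtract(egm0)$signals, egm0$signals)
  # R-times at the record edge are skipped with a warning
  expect_warning(qrs_subtract(egm, r_times_ms = c(10, r_times)), "edge")
})

test_that("gaussian_spatiotemporal_filter smooths white noise and preserves constants", {
  arr <- array(5, c(3, 20, 20))
  sm <- gaussian_spatiotemporal_filter(arr, sigma = 2)
  expect_equal(sm, arr, tolerance = 1e-6)
  noisy <- with_seed(2, array(rnorm(3 * 40 * 40), c(3, 40, 40)))
  sm2 <- gaussian_spatiotemporal_filter(noisy, sigma = 4)
  expect_lt(sd(sm2[1, , ]), 0.2 * sd(noisy[1, , ]))
  expect_error(gaussian_spatiotemporal_filter(noisy, sigma = 0), "positive")
})

test_that("voltage_to_phase_movie masks flat pixels and phases oscillating ones", {
  fs_dt <- 2
  n <- 400; H <- 6; W <- 6
  vol <- array(0, c(n, H, W))
  t <- seq_len(n)
  for (i in 1:H) for (j in 1:W)
    vol[, i, j] <- cos(2 * pi * t / 50 + 0.3 * (i + j))
  vol[, 2, 3] <- 7                         # dead pixel
  movie <- voltage_to_phase_movie(vol, dt_ms = fs_dt)
  expect_false(movie$mask[2, 3])
  expect_true(all(movie$mask[-2, -3]))
  step <- wrap_phase(diff(movie$values[100:300, 4, 4]))
  expect_equal(mean(step), 2 * pi / 50, tolerance = 1e-3)
})
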