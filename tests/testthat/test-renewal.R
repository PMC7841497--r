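test_that("extract_intervals pools onset gaps and excludes right-censored lifetimes", {
  ev <- event_table(id = 1:3, kind = "PS", onset_ms = c(0, 4, 10),
                    offset_ms = c(6, 9, 20), x = 0, y = 0, chirality = 1,
                    censored_left = c(TRUE, FALSE, FALSE),
                    censored_right = c(FALSE, FALSE, TRUE), epoch_ms = 20)
  iv <- extract_intervals(ev)
  expect_equal(iv$interformation$values, c(4, 6))
  expect_equal(iv$lifetime$values, c(6, 5))
  expect_equal(iv$lifetime$n_censored_excluded, 1L)
  expect_error(extract_intervals(ev, "wavelet"), "empty")
})

test_that("fit_exponential is the reciprocal-mean MLE with an exact gamma CI", {
  fit <- fit_exponential(c(2, 2, 2), gof = FALSE)
  expect_equal(fit$lambda_per_ms, 0.5)
  expect_equal(fit$ci95, qgamma(c(0.025, 0.975), shape = 3, rate = 6))
  expect_identical(fit$ci_method, "exact_gamma")
  expect_error(fit_exponential(numeric()), "at least 2")
  expect_error(fit_exponential(5), "at least 2")
})

test_that("the MLE recovers a planted rate and its CI has near-nominal coverage", {
  lambda <- 0.04
  hits <- 0L
  for (s in 1:100) {
    x <- with_seed(s, rexp(80, lambda))
    fit <- fit_exponential(x, gof = FALSE)
    if (fit$ci95[1] <= lambda && lambda <= fit$ci95[2]) hits <- hits + 1L
  }
  expect_gte(hits, 90)   # nominal 95, binomial noise allows a few misses
})

test_that("large samples switch to the normal CI and stay close to the gamma one", {
  x <- with_seed(1, rexp(600, 0.1))
  fit <- fit_exponential(x, gof = FALSE)
  expect_identical(fit$ci_method, "normal_approx")
  exact <- qgamma(c(0.025, 0.975), shape = 600, rate = sum(x))
  expect_equal(fit$ci95, exact, tolerance = 5e-3)
})

test_that("chi2_gof is calibrated under the null and powerful against a uniform", {
  p_null <- vapply(1:100, function(s) {
    x <- with_seed(s, rexp(200, 0.2))
    chi2_gof(x, fit_exponential(x, gof = FALSE))$p
  }, 1)
  expect_lt(mean(p_null < 0.05), 0.12)           # near-nominal size
  expect_gt(mean(p_null > 0.5), 0.3)             # p roughly uniform
  p_alt <- vapply(1:20, function(s) {
    x <- with_seed(1000 + s, runif(200, 0, 10))  # same mean, wrong shape
    chi2_gof(x, fit_exponential(x, gof = FALSE))$p
  }, 1)
  expect_gt(mean(p_alt < 0.01), 0.9)
  expect_error(chi2_gof(rexp(10), 0.5), "at least 20")
})

test_that("stationarity_check passes an iid exponential stream and flags a rate switch", {
  ev <- simulate_mminf_events(0.1, 0.02, 5e4, seed = 4)
  st <- stationarity_check(ev, seed = 1)
  expect_false(st$degenerate)
  expect_true(st$stationary)
  expect_lte(st$max_abs_z, 3)
  # rate switch: first half 0.02/ms arrivals, second half 0.4/ms
  o1 <- with_seed(2, cumsum(rexp(400, 0.02)))
  o1 <- o1[o1 < 2e4]
  o2 <- 2e4 + with_seed(3, cumsum(rexp(8000, 0.4)))
  o2 <- o2[o2 < 4e4]
  on <- c(o1, o2)
  ev2 <- event_table(id = seq_along(on), kind = "PS", onset_ms = on,
                     offset_ms = on + 1, x = 0, y = 0, chirality = 1,
                     censored_left = FALSE, censored_right = FALSE,
                     epoch_ms = 4e4)
  st2 <- stationarity_check(ev2, seed = 1)
  expect_false(st2$stationary)
})

test_that("stationarity_check reports degenerate constant-interval streams", {
  on <- seq(0, 990, by = 10)
  ev <- event_table(id = seq_along(on), kind = "PS", onset_ms = on,
                    offset_ms = on + 5, x = 0, y = 0, chirality = 1,
                    censored_left = FALSE, censored_right = FALSE,
                    epoch_ms = 1000)
  st <- stationarity_check(ev)
  expect_true(st$degenerate)
  expect_true(is.na(st$stationary))
})
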