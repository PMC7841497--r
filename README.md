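# fibrenew

Renewal-theory analysis of rotor and wavelet population dynamics in
atrial fibrillation (AF).

During AF, phase singularities (PS — the pivots of re-entrant rotors) and
wavefronts continually form and are destroyed. fibrenew models this
turnover as an M/M/∞ birth–death process: formations arrive as a Poisson
process with rate λf (per ms) and each entity lives an independent
exponential time with destruction rate λd (per ms). Two consequences
carry the whole analysis:

* **Eq. 1 (mean):** the steady-state mean concurrent count is
  `N = λf / λd`.
* **Eq. 2 (distribution):** the concurrent count is Poisson with mean
  `ρ = λf / λd`: `P(n) = ρⁿ e^(−ρ) / n!`.

The package provides the complete chain from raw signals to these
population statistics:

| Stage | Functions |
|---|---|
| Synthetic data (event streams, planted spiral movies, excitable medium, electrograms) | `simulate_mminf_events`, `make_spiral_phase_movie`, `make_mminf_phase_movie`, `simulate_excitable_tissue`, `make_synthetic_egm` |
| Signal processing (QRS subtraction, zero-phase band-pass, dominant frequency, sinusoidal recomposition, Hilbert phase, Gaussian smoothing) | `qrs_subtract`, `bandpass_zero_phase`, `dominant_frequency`, `sinusoidal_recompose`, `hilbert_phase`, `egm_to_phase_movie` |
| Phase mapping (PS detection, wavefront isolines, tracking) | `detect_ps`, `detect_ps_kernel`, `detect_ps_double_ring`, `extract_wavefronts`, `track_entities` |
| Renewal statistics (rate MLE, CIs, χ² GOF, stationarity) | `extract_intervals`, `fit_exponential`, `chi2_gof`, `stationarity_check` |
| M/M/∞ model and spectra (predictions, count comparison, birth–death matrix, SLEM / mixing rate) | `predict_mean`, `predict_pmf`, `compare_to_observed`, `estimate_bd_matrix`, `analytic_generator` |
| Pipeline and cohorts | `run_epoch`, `run_scale_study`, `run_group_contrast`, `termination_contrast`, CLI `exec/fibrenew` |

## Worked example

Predict, simulate, and recover the worked-example PS rates
(λf = 0.27/ms, λd = 0.05/ms):

```r
library(fibrenew)

predict_mean(0.27, 0.05)
#> [1] 5.4

ev <- simulate_mminf_events(0.27, 0.05, 1e5, seed = 1)
report <- run_epoch(analysis_config(events = ev, dt_ms = 1,
                                    compare_every = 100, seed = 1))
report
#> epoch_report (PS): lambda_f = 0.269 /ms, lambda_d = 0.04999 /ms
#>   predicted mean N = 5.380, observed mean = 5.379
#>   SLEM = 0.9506, spectral gap (mixing rate) = 0.0494
```

The same analysis end to end from a phase movie with planted ground
truth — render an event stream as drifting spiral defects, detect,
track, and fit:

```r
out <- make_mminf_phase_movie(0.02, 0.004, 1e4, dt_ms = 10,
                              shape = c(48, 48), seed = 11)
out$movie
#> phase_movie: 1000 frames of 48 x 48, dt = 10 ms, pixel = 1 mm (0 masked px)

det <- detect_ps(out$movie, "kernel")
tracked <- track_entities(det, track_config(r = 4, r_unit = "px",
                                            tau_ms = 10),
                          dt_ms = 10, n_frames = 1000)
tracked
#> event_table: 188 entities (PS), epoch 10000 ms
#>   id kind onset_ms offset_ms    x        y chirality censored_left censored_right
#> 1  1   PS      140       490  6.5 35.64286        -1         FALSE          FALSE
#> ...

fit_exponential(extract_intervals(tracked)$lifetime)
#> rate_fit: lambda = 0.004226 /ms (95% CI 0.0036374-0.0048581, exact_gamma),
#>   n = 184; exponential GOF chi2 = 11.7, p = 0.768
```

The planted λd = 0.004/ms is recovered within its confidence interval
and the lifetimes pass the exponential goodness of fit.

See the methods vignette
(`vignettes/population-renewal-methods.Rmd`) for the model assumptions,
the signal chain, parameter conventions (τ, r, Δt bounds, censoring), and
the cohort-contrast design.

## License

MIT (see `LICENSE`).
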