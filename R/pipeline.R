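#' Epoch analysis configuration
#'
#' Bundles every tunable of the epoch pipeline. Defaults follow the primary
#' clinical analysis settings: tau = 10 ms, r = 4 mm, detection by the
#' convolutional kernel method.
#'
#' @param movie a [phase_movie], or a path to an NPY phase movie; exactly
#'   one of `movie` / `events` must be given.
#' @param events an [event_table] (or CSV path) when detection/tracking has
#'   already been done or events are simulated directly.
#' @param egm optionally, an [egm_set] plus `grid_shape` to run the
#'   preprocessing chain first.
#' @param grid_shape electrode layout for `egm` input.
#' @param method PS detection method, `"kernel"` or `"double_ring"`.
#' @param track a [track_config].
#' @param kind entity kind analyzed.
#' @param dt_ms running-count interval; defaults to the movie's frame
#'   interval.
#' @param compare_every thinning stride for the distribution comparison.
#' @param min_lifetime_ms optional extra filter keeping only long-lasting
#'   entities (e.g. 150 ms for stable re-entry); `NULL` disables.
#' @param preprocess config list passed to [egm_to_phase_movie].
#' @param seed RNG seed echoed into the report.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(movie = NULL, events = NULL, egm = NULL,
                            grid_shape = NULL,
                            method = c("kernel", "double_ring"),
                            track = track_config(), kind = "PS",
                            dt_ms = NULL, compare_every = 1L,
                            min_lifetime_ms = NULL,
                            preprocess = list(), seed = NULL) {
  method <- match.arg(method)
  if (is.null(movie) && is.null(events) && is.null(egm))
    stop("one of movie, events, egm must be supplied")
  structure(list(movie = movie, events = events, egm = egm,
                 grid_shape = grid_shape, method = method, track = track,
                 kind = kind, dt_ms = dt_ms, compare_every = compare_every,
                 min_lifetime_ms = min_lifetime_ms,
                 preprocess = preprocess, seed = seed),
            class = "analysis_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full epoch analysis
#'
#' preprocess (if electrograms) -> detect -> track -> interval extraction ->
#' exponential rate fits -> M/M/infinity prediction -> observed-vs-predicted
#' comparison -> birth-death spectrum -> stationarity diagnostics. Failures
#' carry the stage name. Deterministic given the config (and its seed).
#'
#' @param config an [analysis_config].
#' @return A list of class `epoch_report` with `fits` (`lambda_f`,
#'   `lambda_d` [rate_fit]s), `prediction`, `observed` (mean and histogram
#'   comparison), `spectrum`, `stationarity`, `events`, `config_echo`, and
#'   `version`.
#' @export
run_epoch <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  movie <- config$movie
  if (!is.null(config$egm))
    movie <- stage("preprocess",
                   egm_to_phase_movie(config$egm, config$grid_shape,
                                      config$preprocess))
  if (is.character(movie)) movie <- stage("load", read_phase_movie_npy(movie))
  events <- config$events
  if (is.character(events)) events <- stage("load", read_event_table(events))
  if (is.null(events)) {
    det <- stage("detect", detect_ps(movie, config$method))
    events <- stage("track",
                    track_entities(det, config$track, dt_ms = movie$dt_ms,
                                   n_frames = dim(movie)[1],
                                   pixel_mm = movie$pixel_mm))
  }
  if (!is.null(config$min_lifetime_ms))
    events <- events[events$offset_ms - events$onset_ms >
                       config$min_lifetime_ms, , drop = FALSE]
  dt_ms <- config$dt_ms
  if (is.null(dt_ms)) dt_ms <- if (!is.null(movie)) movie$dt_ms else 1
  iv <- stage("fit", extract_intervals(events, config$kind))
  fit_f <- stage("fit", fit_exponential(iv$interformation))
  fit_d <- stage("fit", fit_exponential(iv$lifetime))
  pred <- stage("predict",
                predict_pmf(fit_f$lambda_per_ms, fit_d$lambda_per_ms))
  series <- stage("compare", population_series(events, dt_ms, kind = config$kind))
  comparison <- stage("compare", tryCatch(
    compare_to_observed(pred, series, every = config$compare_every),
    error = function(e) list(error = conditionMessage(e))))
  spectrum <- stage("spectral", estimate_bd_matrix(series))
  stat <- tryCatch(
    stationarity_check(events, config$kind, seed = config$seed),
    error = function(e) list(error = conditionMessage(e)))
  structure(list(
    fits = list(lambda_f = fit_f, lambda_d = fit_d,
                n_censored_excluded = iv$lifetime$n_censored_excluded),
    prediction = pred,
    observed = c(list(mean_count = mean(series$counts)), comparison),
    spectrum = spectrum,
    stationarity = stat,
    events = events,
    series = series,
    config_echo = config_echo(config),
    version = as.character(utils::packageVersion("fibrenew"))),
    class = "epoch_report")
}

config_echo <- function(config) {
  list(method = config$method, track = unclass(config$track),
       kind = config$kind, dt_ms = config$dt_ms,
       compare_every = config$compare_every,
       min_lifetime_ms = config$min_lifetime_ms,
       preprocess = config$preprocess, seed = config$seed)
}

#' @export
print.epoch_report <- function(x, ...) {
  cat(sprintf(paste0(
    "epoch_report (%s): lambda_f = %.4g /ms, lambda_d = %.4g /ms\n",
    "  predicted mean N = %.3f, observed mean = %.3f\n",
    "  SLEM = %.4f, spectral gap (mixing rate) = %.4f\n"),
    x$config_echo$kind,
    x$fits$lambda_f$lambda_per_ms, x$fits$lambda_d$lambda_per_ms,
    x$prediction$mean_n, x$observed$mean_count,
    x$spectrum$slem, x$spectrum$spectral_gap))
  invisible(x)
}

#' Scale study: epoch analyses across fields of view or densities
#'
#' Re-analyzes one movie at several crops (`windows`) and/or decimation
#' densities (`keep_shapes`), reporting per-scale mean counts and rate
#' estimates; the exponential GOF at each scale checks that the renewal
#' structure survives coarse-graining.
#'
#' @param config an [analysis_config] with a movie.
#' @param keep_shapes list of `c(h, w)` decimation shapes (optional).
#' @param windows list of crop windows `c(row0, row1, col0, col1)`
#'   (optional). At least 2 scales in total are required.
#' @return A list with `reports` (one [run_epoch] result per scale) and
#'   `summary` (a data frame of scale, mean count, rates, GOF p).
#' @export
run_scale_study <- function(config, keep_shapes = NULL, windows = NULL) {
  movie <- config$movie
  if (is.character(movie)) movie <- read_phase_movie_npy(movie)
  if (is.null(movie)) stop("scale study needs a movie input")
  scales <- c(
    lapply(keep_shapes %||% list(), function(k) list(type = "decimate", value = k)),
    lapply(windows %||% list(), function(w) list(type = "crop", value = w)))
  if (length(scales) < 2L) stop("need at least 2 scales")
  reports <- lapply(scales, function(s) {
    m <- if (s$type == "decimate") decimate_and_interpolate(movie, s$value)
         else crop_field(movie, s$value)
    cfg <- config; cfg$movie <- m; cfg$egm <- NULL
    run_epoch(cfg)
  })
  summary <- do.call(rbind, Map(function(s, r) data.frame(
    type = s$type, scale = paste(s$value, collapse = "x"),
    mean_count = r$observed$mean_count,
    lambda_f = r$fits$lambda_f$lambda_per_ms,
    lambda_d = r$fits$lambda_d$lambda_per_ms,
    gof_p_interformation = r$fits$lambda_f$chi2_p,
    gof_p_lifetime = r$fits$lambda_d$chi2_p,
    stringsAsFactors = FALSE), scales, reports))
  list(reports = reports, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group contrast: sustained versus terminating cohorts
#'
#' Runs [run_epoch] on every config and hands the per-epoch metrics to
#' [termination_contrast].
#'
#' @param configs_a,configs_b lists of [analysis_config]s (>= 2 each).
#' @param labels group names.
#' @return A list with `reports_a`, `reports_b`, and `contrast` (the metric
#'   table from [termination_contrast]).
#' @export
run_group_contrast <- function(configs_a, configs_b,
                               labels = c("sustained", "terminating")) {
  if (length(configs_a) < 2L || length(configs_b) < 2L)
    stop("need at least 2 epochs per group")
  run_all <- function(cfgs) lapply(cfgs, run_epoch)
  ra <- run_all(configs_a); rb <- run_all(configs_b)
  metrics <- function(r) list(
    lambda_f = r$fits$lambda_f$lambda_per_ms,
    lambda_d = r$fits$lambda_d$lambda_per_ms,
    slem = r$spectrum$slem, spectral_gap = r$spectrum$spectral_gap,
    mixing_rate = r$spectrum$mixing_rate,
    mean_count = r$observed$mean_count)
  list(reports_a = ra, reports_b = rb,
       contrast = termination_contrast(lapply(ra, metrics),
                                       lapply(rb, metrics), labels))
}

#' Serialize an epoch report to JSON
#'
#' Writes the numeric content of a report (fits, prediction, comparison,
#' spectrum, config echo) losslessly; the event table itself is written
#' separately with [write_event_table].
#'
#' @param report an `epoch_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_epoch_report <- function(report, path) {
  x <- list(
    lambda_f = report$fits$lambda_f[c("lambda_per_ms", "ci95", "n",
                                      "chi2_stat", "chi2_p")],
    lambda_d = report$fits$lambda_d[c("lambda_per_ms", "ci95", "n",
                                      "chi2_stat", "chi2_p")],
    n_censored_excluded = report$fits$n_censored_excluded,
    prediction = list(rho = report$prediction$rho,
                      mean_n = report$prediction$mean_n,
                      pmf = report$prediction$pmf),
    observed = report$observed,
    spectrum = report$spectrum[c("states", "slem", "spectral_gap",
                                 "mixing_rate", "dt_ms", "eigen_moduli")],
    config = report$config_echo,
    version = report$version)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
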