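# Pure-tone audiometry simulation: a modified Hughson-Westlake staircase
# (down 10 dB after a response, up 5 dB after a miss, threshold = lowest
# level with >= 2 responses out of up to 3 ascending presentations) run
# against a probabilistic listener model, for a clinical and an app-based
# remote paradigm that differ in response latency. Latency converts to a
# level bias through the presentation sweep rate: the effective level at
# the moment the response registers is `presented - latency * sweep_rate`,
# so a slower paradigm measures systematically higher thresholds.

#' Default audiometric test frequencies
#'
#' The five frequencies measured by both paradigms: 500, 1000, 2000, 4000
#' and 6000 Hz.
#'
#' @return Integer vector of frequencies in Hz.
#' @export
audiometry_frequencies <- function() {
  c(500L, 1000L, 2000L, 4000L, 6000L)
}

#' Construct a simulated listener
#'
#' @param true_thresholds Named numeric vector, frequency (Hz, as name) to
#'   true threshold in dB HL.
#' @param psychometric_slope Spread (dB) of the probit response function
#'   around threshold; 0 gives a deterministic step listener.
#' @param lapse_rate Probability of missing a clearly audible tone; in
#'   [0, 0.1].
#' @param response_latency Named numeric vector `c(clinical = , remote_app
#'   = )`, seconds.
#' @return A `sim_listener`.
#' @export
sim_listener <- function(true_thresholds,
                         psychometric_slope = 3,
                         lapse_rate = 0.02,
                         response_latency = c(clinical = 0.2,
                                              remote_app = 0.2)) {
  stopifnot(all(is.finite(true_thresholds)), psychometric_slope >= 0,
            lapse_rate >= 0, lapse_rate <= 0.1,
            all(response_latency >= 0),
            all(c("clinical", "remote_app") %in% names(response_latency)))
  structure(list(true_thresholds = true_thresholds,
                 psychometric_slope = psychometric_slope,
                 lapse_rate = lapse_rate,
                 response_latency = response_latency),
            class = "sim_listener")
}

#' Draw a random normal-hearing cohort
#'
#' Per-frequency true thresholds from N(`mean_db`, `sd_db`), clipped to
#' [-10, 40] dB HL; continuous values (the 5-dB grid is a property of the
#' measurement, not of the listener).
#'
#' @param n Number of listeners.
#' @param frequencies Test frequencies.
#' @param mean_db,sd_db Cohort threshold distribution. Defaults 5 and 6 dB.
#' @param latency_clinical,latency_remote Response latencies (s).
#' @param psychometric_slope,lapse_rate Listener model parameters.
#' @param seed Integer seed.
#' @return List of `sim_listener`.
#' @export
sample_cohort <- function(n, frequencies = audiometry_frequencies(),
                          mean_db = 5, sd_db = 6,
                          latency_clinical = 0.2, latency_remote = 0.2,
                          psychometric_slope = 3, lapse_rate = 0.02,
                          seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      th <- pmin(pmax(stats::rnorm(length(frequencies), mean_db, sd_db),
                      -10), 40)
      names(th) <- frequencies
      sim_listener(th, psychometric_slope, lapse_rate,
                   c(clinical = latency_clinical,
                     remote_app = latency_remote))
    })
  })
}

# one Bernoulli response of the listener at a presented level
respond <- function(listener, freq, level, paradigm, sweep_rate) {
  theta <- listener$true_thresholds[[as.character(freq)]]
  eff <- level - listener$response_latency[[paradigm]] * sweep_rate
  p_hear <- if (listener$psychometric_slope == 0) {
    as.numeric(eff >= theta)
  } else {
    stats::pnorm((eff - theta) / listener$psychometric_slope)
  }
  stats::runif(1) < (1 - listener$lapse_rate) * p_hear
}

# modified Hughson-Westlake staircase at one frequency; levels stay on the
# 5-dB grid by construction
staircase <- function(listener, freq, paradigm, sweep_rate,
                      start_level = 40, min_level = -10, max_level = 110,
                      max_trials = 60L) {
  level <- start_level
  ascent_hits <- list()
  ascending <- FALSE
  floor_hits <- 0L
  ceil_misses <- 0L
  for (trial in seq_len(max_trials)) {
    r <- respond(listener, freq, level, paradigm, sweep_rate)
    if (r) {
      if (level <= min_level) {
        floor_hits <- floor_hits + 1L
        if (floor_hits >= 2L) return(min_level)
      }
      if (ascending) {
        key <- as.character(level)
        ascent_hits[[key]] <- (ascent_hits[[key]] %||% 0L) + 1L
        if (ascent_hits[[key]] >= 2L) return(level)
      }
      level <- max(level - 10, min_level)
      ascending <- FALSE
    } else {
      if (level >= max_level) {
        ceil_misses <- ceil_misses + 1L
        if (ceil_misses >= 3L) return(NA_real_)   # unmeasurable
      }
      level <- min(level + 5, max_level)
      ascending <- TRUE
    }
  }
  NA_real_
}

#' Measure one audiogram under one paradigm
#'
#' Runs the staircase at every test frequency against the listener's
#' response model. The paradigm's response latency biases the effective
#' level by `latency * sweep_rate` dB. Results lie on the 5-dB grid;
#' frequencies where the staircase hits the level ceiling repeatedly are
#' flagged `NA` (unmeasurable).
#'
#' @param listener A [sim_listener()].
#' @param paradigm `"clinical"` or `"remote_app"`.
#' @param frequencies Test frequencies; default the standard five.
#' @param seed Integer seed.
#' @param sweep_rate Level sweep rate (dB/s) converting latency to a level
#'   bias. Default 10.
#' @return An `audiogram_result`: list with `paradigm`, `thresholds`
#'   (named numeric, 5-dB grid), `frequencies`.
#' @export
measure_audiogram <- function(listener, paradigm = c("clinical", "remote_app"),
                              frequencies = audiometry_frequencies(),
                              seed = 1L, sweep_rate = 10) {
  stopifnot(inherits(listener, "sim_listener"), length(frequencies) > 0)
  paradigm <- match.arg(paradigm)
  with_seed(seed, {
    th <- vapply(frequencies, function(f)
      staircase(listener, f, paradigm, sweep_rate), numeric(1))
    names(th) <- frequencies
    structure(list(paradigm = paradigm, thresholds = th,
                   frequencies = frequencies),
              class = "audiogram_result")
  })
}

#' Compare clinical and remote measurement paradigms on a simulated cohort
#'
#' Each listener is measured `n_repetitions` times under both paradigms;
#' differences are computed as clinical - remote per frequency and
#' repetition, and summarised per frequency by median, 25/75 percentiles,
#' extremes and outliers beyond 1.5 IQR (the box-plot convention).
#'
#' @param n_listeners Cohort size (>= 1).
#' @param n_repetitions Repetitions per paradigm per listener. Default 3.
#' @param latency_clinical,latency_remote Response latencies (s).
#' @param seed Integer seed.
#' @param frequencies Test frequencies.
#' @param sweep_rate dB/s; see [measure_audiogram()].
#' @param cohort Optional pre-built list of `sim_listener` (overrides
#'   `n_listeners` and the latency arguments are then taken from the
#'   listeners).
#' @return A `paradigm_comparison`: list with `differences` (data.frame
#'   `listener,frequency_hz,repetition,clinical_db,remote_db,
#'   difference_db`) and `summary` (data.frame per frequency with
#'   `median, q25, q75, min, max, n, n_outliers`).
#' @export
compare_paradigms <- function(n_listeners, n_repetitions = 3L,
                              latency_clinical = 0.2, latency_remote = 0.2,
                              seed = 1L,
                              frequencies = audiometry_frequencies(),
                              sweep_rate = 10, cohort = NULL) {
  stopifnot(n_listeners >= 1, n_repetitions >= 1)
  if (is.null(cohort))
    cohort <- sample_cohort(n_listeners, frequencies,
                            latency_clinical = latency_clinical,
                            latency_remote = latency_remote,
                            seed = derive_seed(seed, 1L))
  rows <- vector("list", length(cohort) * n_repetitions)
  k <- 0L
  for (i in seq_along(cohort)) {
    for (rep in seq_len(n_repetitions)) {
      cl <- measure_audiogram(cohort[[i]], "clinical", frequencies,
                              seed = derive_seed(seed, 17L + 4L * (i * 100L + rep)),
                              sweep_rate = sweep_rate)
      rm_ <- measure_audiogram(cohort[[i]], "remote_app", frequencies,
                               seed = derive_seed(seed, 19L + 4L * (i * 100L + rep)),
                               sweep_rate = sweep_rate)
      k <- k + 1L
      rows[[k]] <- data.frame(
        listener = i, frequency_hz = frequencies, repetition = rep,
        clinical_db = unname(cl$thresholds),
        remote_db = unname(rm_$thresholds),
        difference_db = unname(cl$thresholds - rm_$thresholds)
      )
    }
  }
  diffs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(diffs, diffs$frequency_hz), function(d) {
    x <- d$difference_db[is.finite(d$difference_db)]
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    data.frame(frequency_hz = d$frequency_hz[1],
               median = stats::median(x), q25 = q[1], q75 = q[2],
               min = min(x), max = max(x), n = length(x),
               n_outliers = sum(x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr))
  }))
  rownames(summ) <- NULL
  summ <- summ[order(summ$frequency_hz), ]
  structure(list(differences = diffs, summary = summ,
                 n_listeners = length(cohort),
                 n_repetitions = n_repetitions),
            class = "paradigm_comparison")
}

#' @export
print.paradigm_comparison <- function(x, ...) {
  cat(sprintf(
    "Paradigm comparison: %d listeners x %d repetitions (clinical - remote, dB)\n",
    x$n_listeners, x$n_repetitions))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write paradigm-comparison results to CSV and JSON
#'
#' The long table goes to `<path>.csv`
#' (`listener_id,frequency_hz,paradigm,repetition,threshold_db`), the
#' per-frequency summary to `<path>.json`.
#'
#' @param cmp A `paradigm_comparison`.
#' @param path Output path stem.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(cmp, path) {
  stopifnot(inherits(cmp, "paradigm_comparison"))
  d <- cmp$differences
  long <- rbind(
    data.frame(listener_id = d$listener, frequency_hz = d$frequency_hz,
               paradigm = "clinical", repetition = d$repetition,
               threshold_db = d$clinical_db),
    data.frame(listener_id = d$listener, frequency_hz = d$frequency_hz,
               paradigm = "remote_app", repetition = d$repetition,
               threshold_db = d$remote_db)
  )
  utils::write.csv(long, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(cmp$summary, paste0(path, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
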