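det_listener <- function(theta, latency = c(clinical = 0, remote_app = 0)) {
  th <- rep(theta, 5)
  names(th) <- audiometry_frequencies()
  sim_listener(th, psychometric_slope = 0, lapse_rate = 0,
               response_latency = latency)
}

test_that("a deterministic listener measures ceil(threshold / 5) * 5", {
  for (theta in c(-3, 0, 12, 27.5, 40, 43, 45)) {
    res <- measure_audiogram(det_listener(theta), "clinical", seed = 1)
    expect_equal(unname(res$thresholds),
                 rep(5 * ceiling(theta / 5), 5),
                 info = paste("theta =", theta))
  }
})

test_that("five standard frequencies are measured on the 5-dB grid", {
  expect_equal(audiometry_frequencies(), c(500L, 1000L, 2000L, 4000L, 6000L))
  cohort <- sample_cohort(5, seed = 8)
  for (i in seq_along(cohort)) {
    res <- measure_audiogram(cohort[[i]], "remote_app", seed = 100 + i)
    expect_length(res$thresholds, 5)
    ok <- is.finite(res$thresholds)
    expect_true(all(res$thresholds[ok] %% 5 == 0))
  }
  # same listener, same seed: identical measurement
  r1 <- measure_audiogram(cohort[[1]], "clinical", seed = 42)
  r2 <- measure_audiogram(cohort[[1]], "clinical", seed = 42)
  expect_identical(r1$thresholds, r2$thresholds)
})

test_that("latency shifts the measured threshold by latency * sweep_rate", {
  # deterministic listener at 20 dB: 1 s latency at 10 dB/s biases the
  # effective level 10 dB down, so the staircase settles 10 dB higher
  slow <- det_listener(20, latency = c(clinical = 0, remote_app = 1))
  res_r <- measure_audiogram(slow, "remote_app", seed = 3, sweep_rate = 10)
  res_c <- measure_audiogram(slow, "clinical", seed = 3, sweep_rate = 10)
  expect_equal(unname(res_r$thresholds - res_c$thresholds), rep(10, 5))
})

test_that("the paradigm comparison produces the full difference sample", {
  cmp <- compare_paradigms(18, 3, seed = 6)
  expect_equal(nrow(cmp$differences), 18 * 3 * 5)
  expect_equal(unique(cmp$summary$n), 54)
  expect_true(all(cmp$differences$difference_db %% 5 == 0))
  expect_equal(cmp$summary$frequency_hz, c(500, 1000, 2000, 4000, 6000))
})

test_that("equal latencies give a centred difference distribution", {
  cmp <- compare_paradigms(50, 3, latency_clinical = 0.2,
                           latency_remote = 0.2, seed = 9)
  expect_true(all(abs(cmp$summary$median) <= 5))
})

test_that("a 5-dB latency-equivalent offset is recovered in the median", {
  cmp <- compare_paradigms(50, 3, latency_clinical = 0.2,
                           latency_remote = 0.7, seed = 9, sweep_rate = 10)
  expect_equal(cmp$summary$median, rep(-5, 5))
})

test_that("test-retest spread on one listener is about one grid step", {
  cohort <- sample_cohort(1, seed = 12)
  th <- replicate(12, {
    s <- sample.int(1e6, 1)
    unname(measure_audiogram(cohort[[1]], "clinical", seed = s)$thresholds)
  })
  spread <- apply(th, 1, stats::sd)
  expect_true(all(spread <= 10))
})

test_that("comparison results round-trip through CSV and JSON", {
  cmp <- compare_paradigms(4, 2, seed = 3)
  stem <- tempfile()
  write_comparison(cmp, stem)
  long <- utils::read.csv(paste0(stem, ".csv"))
  expect_named(long, c("listener_id", "frequency_hz", "paradigm",
                       "repetition", "threshold_db"))
  expect_equal(nrow(long), 2 * nrow(cmp$differences))
  summ <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(summ$median, cmp$summary$median)
})

test_that("listener invariants are enforced", {
  th <- c("500" = 10)
  expect_error(sim_listener(th, lapse_rate = 0.5), "lapse")
  expect_error(sim_listener(c("500" = NA)), "finite")
})
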