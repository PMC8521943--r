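test_that("the taxonomy has 14 scenes spanning all three groups", {
  tax <- default_taxonomy()
  expect_length(tax, 14)
  names_ <- vapply(tax, `[[`, character(1), "name")
  groups <- vapply(tax, `[[`, character(1), "group")
  expect_setequal(unique(groups),
                  c("speech", "background", "speech_in_background"))
  expect_true(all(c("cocktail_party", "interfering_speakers",
                    "speech_in_traffic", "speech_in_vehicle",
                    "in_vehicle", "reverberant_environment") %in% names_))
  # every mixed scene carries a finite SNR
  for (spec in tax[groups == "speech_in_background"])
    expect_true(is.finite(spec$params$snr_db))
})

test_that("generation is deterministic in (spec, seed) and varies across seeds", {
  spec <- default_taxonomy()[[3]]
  a <- generate_scene(spec, 11, duration = 1)
  b <- generate_scene(spec, 11, duration = 1)
  c <- generate_scene(spec, 12, duration = 1)
  expect_identical(a$audio, b$audio)
  expect_false(identical(a$audio, c$audio))
})

test_that("records have exact duration and no clipping", {
  tax <- default_taxonomy()
  for (spec in tax[c(1, 4, 9, 14)]) {
    r <- generate_scene(spec, 5, duration = 1.5, sample_rate = 8000)
    expect_equal(length(r$audio), 12000)
    expect_lte(max(abs(r$audio)), 1)
    expect_true(all(is.finite(r$audio)))
  }
})

test_that("mixed scenes realise their SNR exactly at the component level", {
  tax <- default_taxonomy()
  mixed <- tax[vapply(tax, `[[`, character(1), "group") ==
                 "speech_in_background"]
  for (spec in mixed[1:3]) {
    r <- generate_scene(spec, 23, duration = 1, keep_components = TRUE)
    snr <- 10 * log10(sum(r$components$speech^2) /
                        sum(r$components$background^2))
    expect_equal(snr, spec$params$snr_db, tolerance = 0.1)
    expect_equal(r$components$speech + r$components$background, r$audio,
                 tolerance = 1e-12)
  }
})

test_that("zero-event-rate backgrounds are stationary (crest factor < 3)", {
  tax <- default_taxonomy()
  names_ <- vapply(tax, `[[`, character(1), "name")
  for (nm in c("in_vehicle", "wind")) {
    r <- generate_scene(tax[[which(names_ == nm)]], 9, duration = 2)
    crest <- max(abs(r$audio)) / sqrt(mean(r$audio^2))
    expect_lt(crest, 3)
  }
})

test_that("corpus generation is balanced, seeded and reproducible", {
  c1 <- generate_corpus(2, seed = 5, duration = 0.5, sample_rate = 8000)
  c2 <- generate_corpus(2, seed = 5, duration = 0.5, sample_rate = 8000)
  c3 <- generate_corpus(2, seed = 6, duration = 0.5, sample_rate = 8000)
  expect_length(c1$records, 28)
  expect_true(all(table(c1$manifest$label) == 2))
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$records[[1]]$audio, c2$records[[1]]$audio)
  sum1 <- vapply(c1$records, function(r) sum(r$audio), numeric(1))
  sum3 <- vapply(c3$records, function(r) sum(r$audio), numeric(1))
  expect_false(any(sum1 == sum3))
})

test_that("distinct classes produce distinct mean spikegram features", {
  bank <- build_filterbank(M = 16, fmin = 80, fmax = 7000,
                           sample_rate = 16000)
  corpus <- generate_corpus(2, seed = 31, duration = 1)
  fx <- corpus_features(corpus, bank, K = 102)
  means <- lapply(split(seq_along(fx$labels), fx$labels), function(idx)
    Reduce(`+`, fx$features[idx]) / length(idx))
  labs <- names(means)
  for (i in seq_along(labs)) {
    for (j in seq_len(i - 1)) {
      d <- sqrt(sum((means[[i]] - means[[j]])^2))
      expect_gt(d, 1e-2)
    }
  }
})

test_that("corpora round-trip through WAV files and a manifest", {
  dir <- tempfile()
  corpus <- generate_corpus(1, seed = 2, duration = 0.3, sample_rate = 8000)
  write_corpus(corpus, dir)
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 14)
  expect_true(all(file.exists(file.path(dir, man$path))))
  wav <- read_wav(file.path(dir, man$path[1]))
  expect_lt(max(abs(wav$samples - corpus$records[[1]]$audio)), 1 / 32768)
})
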