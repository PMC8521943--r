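make_code <- function(atoms, signal_length, bank) {
  structure(list(atoms = atoms, signal_length = signal_length,
                 sample_rate = bank$sample_rate,
                 initial_energy = 1, residual_energy = 0.5,
                 energy_path = numeric(0),
                 bank_key = hearscene:::bank_key(bank)),
            class = "sparse_code")
}

test_that("rasterisation places magnitudes in the right cells", {
  bank <- toy_bank()
  bw <- 10L
  empty <- make_code(data.frame(filter_index = integer(0),
                                time_offset = integer(0),
                                amplitude = numeric(0)), 100, bank)
  g0 <- rasterize(empty, bank, bin_width = bw, transform = "linear")$grid
  expect_equal(dim(g0), c(bank$M, 10))
  expect_true(all(g0 == 0))
  one <- make_code(data.frame(filter_index = 3L,
                              time_offset = 2L * bw + 1L,
                              amplitude = -2), 100, bank)
  g1 <- rasterize(one, bank, bin_width = bw, transform = "linear")$grid
  expect_equal(sum(g1 != 0), 1)
  expect_equal(g1[3, 3], 2)   # third bin holds offsets [2*bw, 3*bw)
})

test_that("linear raster mass equals the total atom magnitude", {
  bank <- toy_bank()
  code <- matching_pursuit(rand_signal(400, 21), bank, K = 15)
  g <- rasterize(code, bank, bin_width = 16L, transform = "linear")$grid
  expect_equal(sum(g), sum(abs(code$atoms$amplitude)), tolerance = 1e-12)
  glog <- rasterize(code, bank, bin_width = 16L, transform = "log1p")$grid
  expect_equal(sum(glog), sum(log1p(abs(code$atoms$amplitude))),
               tolerance = 1e-12)
  expect_true(all(g >= 0) && all(is.finite(g)))
})

test_that("rasterisation is invariant to atom order", {
  bank <- toy_bank()
  code <- matching_pursuit(rand_signal(300, 8), bank, K = 12)
  set.seed(1)
  shuffled <- code
  shuffled$atoms <- code$atoms[sample(nrow(code$atoms)), ]
  expect_equal(rasterize(code, bank, 8L)$grid,
               rasterize(shuffled, bank, 8L)$grid)
})

test_that("privacy report quantifies retained energy correctly", {
  bank <- toy_bank()
  zero <- matching_pursuit(numeric(200), bank, K = 4)
  rz <- privacy_report(zero, numeric(200), bank)
  expect_equal(rz$retained_fraction, 0)
  x1 <- 0.8 * atom_waveform(bank, 1, 20, 400)
  c1 <- matching_pursuit(x1, bank, K = 1)
  expect_equal(privacy_report(c1, x1, bank)$retained_fraction, 1,
               tolerance = 1e-9)
  x <- rand_signal(2000, seed = 14)
  code <- matching_pursuit(x, bank, K = 16)
  rep16 <- privacy_report(code, x, bank)
  xhat <- reconstruct(code, bank)
  expect_equal(rep16$retained_fraction,
               1 - sum((x - xhat)^2) / sum(x^2), tolerance = 1e-9)
  expect_error(privacy_report(code, x[-1], bank), "length")
})

test_that("serialised codes hold atom triples and scalars only", {
  bank <- toy_bank()
  x <- rand_signal(350, seed = 4)
  code <- matching_pursuit(x, bank, K = 10)
  path <- tempfile(fileext = ".csv")
  write_sparse_code(code, path)
  csv <- utils::read.csv(path)
  expect_named(csv, c("atom_rank", "filter_index", "time_offset_samples",
                      "amplitude"))
  expect_lte(nrow(csv), 10)
  side <- jsonlite::read_json(paste0(path, ".json"))
  # privacy contract: no serialised field can hold >= signal_length values
  expect_true(all(lengths(side) < code$signal_length))
  back <- read_sparse_code(path)
  expect_equal(back$atoms, code$atoms)
  expect_equal(back$residual_energy, code$residual_energy)
  expect_equal(reconstruct(back, bank), reconstruct(code, bank))
})
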