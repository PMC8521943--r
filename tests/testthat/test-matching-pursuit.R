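test_that("zero input yields an empty code with zero residual", {
  bank <- toy_bank()
  code <- matching_pursuit(numeric(300), bank, K = 10)
  expect_equal(nrow(code$atoms), 0)
  expect_equal(code$residual_energy, 0)
  expect_equal(code$initial_energy, 0)
})

test_that("a single scaled atom is recovered exactly", {
  bank <- build_filterbank(M = 12, fmin = 300, fmax = 3000,
                           sample_rate = 8000)
  x <- 0.5 * atom_waveform(bank, 10, 100, 800)
  code <- matching_pursuit(x, bank, K = 5)
  expect_equal(code$atoms$filter_index[1], 10)
  expect_equal(code$atoms$time_offset[1], 100)
  expect_equal(code$atoms$amplitude[1], 0.5, tolerance = 1e-6)
  expect_lt(code$residual_energy, 1e-10)
})

test_that("selections match the exhaustive brute-force oracle", {
  bank <- toy_bank()
  x <- rand_signal(256, seed = 31)
  code <- matching_pursuit(x, bank, K = 5)
  orac <- mp_oracle(x, bank, K = 5)
  expect_equal(code$atoms$filter_index, orac$atoms$filter_index)
  expect_equal(code$atoms$time_offset, orac$atoms$time_offset)
  expect_equal(code$atoms$amplitude, orac$atoms$amplitude,
               tolerance = 1e-9)
})

test_that("greedy selections equal exhaustive search across random instances", {
  set.seed(77)
  for (i in 1:20) {
    M <- sample(2:8, 1)
    n <- sample(128:512, 1)
    bank <- build_filterbank(M = M, fmin = runif(1, 250, 400),
                             fmax = runif(1, 1200, 1800),
                             sample_rate = 4000)
    x <- rnorm(n)
    K <- sample(3:6, 1)
    code <- matching_pursuit(x, bank, K = K)
    orac <- mp_oracle(x, bank, K = K)
    expect_identical(code$atoms$filter_index, orac$atoms$filter_index)
    expect_identical(code$atoms$time_offset, orac$atoms$time_offset)
    expect_equal(code$atoms$amplitude, orac$atoms$amplitude,
                 tolerance = 1e-9)
  }
})

test_that("energy is conserved and the residual path is monotone", {
  bank <- toy_bank()
  for (seed in c(5, 6, 7)) {
    x <- rand_signal(400, seed)
    code <- matching_pursuit(x, bank, K = 20)
    ident <- code$initial_energy -
      (sum(code$atoms$amplitude^2) + code$residual_energy)
    expect_lt(abs(ident) / code$initial_energy, 1e-6)
    expect_true(all(diff(c(code$initial_energy, code$energy_path)) <= 0))
    # strictly decreasing while atoms keep nonzero amplitude
    expect_true(all(diff(c(code$initial_energy, code$energy_path)) < 0))
  }
})

test_that("reconstruction reproduces the encoded superposition", {
  bank <- toy_bank()
  # empty code
  empty <- matching_pursuit(numeric(200), bank, K = 3)
  expect_equal(reconstruct(empty, bank), numeric(200))
  # one-term sum
  x1 <- 0.5 * atom_waveform(bank, 2, 50, 400)
  c1 <- matching_pursuit(x1, bank, K = 1)
  expect_equal(reconstruct(c1, bank), x1, tolerance = 1e-9)
  # residual identity on a generic run
  x <- rand_signal(500, seed = 12)
  code <- matching_pursuit(x, bank, K = 25)
  xhat <- reconstruct(code, bank)
  expect_equal(sum((x - xhat)^2), code$residual_energy,
               tolerance = 1e-6)
  # mismatched dictionary is refused
  other <- build_filterbank(M = 5, fmin = 300, fmax = 1500,
                            sample_rate = 4000)
  expect_error(reconstruct(code, other), "match")
})

test_that("binaural input is downmixed to the channel mean", {
  bank <- toy_bank()
  set.seed(3)
  left <- rnorm(300)
  right <- rnorm(300)
  stereo <- cbind(left, right)
  c_st <- matching_pursuit(stereo, bank, K = 8)
  c_mono <- matching_pursuit((left + right) / 2, bank, K = 8)
  expect_equal(c_st$atoms, c_mono$atoms)
})

test_that("invalid encode inputs raise data errors", {
  bank <- toy_bank()
  expect_error(matching_pursuit(numeric(0), bank, K = 3), "empty")
  expect_error(matching_pursuit(c(rnorm(100), NA), bank, K = 3),
               "finite")
  expect_error(matching_pursuit(rnorm(100), bank, K = 0), "K")
})
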