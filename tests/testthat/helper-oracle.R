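# Shared fixtures and the exhaustive matching-pursuit oracle.
#
# The oracle recomputes every inner product directly at every step - no
# correlation table, no incremental updates - so it is an independent
# check of the fast encoder's selections and amplitudes.

toy_bank <- function(M = 4L, fmin = 300, fmax = 1500, fs = 4000) {
  build_filterbank(M = M, fmin = fmin, fmax = fmax, sample_rate = fs)
}

# all (filter, offset) inner products with full-support placements
mp_all_correlations <- function(res, bank) {
  N <- length(res)
  lapply(seq_len(bank$M), function(m) {
    a <- bank$impulse_responses[[m]]
    L <- length(a)
    if (L > N) return(numeric(0))
    vapply(0:(N - L), function(t0) sum(res[t0 + seq_len(L)] * a),
           numeric(1))
  })
}

# brute-force matching pursuit: at each step scan every correlation,
# pick the largest |value| (ties: lowest filter, then lowest offset)
mp_oracle <- function(signal, bank, K) {
  res <- as.numeric(signal)
  sel <- data.frame(filter_index = integer(0), time_offset = integer(0),
                    amplitude = numeric(0))
  e0 <- sum(res^2)
  for (k in seq_len(K)) {
    if (sum(res^2) <= 1e-12 * e0) break
    corr <- mp_all_correlations(res, bank)
    best <- c(NA_integer_, NA_integer_)
    bestv <- -1
    for (m in seq_along(corr)) {
      cm <- corr[[m]]
      if (length(cm) == 0) next
      i <- which.max(abs(cm))          # first max: lowest offset
      if (abs(cm[i]) > bestv) {
        bestv <- abs(cm[i])
        best <- c(m, i - 1L)
        besta <- cm[i]
      }
    }
    if (is.na(best[1]) || bestv <= 0) break
    a <- bank$impulse_responses[[best[1]]]
    idx <- best[2] + seq_along(a)
    res[idx] <- res[idx] - besta * a
    sel <- rbind(sel, data.frame(filter_index = best[1],
                                 time_offset = best[2],
                                 amplitude = besta))
  }
  list(atoms = sel, residual = res, residual_energy = sum(res^2),
       initial_energy = e0)
}

rand_signal <- function(n, seed) {
  set.seed(seed)
  rnorm(n)
}

# small architectures keep the CNN unit tests fast
tiny_arch <- function(n_classes = 3L, dropout = 0) {
  cnn_architecture(conv_filters = c(2L, 3L), fc1_width = 6L,
                   dropout_rate = dropout, n_classes = n_classes)
}

tiny_features <- function(n, seed = 1, shape = c(8L, 8L)) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(runif(prod(shape)), shape[1], shape[2]))
}
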