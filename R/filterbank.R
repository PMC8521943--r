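#' Convert frequency in Hz to the ERB-rate scale
#'
#' The equivalent-rectangular-bandwidth (ERB) rate scale of Glasberg and
#' Moore maps frequency to a psychoacoustic "number of ERBs" axis on which
#' auditory filters are approximately uniformly spaced.
#'
#' @param f Frequency in Hz (vectorised).
#' @return ERB-rate value(s) in Cams.
#' @export
hz_to_erb_rate <- function(f) {
  21.4 * log10(4.37e-3 * f + 1)
}

#' Inverse of [hz_to_erb_rate()]
#'
#' @param e ERB-rate value(s) in Cams.
#' @return Frequency in Hz.
#' @export
erb_rate_to_hz <- function(e) {
  (10^(e / 21.4) - 1) / 4.37e-3
}

#' Equivalent rectangular bandwidth at a centre frequency
#'
#' Glasberg-Moore formula: ERB(f) = 24.7 (4.37 f/1000 + 1). Monotonically
#' increasing in f, which gives the characteristic widening of auditory
#' filters toward high frequencies.
#'
#' @param f Centre frequency in Hz.
#' @return Bandwidth in Hz.
#' @export
erb_bandwidth <- function(f) {
  24.7 * (4.37e-3 * f + 1)
}

# Impulse response of a 4th-order Gammatone filter at unit gain, truncated
# where the gamma envelope t^(n-1) exp(-2 pi b t) falls 60 dB below its peak.
# b is the envelope bandwidth parameter (1.019 * ERB for order 4).
gammatone_ir <- function(cf, sample_rate, order = 4L, env_drop_db = 60) {
  b <- 1.019 * erb_bandwidth(cf)
  # envelope peak at t = (order-1) / (2 pi b); find where it has dropped by
  # env_drop_db via monotone decay past the peak (numeric bisection on the
  # log-envelope, cheap and robust)
  tpk <- (order - 1) / (2 * pi * b)
  log_env <- function(t) (order - 1) * log(t) - 2 * pi * b * t
  target <- log_env(tpk) - env_drop_db * log(10) / 20
  lo <- tpk
  hi <- tpk * 2
  while (log_env(hi) > target) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (log_env(mid) > target) lo <- mid else hi <- mid
  }
  n <- max(4L, ceiling(hi * sample_rate))
  t <- (seq_len(n) - 0.5) / sample_rate
  ir <- t^(order - 1) * exp(-2 * pi * b * t) * cos(2 * pi * cf * t)
  ir / sqrt(sum(ir^2))
}

#' Build a Gammatone dictionary filterbank
#'
#' Constructs `M` 4th-order Gammatone filters with centre frequencies
#' uniformly spaced on the ERB-rate scale between `fmin` and `fmax`
#' (endpoints included). Each impulse response is truncated where its gamma
#' envelope falls 60 dB below peak and normalised to unit Euclidean norm,
#' so that the inner product of a signal with a shifted atom directly
#' equals the least-squares amplitude of that atom.
#'
#' @param M Number of filters (>= 2). Default 64.
#' @param fmin,fmax Frequency range in Hz; must satisfy
#'   `0 < fmin < fmax < sample_rate/2`. Defaults: 80 Hz and
#'   `0.45 * sample_rate`.
#' @param sample_rate Working sample rate in Hz. Default 16000.
#' @return An object of class `gammatone_bank`: a list with `sample_rate`,
#'   `M`, `fmin`, `fmax`, `center_frequencies`, `bandwidths` (ERB, Hz) and
#'   `impulse_responses` (list of unit-norm numeric vectors, increasing
#'   centre frequency).
#' @examples
#' bank <- build_filterbank(M = 8, fmin = 100, fmax = 4000, sample_rate = 16000)
#' sapply(bank$impulse_responses, function(h) sum(h^2))
#' @export
build_filterbank <- function(M = 64L, fmin = 80, fmax = 0.45 * sample_rate,
                             sample_rate = 16000) {
  M <- as.integer(M)
  if (is.na(M) || M < 2L)
    stop("M must be an integer >= 2", call. = FALSE)
  if (!(fmin > 0 && fmax > fmin && fmax < sample_rate / 2))
    stop("need 0 < fmin < fmax < sample_rate/2", call. = FALSE)
  e <- seq(hz_to_erb_rate(fmin), hz_to_erb_rate(fmax), length.out = M)
  cf <- erb_rate_to_hz(e)
  cf[1] <- fmin
  cf[M] <- fmax
  irs <- lapply(cf, gammatone_ir, sample_rate = sample_rate)
  structure(
    list(
      sample_rate = sample_rate,
      M = M,
      fmin = fmin,
      fmax = fmax,
      center_frequencies = cf,
      bandwidths = erb_bandwidth(cf),
      impulse_responses = irs
    ),
    class = "gammatone_bank"
  )
}

#' @export
print.gammatone_bank <- function(x, ...) {
  cat(sprintf(
    "Gammatone filterbank: %d filters, %.0f-%.0f Hz (ERB-rate spaced), fs = %g Hz\n",
    x$M, x$fmin, x$fmax, x$sample_rate
  ))
  cat(sprintf(
    "  atom lengths %d-%d samples (unit norm, -60 dB envelope truncation)\n",
    min(lengths(x$impulse_responses)), max(lengths(x$impulse_responses))
  ))
  invisible(x)
}

#' Materialise one dictionary atom as a waveform
#'
#' Returns the filter's unit-norm impulse response placed at a given time
#' offset inside a zero vector of the requested length, truncating at the
#' end if the atom does not fit.
#'
#' @param bank A `gammatone_bank`.
#' @param filter_index 1-based filter index in `[1, M]`.
#' @param time_offset Offset in samples (0-based, >= 0).
#' @param length Output length in samples.
#' @return Numeric vector of length `length`.
#' @export
atom_waveform <- function(bank, filter_index, time_offset, length) {
  stopifnot(inherits(bank, "gammatone_bank"))
  filter_index <- as.integer(filter_index)
  if (is.na(filter_index) || filter_index < 1L || filter_index > bank$M)
    stop("filter_index out of range [1, M]", call. = FALSE)
  if (time_offset < 0) stop("time_offset must be >= 0", call. = FALSE)
  out <- numeric(length)
  ir <- bank$impulse_responses[[filter_index]]
  n <- min(length(ir), length - time_offset)
  if (n > 0) out[time_offset + seq_len(n)] <- ir[seq_len(n)]
  out
}

#' Export a filterbank description as JSON
#'
#' Writes a sidecar that makes sparse codes interpretable without
#' re-deriving the dictionary: M, frequency range, sample rate and the
#' per-filter centre frequencies and ERBs. Impulse responses are not
#' stored; they are reconstructed deterministically by
#' [import_filterbank()].
#'
#' @param bank A `gammatone_bank`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_filterbank <- function(bank, path) {
  stopifnot(inherits(bank, "gammatone_bank"))
  obj <- list(
    type = "gammatone_bank",
    M = bank$M,
    fmin = bank$fmin,
    fmax = bank$fmax,
    sample_rate = bank$sample_rate,
    center_frequencies = bank$center_frequencies,
    bandwidths = bank$bandwidths
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a filterbank from its JSON description
#'
#' @param path Path written by [export_filterbank()].
#' @return A `gammatone_bank` identical to the exported one.
#' @export
import_filterbank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$type) || obj$type != "gammatone_bank")
    stop("not a filterbank JSON file: ", path, call. = FALSE)
  bank <- build_filterbank(
    M = obj$M, fmin = obj$fmin, fmax = obj$fmax,
    sample_rate = obj$sample_rate
  )
  if (max(abs(bank$center_frequencies - obj$center_frequencies)) > 1e-6)
    stop("filterbank JSON inconsistent with its parameters", call. = FALSE)
  bank
}

# stable identifier used to cache per-bank Gram tables
bank_key <- function(bank) {
  paste(bank$M, bank$fmin, bank$fmax, bank$sample_rate, sep = "|")
}
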