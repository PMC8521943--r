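# cache of atom-atom cross-correlation (Gram) tables, one per filterbank
.hearscene_cache <- new.env(parent = emptyenv())

gram_for_bank <- function(bank) {
  key <- bank_key(bank)
  g <- .hearscene_cache[[key]]
  if (is.null(g)) {
    g <- mp_gram_table(bank$impulse_responses)
    .hearscene_cache[[key]] <- g
  }
  g
}

#' Sparse-encode a signal by matching pursuit over a Gammatone dictionary
#'
#' Greedy decomposition x(t) = sum_k a_k * gamma_(f_k, t_k)(t) + eps(t):
#' at each step the (filter, time offset) pair whose unit-norm shifted atom
#' has the largest absolute inner product with the current residual is
#' selected, the signed inner product becomes the amplitude a_k, and the
#' scaled atom is subtracted from the residual. Atoms are only placed where
#' they lie fully inside the signal, so the inner product equals the
#' least-squares amplitude exactly. Ties are broken toward the lowest
#' filter index, then the smallest offset. Iteration stops after `K` atoms
#' or as soon as the residual energy falls below `stop_ratio` times the
#' initial energy.
#'
#' The serialised result holds only atom triples and scalar energies -
#' never raw samples - which is the privacy contract of the representation.
#'
#' @param signal Finite numeric vector, or a 2-column matrix (binaural
#'   input, downmixed to the channel mean before encoding).
#' @param bank A [build_filterbank()] dictionary.
#' @param K Maximum number of atoms (>= 1). Default 1024, the budget used
#'   for a 10-s segment at the default configuration.
#' @param stop_ratio Early-stop threshold on residual/initial energy.
#' @return A `sparse_code`: list with `atoms` (data.frame `filter_index`
#'   (1-based), `time_offset` (0-based samples), `amplitude`, in selection
#'   order), `signal_length`, `sample_rate`, `initial_energy`,
#'   `residual_energy` and `energy_path` (residual energy after each step).
#' @examples
#' bank <- build_filterbank(M = 4, fmin = 300, fmax = 1500, sample_rate = 4000)
#' x <- atom_waveform(bank, 2, 50, 400) * 0.5
#' matching_pursuit(x, bank, K = 4)$atoms
#' @export
matching_pursuit <- function(signal, bank, K = 1024L,
                             stop_ratio = 1e-12) {
  stopifnot(inherits(bank, "gammatone_bank"))
  if (is.matrix(signal)) signal <- rowMeans(signal)
  if (length(signal) == 0) stop("empty signal", call. = FALSE)
  if (!all(is.finite(signal))) stop("signal contains non-finite samples",
                                    call. = FALSE)
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be >= 1", call. = FALSE)
  res <- mp_encode_cpp(as.numeric(signal), bank$impulse_responses,
                       gram_for_bank(bank), K, stop_ratio)
  structure(
    list(
      atoms = data.frame(
        filter_index = res$filter_index + 1L,
        time_offset = res$time_offset,
        amplitude = res$amplitude
      ),
      signal_length = length(signal),
      sample_rate = bank$sample_rate,
      initial_energy = res$initial_energy,
      residual_energy = max(res$residual_energy, 0),
      energy_path = res$energy_path,
      bank_key = bank_key(bank)
    ),
    class = "sparse_code"
  )
}

#' @export
print.sparse_code <- function(x, ...) {
  retained <- if (x$initial_energy > 0)
    1 - x$residual_energy / x$initial_energy else 0
  cat(sprintf(
    "Sparse Gammatone code: %d atoms over %d samples (%.2f s @ %g Hz)\n",
    nrow(x$atoms), x$signal_length, x$signal_length / x$sample_rate,
    x$sample_rate
  ))
  cat(sprintf("  retained energy fraction: %.4f\n", retained))
  invisible(x)
}

#' Reconstruct the audio approximation encoded by a sparse code
#'
#' Materialises the superposition of the amplitude-scaled shifted atoms.
#' The difference to the originally encoded signal is the matching-pursuit
#' residual; its energy equals `code$residual_energy` up to floating-point
#' tolerance. Used to audit what an adversary holding only the code could
#' recover.
#'
#' @param code A `sparse_code`.
#' @param bank The dictionary the code was computed with.
#' @return Numeric vector of length `code$signal_length`.
#' @export
reconstruct <- function(code, bank) {
  stopifnot(inherits(code, "sparse_code"), inherits(bank, "gammatone_bank"))
  if (bank_key(bank) != code$bank_key)
    stop("filterbank does not match the one used for encoding",
         call. = FALSE)
  out <- numeric(code$signal_length)
  a <- code$atoms
  for (i in seq_len(nrow(a))) {
    ir <- bank$impulse_responses[[a$filter_index[i]]]
    idx <- a$time_offset[i] + seq_along(ir)
    out[idx] <- out[idx] + a$amplitude[i] * ir
  }
  out
}

#' Rasterise a sparse code into a spikegram feature grid
#'
#' Accumulates transformed atom magnitudes on an M x T grid: row = filter
#' index, column = `floor(time_offset / bin_width)`. This is the input
#' representation handed to the scene classifier. The result is a
#' deterministic, permutation-invariant function of the atom multiset.
#'
#' @param code A `sparse_code`.
#' @param bank The dictionary (provides M).
#' @param bin_width Bin width in samples (>= 1). Default 25 ms worth of
#'   samples, giving 400 columns for a 10-s segment at 16 kHz.
#' @param transform `"log1p"` (default; log(1+|a|) summed per cell, a mild
#'   dynamic-range compression in the spirit of log-spectral features) or
#'   `"linear"` (|a| summed per cell).
#' @return A `spikegram`: list with `grid` (M x T non-negative matrix),
#'   `bin_width`, `transform`.
#' @export
rasterize <- function(code, bank, bin_width = round(0.025 * bank$sample_rate),
                      transform = c("log1p", "linear")) {
  stopifnot(inherits(code, "sparse_code"), inherits(bank, "gammatone_bank"))
  transform <- match.arg(transform)
  bin_width <- as.integer(bin_width)
  if (is.na(bin_width) || bin_width < 1L)
    stop("bin_width must be >= 1 sample", call. = FALSE)
  T <- as.integer(ceiling(code$signal_length / bin_width))
  grid <- matrix(0, nrow = bank$M, ncol = T)
  a <- code$atoms
  if (nrow(a) > 0) {
    mag <- abs(a$amplitude)
    if (transform == "log1p") mag <- log1p(mag)
    bin <- a$time_offset %/% bin_width + 1L
    for (i in seq_len(nrow(a)))
      grid[a$filter_index[i], bin[i]] <- grid[a$filter_index[i], bin[i]] + mag[i]
  }
  structure(list(grid = grid, bin_width = bin_width, transform = transform),
            class = "spikegram")
}

#' Audit how much of a signal a sparse code retains
#'
#' Quantifies the privacy/utility trade-off of the sparse representation:
#' the fraction of signal energy the code captures, the residual fraction,
#' and the Pearson correlation between the reconstruction and the original
#' signal. The report carries scalars only, never samples.
#'
#' @param code A `sparse_code` computed from `original`.
#' @param original The encoded signal (mono numeric vector).
#' @param bank The dictionary used for encoding.
#' @return List with `retained_fraction`, `residual_fraction`,
#'   `reconstruction_correlation`, `n_atoms`, `signal_length`.
#' @export
privacy_report <- function(code, original, bank) {
  stopifnot(inherits(code, "sparse_code"))
  if (is.matrix(original)) original <- rowMeans(original)
  if (length(original) != code$signal_length)
    stop("original length does not match the encoded signal", call. = FALSE)
  e0 <- sum(original^2)
  if (e0 == 0) {
    return(list(retained_fraction = 0, residual_fraction = 1,
                reconstruction_correlation = 0,
                n_atoms = nrow(code$atoms),
                signal_length = code$signal_length))
  }
  xhat <- reconstruct(code, bank)
  eres <- sum((original - xhat)^2)
  rho <- if (stats::sd(xhat) > 0) stats::cor(original, xhat) else 0
  list(
    retained_fraction = max(0, min(1, 1 - eres / e0)),
    residual_fraction = eres / e0,
    reconstruction_correlation = rho,
    n_atoms = nrow(code$atoms),
    signal_length = code$signal_length
  )
}

#' Write a sparse code to CSV plus JSON sidecar
#'
#' The CSV holds one row per atom (`atom_rank,filter_index,
#' time_offset_samples,amplitude`); the sidecar holds the scalars needed to
#' interpret it. Neither file can hold raw audio samples.
#'
#' @param code A `sparse_code`.
#' @param path CSV output path; the sidecar is written to `paste0(path,
#'   ".json")`.
#' @return `path`, invisibly.
#' @export
write_sparse_code <- function(code, path) {
  stopifnot(inherits(code, "sparse_code"))
  df <- data.frame(
    atom_rank = seq_len(nrow(code$atoms)),
    filter_index = code$atoms$filter_index,
    time_offset_samples = code$atoms$time_offset,
    amplitude = code$atoms$amplitude
  )
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(
    signal_length = code$signal_length,
    sample_rate = code$sample_rate,
    initial_energy = code$initial_energy,
    residual_energy = code$residual_energy,
    bank_key = code$bank_key
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sparse code written by [write_sparse_code()]
#'
#' @param path CSV path (sidecar expected at `paste0(path, ".json")`).
#' @return A `sparse_code` (without the per-step energy path, which is not
#'   serialised).
#' @export
read_sparse_code <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(
      atoms = data.frame(
        filter_index = as.integer(df$filter_index),
        time_offset = as.integer(df$time_offset_samples),
        amplitude = df$amplitude
      ),
      signal_length = as.integer(side$signal_length),
      sample_rate = side$sample_rate,
      initial_energy = side$initial_energy,
      residual_energy = side$residual_energy,
      energy_path = NULL,
      bank_key = side$bank_key
    ),
    class = "sparse_code"
  )
}
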