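# Minimal RIFF/WAVE PCM reader and writer (16- and 24-bit integer PCM).
# Samples are exchanged with R as doubles in [-1, 1]; multi-channel audio
# is returned as an n x channels matrix.

#' Read a PCM WAV file
#'
#' Supports uncompressed RIFF/WAVE with 16- or 24-bit integer samples,
#' mono or multi-channel. Samples are scaled to [-1, 1]. Truncated or
#' malformed files raise a format error rather than returning corrupt
#' audio.
#'
#' @param path Path to a `.wav` file.
#' @return List with `samples` (numeric vector for mono, n x channels
#'   matrix otherwise), `sample_rate`, `bit_depth`, `channels`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")   # chunk size
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0) break
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      if (length(raw_fmt) < 16) stop("truncated fmt chunk", call. = FALSE)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw_fmt[3:4], "integer", 1, 2, endian = "little"),
        sample_rate = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (length(data_raw) < sz)
        stop("truncated data chunk in ", path, call. = FALSE)
      break
    } else {
      skipped <- readBin(con, "raw", sz + sz %% 2)
      if (length(skipped) < sz) stop("truncated chunk in ", path, call. = FALSE)
    }
  }
  if (is.null(fmt)) stop("missing fmt chunk in ", path, call. = FALSE)
  if (is.null(data_raw)) stop("missing data chunk in ", path, call. = FALSE)
  if (fmt$audio_format != 1L)
    stop("unsupported WAV encoding (only integer PCM)", call. = FALSE)
  if (!fmt$bits %in% c(16L, 24L))
    stop("unsupported bit depth: ", fmt$bits, call. = FALSE)
  bytes_per <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes_per
  if (n_total %% fmt$channels != 0)
    stop("data chunk length inconsistent with channel count", call. = FALSE)
  if (fmt$bits == 16L) {
    v <- readBin(data_raw, "integer", n_total, 2, signed = TRUE,
                 endian = "little")
    x <- v / 32768
  } else {
    m <- matrix(as.integer(data_raw), nrow = 3)
    v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  }
  ch <- fmt$channels
  samples <- if (ch == 1L) x else t(matrix(x, nrow = ch))
  list(samples = samples, sample_rate = fmt$sample_rate,
       bit_depth = fmt$bits, channels = ch)
}

#' Write a PCM WAV file
#'
#' @param samples Numeric vector (mono) or n x channels matrix with values
#'   in [-1, 1]; values outside are clipped.
#' @param path Output path.
#' @param sample_rate Sample rate in Hz.
#' @param bit_depth 16 (default) or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate, bit_depth = 16L) {
  if (!bit_depth %in% c(16L, 24L))
    stop("unsupported bit depth: ", bit_depth, call. = FALSE)
  if (is.matrix(samples)) {
    ch <- ncol(samples)
    x <- as.vector(t(samples))
  } else {
    ch <- 1L
    x <- as.numeric(samples)
  }
  x <- pmin(pmax(x, -1), 1)
  bytes_per <- bit_depth %/% 8L
  full <- 2^(bit_depth - 1)
  v <- as.integer(round(pmin(x * full, full - 1)))
  data_size <- length(v) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                       # PCM
  writeBin(as.integer(ch), con, 2, endian = "little")
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * ch * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(ch * bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bit_depth), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bit_depth == 16L) {
    writeBin(v, con, 2, endian = "little")
  } else {
    neg <- v < 0
    u <- ifelse(neg, v + 16777216, v)
    b <- rbind(u %% 256L, (u %/% 256L) %% 256L, u %/% 65536L)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}
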