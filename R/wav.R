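#' Read a PCM WAV file
#'
#' Reads an uncompressed RIFF/WAVE file (integer PCM at 16, 24 or 32 bits, or
#' IEEE float at 32 bits). Multi-channel files are collapsed to mono by
#' averaging the channels. Samples are returned as doubles in \[-1, 1\].
#'
#' @param path file path.
#' @return an `audio_signal`: a list with `samples` (numeric vector) and
#'   `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        format   = readBin(fmt_raw[1:2], "integer", 1L, size = 2, endian = "little", signed = FALSE),
        channels = readBin(fmt_raw[3:4], "integer", 1L, size = 2, endian = "little", signed = FALSE),
        rate     = readBin(fmt_raw[5:8], "integer", 1L, size = 4, endian = "little"),
        bits     = readBin(fmt_raw[15:16], "integer", 1L, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (length(data_raw) < sz) stop("truncated WAV data chunk: expected ", sz,
                                      " bytes, got ", length(data_raw))
      break
    } else {
      junk <- readBin(con, "raw", sz + sz %% 2L)
      if (length(junk) < sz) stop("truncated WAV chunk '", id, "'")
    }
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk")
  if (is.null(data_raw)) stop("WAV file has no data chunk")
  if (!fmt$format %in% c(1L, 3L)) stop("unsupported WAV encoding (format tag ", fmt$format,
                                       "); only PCM and IEEE float are supported")
  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  if (fmt$format == 3L) {
    if (fmt$bits != 32L) stop("unsupported float bit depth: ", fmt$bits)
    x <- readBin(data_raw, "double", n, size = 4, endian = "little")
  } else if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n, size = 2, endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
    v <- m[1L, ] + 256L * m[2L, ] + 65536L * m[3L, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else if (fmt$bits == 32L) {
    x <- readBin(data_raw, "integer", n, size = 4, endian = "little") / 2147483648
  } else {
    stop("unsupported PCM bit depth: ", fmt$bits)
  }
  if (fmt$channels > 1L) {
    nf <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(nf * fmt$channels)], nrow = fmt$channels))
  }
  audio_signal(x, fmt$rate)
}

#' Write a 16-bit PCM WAV file
#'
#' @param audio an `audio_signal` (see [audio_signal()]); samples outside
#'   \[-1, 1\] are clipped.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path) {
  stopifnot(inherits(audio, "audio_signal"))
  x <- pmax(-1, pmin(1, audio$samples))
  pcm <- as.integer(pmin(32767, round(x * 32768)))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(audio$rate), con, size = 4, endian = "little")
  writeBin(as.integer(audio$rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Construct an audio signal
#'
#' @param samples numeric vector of samples in \[-1, 1\].
#' @param rate sampling rate in Hz.
#' @return an object of class `audio_signal`.
#' @export
audio_signal <- function(samples, rate) {
  stopifnot(is.numeric(samples), length(rate) == 1L, rate > 0)
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}
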