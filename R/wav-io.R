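# Minimal RIFF/WAVE PCM reader and writer (16- and 24-bit integer PCM).
# Kept deliberately small: only the canonical fmt/data chunk layout used by
# concert recordings is supported.

#' Read a PCM WAV file as mono samples
#'
#' Supports 16- and 24-bit integer PCM, mono or stereo (stereo channels are
#' averaged). Samples are scaled to \eqn{[-1, 1)}.
#'
#' @param path WAV file path.
#' @return List with \code{samples} (numeric vector) and \code{fs} (Hz).
#' @export
read_wav_mono <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4L))
  if (riff != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # chunk size
  if (rawToChar(readBin(con, "raw", 4L)) != "WAVE") {
    stop("not a WAVE file", call. = FALSE)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4L)
    if (length(id_raw) < 4L) break
    id <- rawToChar(id_raw)
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (id == "fmt ") {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        n_channels = sum(as.integer(body[3:4]) * c(1, 256)),
        fs = sum(as.integer(body[5:8]) * 256^(0:3)),
        bits = sum(as.integer(body[15:16]) * c(1, 256)))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("missing fmt or data chunk", call. = FALSE)
  }
  if (fmt$audio_format != 1L) stop("only integer PCM supported", call. = FALSE)
  if (!(fmt$bits %in% c(16L, 24L))) {
    stop("only 16- or 24-bit PCM supported", call. = FALSE)
  }
  if (fmt$bits == 16L) {
    v <- readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little") / 32768
  } else {
    b <- as.integer(data_raw)
    ns <- length(b) %/% 3L
    idx <- 3L * (seq_len(ns) - 1L)
    raw24 <- b[idx + 1L] + 256 * b[idx + 2L] + 65536 * b[idx + 3L]
    raw24 <- ifelse(raw24 >= 2^23, raw24 - 2^24, raw24)
    v <- raw24 / 2^23
  }
  if (fmt$n_channels == 2L) {
    v <- (v[seq(1L, length(v), by = 2L)] + v[seq(2L, length(v), by = 2L)]) / 2
  } else if (fmt$n_channels != 1L) {
    stop("only mono or stereo supported", call. = FALSE)
  }
  list(samples = v, fs = fmt$fs)
}

#' Write mono samples as a 16-bit PCM WAV file
#'
#' @param samples numeric vector in \eqn{[-1, 1]}.
#' @param fs sample rate (Hz).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_wav_mono <- function(samples, fs, path) {
  pcm <- as.integer(pmax(pmin(round(samples * 32767), 32767), -32768))
  con <- file(path, "wb")
  on.exit(close(con))
  data_sz <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")       # PCM
  writeBin(1L, con, size = 2L, endian = "little")       # mono
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")       # block align
  writeBin(16L, con, size = 2L, endian = "little")      # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_sz, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
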