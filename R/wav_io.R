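#' Read a mono RIFF/WAVE file
#'
#' Minimal WAV reader supporting mono 16-bit PCM (format 1) and 32-bit IEEE
#' float (format 3), the two encodings this package writes. Multi-channel
#' files are rejected.
#'
#' @param path path to a .wav file.
#' @return list with `samples` (numeric, float scale so PCM16 is divided by
#'   32768) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("read_wav: not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE file")
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format    = readBin(con, "integer", 1, size = 2, endian = "little"),
        channels  = readBin(con, "integer", 1, size = 2, endian = "little"),
        fs        = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        block     = readBin(con, "integer", 1, size = 2, endian = "little"),
        bits      = readBin(con, "integer", 1, size = 2, endian = "little"))
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("read_wav: data chunk before fmt chunk")
      if (fmt$channels != 1L) stop("read_wav: only mono files supported")
      if (fmt$format == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", sz / 2, size = 2, signed = TRUE,
                           endian = "little") / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", sz / 4, size = 4, endian = "little")
      } else {
        stop("read_wav: unsupported encoding (need PCM16 or float32)")
      }
      break
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2)))
    }
  }
  if (is.null(samples)) stop("read_wav: no data chunk found")
  list(samples = as.numeric(samples), fs = fmt$fs)
}

#' Write a mono RIFF/WAVE file
#'
#' @param samples numeric vector; for PCM16 values are clipped to [-1, 1).
#' @param fs sampling rate (Hz).
#' @param path output path.
#' @param format `"float32"` (default, lossless for analysis signals) or
#'   `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  samples <- as.numeric(samples)
  n <- length(samples)
  bytes_per <- if (format == "float32") 4L else 2L
  data_sz <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "float32") 3L else 1L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(samples, con, size = 4, endian = "little")
  } else {
    q <- as.integer(round(pmin(pmax(samples, -1), 32767 / 32768) * 32768))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}
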