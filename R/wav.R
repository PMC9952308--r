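# Minimal RIFF/WAVE reader and writer (mono PCM16 or float32).
# Kept deliberately small: enough to round-trip stethoscope audio and
# heart-sound outputs at the slow-time rate.

#' Write a mono WAV file
#'
#' @param samples Numeric samples. For `"pcm16"` they are clipped to
#'   \[-1, 1\] and scaled by 32767; `"float32"` stores them as-is.
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @param format `"pcm16"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  check_finite_scalar(rate, "rate", min = 1)
  if (!all(is.finite(samples)))
    stop("samples contain non-finite values", call. = FALSE)
  n <- length(samples)
  bytes_per <- if (format == "pcm16") 2L else 4L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  audio_fmt <- if (format == "pcm16") 1L else 3L
  writeBin(audio_fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(round(rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(rate) * bytes_per), con, size = 4,
           endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little") # block align
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file as a sensor record
#'
#' Supports PCM16 and IEEE float32 mono files; PCM16 samples are scaled to
#' \[-1, 1\] by 1/32767 (the inverse of [write_wav()]'s scaling).
#'
#' @param path Path to the WAV file.
#' @param kind Sensor kind to tag the record with (default stethoscope).
#' @return A [sensor_record()].
#' @export
read_wav <- function(path, kind = "stethoscope") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  if (!identical(readChar(con, 4), "RIFF"))
    stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE"))
    stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; samples <- NULL; rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      audio_fmt <- readBin(con, "integer", size = 2, endian = "little")
      channels <- readBin(con, "integer", size = 2, endian = "little")
      rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (sz > 16) readBin(con, "raw", n = sz - 16)
      if (channels != 1L)
        stop("only mono WAV supported, found ", channels, " channels",
             call. = FALSE)
      fmt <- list(audio_fmt = audio_fmt, bits = bits)
    } else if (id == "data") {
      if (is.null(fmt)) stop("WAV data chunk before fmt chunk", call. = FALSE)
      if (fmt$audio_fmt == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", n = sz / 2, size = 2,
                           signed = TRUE, endian = "little") / 32767
      } else if (fmt$audio_fmt == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", n = sz / 4, size = 4,
                           endian = "little")
      } else {
        stop(sprintf("unsupported WAV encoding (format %d, %d bit)",
                     fmt$audio_fmt, fmt$bits), call. = FALSE)
      }
      break
    } else {
      readBin(con, "raw", n = sz)
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path, call. = FALSE)
  sensor_record(samples, rate, kind = kind,
                units = if (kind == "accelerometer") "m/s^2" else "a.u.")
}
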