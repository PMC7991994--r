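# Minimal RIFF/WAVE codec. Mono PCM in 16/24/32-bit integer and 32/64-bit
# IEEE-float dialects are read and normalized to [-1, 1]; writing supports
# 16-bit integer PCM and 32-bit float.

#' Read a mono RIFF PCM WAV file
#'
#' @param path Path to a `.wav` file.
#' @return List with `samples` (numeric in `[-1, 1]`) and `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort(paste0(path, ": not a RIFF file"))
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort(paste0(path, ": not a WAVE file"))

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(paste0(path, ": missing fmt or data chunk"))
  }
  if (fmt$channels != 1) {
    abort(paste0(path, ": expected mono audio, got ", fmt$channels, " channels"))
  }

  bytes <- fmt$bits / 8
  n <- length(data_raw) %/% bytes
  x <- if (fmt$audio_format == 3) {        # IEEE float
    readBin(data_raw, "double", n, bytes, endian = "little")
  } else if (fmt$audio_format == 1) {      # integer PCM
    if (fmt$bits == 16) {
      readBin(data_raw, "integer", n, 2, signed = TRUE,
              endian = "little") / 32768
    } else if (fmt$bits == 32) {
      readBin(data_raw, "integer", n, 4, endian = "little") / 2147483648
    } else if (fmt$bits == 24) {
      m <- matrix(as.integer(data_raw), nrow = 3)
      v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (fmt$bits == 8) {
      (as.integer(readBin(data_raw, "raw", n)) - 128) / 128
    } else {
      abort(paste0(path, ": unsupported PCM bit depth ", fmt$bits))
    }
  } else {
    abort(paste0(path, ": unsupported audio format code ", fmt$audio_format))
  }
  list(samples = x, sample_rate_hz = fmt$sample_rate)
}

#' Write a mono WAV file
#'
#' @param x A `voice_recording` or a numeric sample vector in `[-1, 1]`.
#' @param path Output path.
#' @param sample_rate_hz Sampling rate; taken from the recording if omitted.
#' @param bit_depth `"float32"` (IEEE float) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate_hz = NULL,
                      bit_depth = c("float32", "pcm16")) {
  bit_depth <- match.arg(bit_depth)
  if (inherits(x, "voice_recording")) {
    sample_rate_hz <- x$sample_rate_hz
    x <- x$samples
  }
  if (is.null(sample_rate_hz)) abort("sample_rate_hz required")
  x <- pmin(pmax(x, -1), 1)

  con <- file(path, "wb")
  on.exit(close(con))
  if (bit_depth == "float32") {
    fmt_code <- 3L; bits <- 32L
    payload_size <- length(x) * 4L
  } else {
    fmt_code <- 1L; bits <- 16L
    payload_size <- length(x) * 2L
  }
  block <- bits %/% 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + payload_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")             # mono
  writeBin(as.integer(sample_rate_hz), con, 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * block), con, 4, endian = "little")
  writeBin(block, con, 2, endian = "little")
  writeBin(bits, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(payload_size), con, 4, endian = "little")
  if (bit_depth == "float32") {
    writeBin(as.numeric(x), con, 4, endian = "little")
  } else {
    writeBin(as.integer(round(x * 32767)), con, 2, endian = "little")
  }
  invisible(path)
}

#' Assemble a voice recording from samples and metadata
#'
#' @param samples Numeric sample vector, nominal range `[-1, 1]`.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param subject_id,vowel,sex,age_years,group Subject metadata.
#' @return A `voice_recording`.
#' @export
voice_recording <- function(samples, sample_rate_hz, subject_id = "S000",
                            vowel = "a", sex = "male", age_years = NA_real_,
                            group = NA_character_) {
  if (length(samples) == 0) abort("samples must be non-empty")
  if (sample_rate_hz <= 0) abort("sample_rate_hz must be positive")
  if (!vowel %in% c("a", "e", "i", "o", "u")) {
    abort("vowel must be one of a, e, i, o, u")
  }
  structure(
    list(samples = as.numeric(samples), sample_rate_hz = sample_rate_hz,
         subject_id = subject_id, vowel = vowel, sex = sex,
         age_years = age_years, group = group, ground_truth = NULL),
    class = "voice_recording"
  )
}
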