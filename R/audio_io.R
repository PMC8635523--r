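#' Construct a waveform object
#'
#' A waveform is a sampled mono audio signal: a numeric vector of amplitudes
#' (nominal range \[-1, 1\]) together with its sample rate, and optionally a
#' class label and a provenance identifier.
#'
#' @param samples Numeric vector of finite amplitude values.
#' @param sample_rate Sampling rate in Hz (positive).
#' @param label Optional class token (see [class_vocabulary()]).
#' @param source_id Optional provenance string.
#' @return An object of class `rs_wave` with fields `samples`, `sample_rate`,
#'   `label`, `source_id`.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 100 * seq(0, 1, length.out = 8000)), 8000)
#' w
waveform <- function(samples, sample_rate, label = NULL, source_id = NULL) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) {
    stop("waveform samples must all be finite")
  }
  sample_rate <- as.numeric(sample_rate)
  if (length(sample_rate) != 1L || !is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be a single positive number")
  }
  structure(
    list(samples = samples, sample_rate = sample_rate,
         label = label, source_id = source_id),
    class = "rs_wave"
  )
}

#' @export
print.rs_wave <- function(x, ...) {
  cat(sprintf("<rs_wave> %d samples @ %g Hz (%.3f s)%s\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (is.null(x$label)) "" else paste0(" label=", x$label)))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param waveform An `rs_wave`.
#' @return Duration in seconds.
#' @export
wave_duration <- function(waveform) {
  stopifnot(inherits(waveform, "rs_wave"))
  length(waveform$samples) / waveform$sample_rate
}

# ---- WAV (RIFF/WAVE) I/O --------------------------------------------------
# Minimal chunk-walking reader: PCM 8/16/24/32-bit and IEEE float 32-bit,
# any channel count (averaged to mono). Writer emits 16-bit PCM mono.

#' Read a WAV file as a mono waveform
#'
#' Accepts RIFF/WAVE files containing 8/16/24/32-bit integer PCM or 32-bit
#' IEEE float samples. Multi-channel input is averaged to mono; sample values
#' are rescaled to \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @param label Optional class token to attach.
#' @return An [waveform()] object; `source_id` is the file name.
#' @export
read_wav <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # total size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1, 2,
                           signed = FALSE, endian = "little"),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2,
                       signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip (chunks are word-aligned)
      next
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1L)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("corrupt WAV (missing fmt/data chunk): ", path)
  }
  # WAVE_FORMAT_EXTENSIBLE (0xFFFE) carries the real format in its extension;
  # treat as PCM/float by bit depth, which covers the common encodings.
  af <- fmt$audio_format
  bits <- fmt$bits
  x <- if (af == 3L || (af == 65534L && bits == 32L)) {
    readBin(data_raw, "double", length(data_raw) / 4L, 4L, endian = "little")
  } else if (bits == 8L) {
    (readBin(data_raw, "integer", length(data_raw), 1L,
             signed = FALSE) - 128) / 128
  } else if (bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) / 2L, 2L,
            endian = "little") / 32768
  } else if (bits == 24L) {
    n <- length(data_raw) %/% 3L
    b <- matrix(as.integer(data_raw), nrow = 3L)[, seq_len(n), drop = FALSE]
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    ifelse(v >= 8388608, v - 16777216, v) / 8388608
  } else if (bits == 32L) {
    readBin(data_raw, "integer", length(data_raw) / 4L, 4L,
            endian = "little") / 2147483648
  } else {
    stop("unsupported WAV bit depth: ", bits)
  }
  if (fmt$channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  waveform(x, fmt$sample_rate, label = label, source_id = basename(path))
}

#' Write a waveform as a 16-bit PCM mono WAV file
#'
#' Samples outside \[-1, 1\] are clipped (with a warning).
#'
#' @param waveform An [waveform()] object with at least one sample.
#' @param path Output file path.
#' @return `path`, invisibly usable; returned visibly for piping.
#' @export
write_wav <- function(waveform, path) {
  stopifnot(inherits(waveform, "rs_wave"))
  x <- waveform$samples
  if (length(x) == 0L) stop("cannot write an empty waveform")
  if (any(x > 1 | x < -1)) {
    warning("samples outside [-1, 1] clipped on write")
    x <- pmin(1, pmax(-1, x))
  }
  pcm <- pmin(as.integer(round(x * 32768)), 32767L)
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")                       # PCM
  writeBin(1L, con, 2L, endian = "little")                       # mono
  writeBin(as.integer(waveform$sample_rate), con, 4L, endian = "little")
  writeBin(as.integer(waveform$sample_rate) * 2L, con, 4L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")                       # block align
  writeBin(16L, con, 2L, endian = "little")                      # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  path
}

#' Peak-normalize a waveform
#'
#' Rescales so the maximum absolute amplitude is exactly 1. An all-zero
#' waveform is returned unchanged with a warning.
#'
#' @param waveform An [waveform()] object with at least one sample.
#' @return The normalized `rs_wave`.
#' @export
normalize_peak <- function(waveform) {
  stopifnot(inherits(waveform, "rs_wave"))
  if (length(waveform$samples) == 0L) stop("cannot normalize an empty waveform")
  peak <- max(abs(waveform$samples))
  if (peak == 0) {
    warning("all-zero waveform; normalization skipped")
    return(waveform)
  }
  waveform$samples <- waveform$samples / peak
  waveform
}

#' Resample a waveform to a new rate
#'
#' Band-limited polyphase resampling (via [signal::resample()]); content
#' above the target Nyquist frequency is removed. Duration is preserved to
#' within one sample period.
#'
#' @param waveform An [waveform()] object.
#' @param target_rate Target sampling rate in Hz (positive).
#' @return The resampled `rs_wave`.
#' @export
resample_wave <- function(waveform, target_rate) {
  stopifnot(inherits(waveform, "rs_wave"))
  if (!is.finite(target_rate) || target_rate <= 0) {
    stop("target_rate must be positive")
  }
  if (target_rate == waveform$sample_rate) return(waveform)
  r <- .rational(target_rate / waveform$sample_rate)
  y <- signal::resample(waveform$samples, p = r[1], q = r[2])
  n_out <- round(length(waveform$samples) * target_rate / waveform$sample_rate)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, numeric(n_out - length(y)))
  waveform(y, target_rate, label = waveform$label,
           source_id = waveform$source_id)
}

# small rational approximation p/q of a positive ratio
.rational <- function(x, max_den = 1000L) {
  stopifnot(x > 0)
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(x - p / q)
    if (e < err - 1e-15) { best <- c(as.integer(p), q); err <- e }
    if (e < 1e-12) break
  }
  best
}
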