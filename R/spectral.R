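#' Solve the elementary wave relations
#'
#' Fills in frequency `f` (Hz), period `t` (s), velocity `v` (m/s) and
#' wavelength `lambda` (m) from any two that determine the rest, using
#' `f = 1/t` and `v = f * lambda`.
#'
#' @param frequency,period,velocity,wavelength Known quantities; leave the
#'   others `NULL`. Exactly two must be supplied (the pair `frequency` +
#'   `period` is accepted only when consistent, and then determines neither
#'   `velocity` nor `wavelength`).
#' @return A list of class `wave_params` with the derivable fields filled;
#'   underdetermined fields are `NA`.
#' @export
#' @examples
#' wave_relations(velocity = 340, wavelength = 1.7)  # 200 Hz
wave_relations <- function(frequency = NULL, period = NULL,
                           velocity = NULL, wavelength = NULL) {
  known <- list(frequency = frequency, period = period,
                velocity = velocity, wavelength = wavelength)
  given <- !vapply(known, is.null, logical(1))
  if (sum(given) != 2L) stop("supply exactly two known quantities")
  for (nm in names(known)[given]) {
    v <- known[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(nm, " must be a single finite number")
    }
    if (v == 0 && nm %in% c("frequency", "period", "wavelength")) {
      stop(nm, " must be non-zero")
    }
  }
  f <- frequency; t <- period; v <- velocity; l <- wavelength
  if (!is.null(f) && !is.null(t)) {
    if (abs(f * t - 1) > 1e-9) {
      stop("inconsistent pair: frequency * period must equal 1")
    }
  }
  for (i in 1:3) {  # propagate until fixed point
    if (is.null(f) && !is.null(t)) f <- 1 / t
    if (is.null(t) && !is.null(f)) t <- 1 / f
    if (is.null(f) && !is.null(v) && !is.null(l)) f <- v / l
    if (is.null(v) && !is.null(f) && !is.null(l)) v <- f * l
    if (is.null(l) && !is.null(v) && !is.null(f)) l <- v / f
  }
  structure(list(frequency = f %||% NA_real_, period = t %||% NA_real_,
                 velocity = v %||% NA_real_, wavelength = l %||% NA_real_),
            class = "wave_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.spectrum <- function(frequencies, magnitudes, sidedness, n, sample_rate) {
  structure(list(frequencies = frequencies, magnitudes = magnitudes,
                 sidedness = sidedness, n = n, sample_rate = sample_rate),
            class = "rs_spectrum")
}

#' @export
print.rs_spectrum <- function(x, ...) {
  cat(sprintf("<rs_spectrum> %s, %d bins over [%g, %g] Hz (n = %d @ %g Hz)\n",
              x$sidedness, length(x$frequencies), min(x$frequencies),
              max(x$frequencies), x$n, x$sample_rate))
  invisible(x)
}

#' Two-sided magnitude spectrum
#'
#' Discrete Fourier transform magnitudes over both negative and positive
#' frequency bins ("complete" FFT).
#'
#' @param waveform An [waveform()] object with at least one sample.
#' @return An `rs_spectrum` with `sidedness = "two_sided"`, `n` bins at
#'   frequencies `(-n/2, n/2] * rate / n` in increasing order.
#' @export
complete_fft <- function(waveform) {
  stopifnot(inherits(waveform, "rs_wave"))
  n <- length(waveform$samples)
  if (n == 0L) stop("cannot transform an empty waveform")
  mag <- Mod(stats::fft(waveform$samples))
  # fft() order: 0, 1, ..., n-1 cycles; shift to increasing frequency
  k <- 0:(n - 1)
  k_signed <- ifelse(k > n / 2, k - n, k)
  ord <- order(k_signed)
  .spectrum(k_signed[ord] * waveform$sample_rate / n, mag[ord],
            "two_sided", n, waveform$sample_rate)
}

#' One-sided magnitude spectrum
#'
#' Discrete Fourier transform magnitudes over `floor(n/2) + 1` non-negative
#' frequency bins spanning \[0, rate/2\] ("positive" FFT). Each positive bin's
#' magnitude equals the corresponding two-sided magnitude.
#'
#' @param waveform An [waveform()] object with at least one sample.
#' @return An `rs_spectrum` with `sidedness = "one_sided"`.
#' @export
positive_fft <- function(waveform) {
  stopifnot(inherits(waveform, "rs_wave"))
  n <- length(waveform$samples)
  if (n == 0L) stop("cannot transform an empty waveform")
  mag <- Mod(stats::fft(waveform$samples))
  nb <- floor(n / 2) + 1L
  .spectrum((0:(nb - 1L)) * waveform$sample_rate / n, mag[seq_len(nb)],
            "one_sided", n, waveform$sample_rate)
}

#' Dominant (peak) frequency of a one-sided spectrum
#'
#' Frequency of the maximum-magnitude bin, ignoring the DC (0 Hz) bin.
#' Ties break toward the lower frequency.
#'
#' @param spectrum A one-sided `rs_spectrum` (from [positive_fft()]).
#' @return Peak frequency in Hz.
#' @export
peak_frequency <- function(spectrum) {
  stopifnot(inherits(spectrum, "rs_spectrum"))
  if (!identical(spectrum$sidedness, "one_sided")) {
    stop("peak_frequency expects a one-sided spectrum")
  }
  keep <- spectrum$frequencies > 0
  mags <- spectrum$magnitudes[keep]
  if (length(mags) == 0L || all(mags == 0)) {
    stop("spectrum has no non-zero non-DC content")
  }
  spectrum$frequencies[keep][which.max(mags)]  # which.max: first == lowest
}

# window generator; n samples, periodic convention not needed here
.window <- function(kind, n) {
  i <- seq_len(n) - 1L
  switch(kind,
         hann = 0.5 * (1 - cos(2 * pi * i / (n - 1))),
         hamming = 0.54 - 0.46 * cos(2 * pi * i / (n - 1)),
         rectangular = rep(1, n),
         stop("unknown window kind: ", kind))
}

#' Short-time Fourier spectrogram
#'
#' Frames the signal (frame count `1 + floor((n - window) / hop)`), applies
#' the analysis window, and stores each frame's one-sided magnitude spectrum
#' as a column-slice of a frames-by-bins matrix.
#'
#' @param waveform An [waveform()] object.
#' @param window_length Analysis window length in samples (default 256,
#'   i.e. 32 ms at the canonical 8 kHz rate).
#' @param hop_length Hop between frames in samples (default
#'   `window_length / 2`).
#' @param window_kind `"hann"` (default), `"hamming"` or `"rectangular"`.
#' @return An `rs_spectrogram`: list with `magnitudes` (frames x bins),
#'   `times` (frame-start seconds), `frequencies` (Hz, `[0, rate/2]`),
#'   `window_length`, `hop_length`, `window_kind`, `sample_rate`.
#' @export
stft_spectrogram <- function(waveform, window_length = 256L,
                             hop_length = window_length %/% 2L,
                             window_kind = "hann") {
  stopifnot(inherits(waveform, "rs_wave"))
  n <- length(waveform$samples)
  window_length <- as.integer(window_length)
  hop_length <- as.integer(hop_length)
  if (hop_length <= 0L) stop("hop_length must be positive")
  if (window_length < hop_length) stop("hop_length must not exceed window_length")
  if (window_length > n) {
    stop("window_length (", window_length, ") exceeds signal length (", n,
         "); pad the signal or shorten the window")
  }
  n_frames <- 1L + (n - window_length) %/% hop_length
  starts <- (seq_len(n_frames) - 1L) * hop_length
  w <- .window(window_kind, window_length)
  frames <- vapply(starts,
                   function(s) waveform$samples[(s + 1):(s + window_length)] * w,
                   numeric(window_length))
  nb <- floor(window_length / 2) + 1L
  mags <- Mod(stats::mvfft(frames))[seq_len(nb), , drop = FALSE]
  structure(
    list(magnitudes = t(mags),
         times = starts / waveform$sample_rate,
         frequencies = (0:(nb - 1L)) * waveform$sample_rate / window_length,
         window_length = window_length, hop_length = hop_length,
         window_kind = window_kind, sample_rate = waveform$sample_rate),
    class = "rs_spectrogram"
  )
}

#' @export
print.rs_spectrogram <- function(x, ...) {
  cat(sprintf("<rs_spectrogram> %d frames x %d bins, window %d hop %d (%s)\n",
              nrow(x$magnitudes), ncol(x$magnitudes), x$window_length,
              x$hop_length, x$window_kind))
  invisible(x)
}

#' ANA: coherent spectral self-addition
#'
#' Artificial Noise Addition adds a spectrum to itself (`gain = 2`, the
#' default) or more generally scales every magnitude by `gain`. Axes,
#' dimensions and all bin-to-bin magnitude ratios are unchanged -- the
#' operator strengthens faint structure without altering spectral shape.
#' It is *not* additive random noise.
#'
#' @param target An `rs_spectrum` or `rs_spectrogram`.
#' @param gain Multiplicative magnitude factor, `>= 1` (default 2 =
#'   self-addition).
#' @return The enhanced object, same class as `target`.
#' @export
apply_ana <- function(target, gain = 2) {
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) || gain < 1) {
    stop("gain must be a single number >= 1")
  }
  if (inherits(target, "rs_spectrum")) {
    target$magnitudes <- target$magnitudes * gain
  } else if (inherits(target, "rs_spectrogram")) {
    target$magnitudes <- target$magnitudes * gain
  } else {
    stop("apply_ana expects an rs_spectrum or rs_spectrogram")
  }
  target
}

#' Amplitude envelope by peak interpolation
#'
#' The envelope is the linear interpolation of the local maxima of the
#' rectified signal `|x|` (endpoints included), a simple demodulation
#' adequate for measuring event durations.
#'
#' @param waveform An [waveform()] object.
#' @return Numeric vector of envelope values, same length as the signal.
#' @export
amplitude_envelope <- function(waveform) {
  stopifnot(inherits(waveform, "rs_wave"))
  a <- abs(waveform$samples)
  n <- length(a)
  if (n < 3L) return(a)
  interior <- which(diff(sign(diff(a))) < 0) + 1L
  # exact-zero samples (silence) anchor the envelope at zero
  idx <- sort(unique(c(1L, interior, which(a == 0), n)))
  stats::approx(idx, a[idx], xout = seq_len(n), rule = 2)$y
}

#' Envelope-support duration of an event
#'
#' The time span over which the amplitude envelope exceeds `frac` of its
#' peak -- the operational definition of an adventitious event's duration.
#'
#' @param waveform An [waveform()] object.
#' @param frac Threshold as a fraction of the envelope peak (default 0.1).
#' @return Duration in seconds.
#' @export
envelope_support <- function(waveform, frac = 0.1) {
  env <- amplitude_envelope(waveform)
  peak <- max(env)
  if (peak == 0) return(0)
  above <- which(env > frac * peak)
  if (length(above) == 0L) return(0)
  (max(above) - min(above) + 1L) / waveform$sample_rate
}
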