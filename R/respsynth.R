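# Parametric simulator of adventitious respiratory sounds.
#
# Continuous adventitious sounds (CAS: wheeze, rhonchi, stridor, squawk) are
# modelled as harmonic tones with slow vibrato under a tapered envelope;
# discontinuous sounds (DAS: crackles, pleural rub) as exponentially damped
# sinusoid bursts. Recordings superimpose events, at breath-phase-appropriate
# offsets, on band-passed vesicular background noise.

.class_table <- function() {
  list(
    wheeze         = list(category = "CAS", f0_low = 400, f0_high = 800,
                          event_duration_ms = 250, phase = "both"),
    rhonchi        = list(category = "CAS", f0_low = 150, f0_high = 250,
                          event_duration_ms = 250, phase = "both"),
    stridor        = list(category = "CAS", f0_low = 500, f0_high = 1000,
                          event_duration_ms = 300, phase = "inspiration"),
    squawk         = list(category = "CAS", f0_low = 200, f0_high = 300,
                          event_duration_ms = 90, phase = "inspiration"),
    fine_crackle   = list(category = "DAS", f0_low = 650, f0_high = 650,
                          event_duration_ms = 5, phase = "inspiration"),
    coarse_crackle = list(category = "DAS", f0_low = 350, f0_high = 350,
                          event_duration_ms = 15,
                          phase = "early_inspiration_and_expiration"),
    pleural_rub    = list(category = "DAS", f0_low = 150, f0_high = 350,
                          event_duration_ms = 15, phase = "both")
  )
}

#' Acoustic specification of an adventitious sound class
#'
#' Returns the per-class acoustic constants used by the simulator: CAS/DAS
#' category, dominant-pitch range (Hz), nominal event duration (ms) and
#' breath-phase placement. Wheeze and stridor are high-pitched tonal CAS
#' (>= 400 / >= 500 Hz); rhonchi (~200 Hz) and squawk (200-300 Hz) low-pitched
#' CAS; fine and coarse crackles are ~5 ms / ~15 ms transients at 650 / 350
#' Hz; pleural rub is a train of low-pitched (<= 350 Hz) friction bursts.
#'
#' @param label One of [class_vocabulary()].
#' @return A list of class `class_spec` with fields `label`, `category`,
#'   `f0_low`, `f0_high`, `event_duration_ms`, `phase`.
#' @export
#' @examples
#' class_spec("fine_crackle")
class_spec <- function(label) {
  tab <- .class_table()
  if (!label %in% names(tab)) {
    stop("unknown class '", label, "'; expected one of: ",
         paste(names(tab), collapse = ", "))
  }
  structure(c(list(label = label), tab[[label]]), class = "class_spec")
}

#' @export
print.class_spec <- function(x, ...) {
  cat(sprintf("<class_spec> %s (%s): %g-%g Hz, %g ms, phase %s\n",
              x$label, x$category, x$f0_low, x$f0_high,
              x$event_duration_ms, x$phase))
  invisible(x)
}

#' Breath-cycle model for the simulator background
#'
#' @param inspiration_s,expiration_s Phase durations in seconds.
#' @param vesicular_band_hz Length-2 passband (Hz) of the vesicular
#'   background noise.
#' @param background_level Background peak amplitude relative to the unit
#'   event amplitude, in (0, 1).
#' @return A list of class `breath_model`.
#' @export
breath_model <- function(inspiration_s = 1.5, expiration_s = 2.0,
                         vesicular_band_hz = c(100, 1000),
                         background_level = 0.1) {
  stopifnot(inspiration_s > 0, expiration_s > 0,
            length(vesicular_band_hz) == 2L,
            vesicular_band_hz[1] < vesicular_band_hz[2],
            background_level > 0, background_level < 1)
  structure(list(inspiration_s = inspiration_s, expiration_s = expiration_s,
                 vesicular_band_hz = vesicular_band_hz,
                 background_level = background_level),
            class = "breath_model")
}

#' Simulator configuration
#'
#' Defaults reproduce the reference corpus composition: 70 recordings with
#' per-class counts wheeze 12, rhonchi 9, stridor 10, squawk 8, fine crackle
#' 11, coarse crackle 11, pleural rub 9.
#'
#' @param counts Named integer vector mapping class tokens to recording
#'   counts (all `>= 0`).
#' @param sample_rate Sampling rate in Hz (default 8000, the package's
#'   canonical internal rate).
#' @param n_cycles Breath cycles per recording (default 2).
#' @param jitter_pct Percent random perturbation of event pitch and duration,
#'   in \[0, 50\] (default 5).
#' @param seed RNG seed for corpus generation.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(counts = c(wheeze = 12, rhonchi = 9, stridor = 10,
                                    squawk = 8, fine_crackle = 11,
                                    coarse_crackle = 11, pleural_rub = 9),
                         sample_rate = 8000, n_cycles = 2,
                         jitter_pct = 5, seed = 0) {
  if (!all(names(counts) %in% class_vocabulary())) {
    stop("counts has labels outside the class vocabulary")
  }
  if (any(counts < 0)) stop("counts must be >= 0")
  if (jitter_pct < 0 || jitter_pct > 50) stop("jitter_pct must be in [0, 50]")
  structure(list(counts = counts, sample_rate = sample_rate,
                 n_cycles = n_cycles, jitter_pct = jitter_pct, seed = seed),
            class = "synth_config")
}

# Tukey (tapered-cosine) window, taper fraction alpha on each... total
# (alpha/2 of the length ramps up, alpha/2 ramps down)
.tukey <- function(n, alpha = 0.25) {
  i <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  r <- alpha / 2
  up <- i < r
  dn <- i > 1 - r
  w[up] <- 0.5 * (1 - cos(pi * i[up] / r))
  w[dn] <- 0.5 * (1 - cos(pi * (1 - i[dn]) / r))
  w
}

.jitter <- function(x, jitter_pct) {
  x * (1 + stats::runif(1, -jitter_pct / 100, jitter_pct / 100))
}

# One damped-sinusoid burst (the DAS building block).
.das_burst <- function(f0, duration_s, sample_rate) {
  n <- max(8L, round(duration_s * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate
  x <- sin(2 * pi * f0 * t) * .tukey(n, 0.25) * exp(-2 * t / duration_s)
  x / max(abs(x))
}

# One harmonic tonal event (the CAS building block).
.cas_tone <- function(f0, duration_s, sample_rate) {
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  vib <- 0.003 * f0 / 4 * sin(2 * pi * 4 * t)    # ~0.3% vibrato at 4 Hz
  x <- sin(2 * pi * f0 * t + 2 * pi * vib) +
    0.35 * sin(2 * pi * 2 * f0 * t) +
    0.15 * sin(2 * pi * 3 * f0 * t)
  x <- x * .tukey(n, 0.25)
  x / max(abs(x))
}

#' Synthesize one adventitious event
#'
#' CAS classes yield a harmonic tone (fundamental at the class pitch with two
#' decaying harmonics and slow vibrato, tapered-cosine onset/offset); DAS
#' classes yield a damped sinusoid burst (pleural rub: a short train of 2-4
#' bursts). The fundamental is the centre of the class pitch range perturbed
#' by `jitter_pct` (and clamped to the range), so that with jitter disabled
#' the nominal class pitch is produced exactly; the event duration is
#' perturbed the same way. Peak amplitude is 1.
#'
#' @param spec A [class_spec()] (or a class token, converted internally).
#' @param sample_rate Sampling rate in Hz; must be at least four times the
#'   class's highest pitch (aliasing guard).
#' @param jitter_pct Percent perturbation of pitch and duration (default 5;
#'   0 disables jitter).
#' @param seed Optional RNG seed for a reproducible draw.
#' @return An [waveform()] with the class token as `label`.
#' @export
#' @examples
#' ev <- synthesize_event(class_spec("fine_crackle"), 8000, jitter_pct = 0)
#' peak_frequency(positive_fft(ev))  # 650 Hz
synthesize_event <- function(spec, sample_rate = 8000, jitter_pct = 5,
                             seed = NULL) {
  if (is.character(spec)) spec <- class_spec(spec)
  stopifnot(inherits(spec, "class_spec"))
  if (sample_rate < 4 * spec$f0_high) {
    stop("sample_rate ", sample_rate, " too low for class pitch ",
         spec$f0_high, " Hz (need >= 4x)")
  }
  if (!is.null(seed)) set.seed(seed)
  f0 <- .jitter((spec$f0_low + spec$f0_high) / 2, jitter_pct)
  f0 <- min(max(f0, spec$f0_low), spec$f0_high)
  dur <- .jitter(spec$event_duration_ms / 1000, jitter_pct)
  x <- if (spec$category == "CAS") {
    .cas_tone(f0, dur, sample_rate)
  } else if (spec$label == "pleural_rub") {
    n_bursts <- sample(2:4, 1)
    gap_s <- stats::runif(n_bursts - 1, 0.03, 0.08)
    parts <- lapply(seq_len(n_bursts), function(i) .das_burst(f0, dur, sample_rate))
    out <- parts[[1]]
    for (i in seq_along(gap_s)) {
      out <- c(out, numeric(round(gap_s[i] * sample_rate)), parts[[i + 1]])
    }
    out
  } else {
    .das_burst(f0, dur, sample_rate)
  }
  waveform(x, sample_rate, label = spec$label)
}

# offsets (s) at which events of this class start, within one breath cycle
.event_offsets <- function(spec, breath, event_s) {
  insp <- breath$inspiration_s
  exp_s <- breath$expiration_s
  place <- function(lo, hi, k) {
    hi <- max(lo, hi - event_s)
    stats::runif(k, lo, hi)
  }
  switch(spec$phase,
    inspiration = if (spec$category == "DAS") place(0, insp, 5L)
                  else place(0, insp, 1L),
    both = if (spec$category == "DAS") {
      c(place(0, insp, 1L), place(insp, insp + exp_s, 1L))
    } else {
      c(place(0, insp, 1L), place(insp, insp + exp_s, 1L))
    },
    early_inspiration_and_expiration =
      c(place(0, 0.4 * insp, 3L), place(insp, insp + exp_s, 2L)),
    stop("unknown phase: ", spec$phase))
}

#' Synthesize a labeled respiratory recording
#'
#' Generates `n_cycles` breath cycles of band-passed vesicular background
#' noise at `background_level`, mixes in class events at breath-phase
#' appropriate offsets (e.g. stridor only within inspiratory windows), and
#' peak-normalizes the result. Deterministic for a fixed seed.
#'
#' @param label Class token.
#' @param breath A [breath_model()].
#' @param config A [synth_config()] (its `sample_rate`, `n_cycles` and
#'   `jitter_pct` are used).
#' @param seed Optional RNG seed.
#' @return An [waveform()] with the class token as `label`.
#' @export
synthesize_recording <- function(label, breath = breath_model(),
                                 config = synth_config(), seed = NULL) {
  spec <- class_spec(label)
  if (!is.null(seed)) set.seed(seed)
  sr <- config$sample_rate
  cycle_s <- breath$inspiration_s + breath$expiration_s
  n <- round(config$n_cycles * cycle_s * sr)
  noise <- stats::rnorm(n)
  bf <- signal::butter(4, breath$vesicular_band_hz / (sr / 2), type = "pass")
  noise <- as.numeric(signal::filtfilt(bf, noise))
  x <- noise / max(abs(noise)) * breath$background_level
  for (cyc in seq_len(config$n_cycles)) {
    base <- (cyc - 1) * cycle_s
    ev_nominal <- spec$event_duration_ms / 1000 *
      (if (spec$label == "pleural_rub") 4 else 1)
    for (off in .event_offsets(spec, breath, ev_nominal)) {
      ev <- synthesize_event(spec, sr, config$jitter_pct)
      i0 <- round((base + off) * sr) + 1L
      i1 <- min(i0 + length(ev$samples) - 1L, n)
      seg <- seq.int(i0, i1)
      x[seg] <- x[seg] + ev$samples[seq_along(seg)]
    }
  }
  normalize_peak(waveform(x, sr, label = label))
}

#' Generate a labeled synthetic corpus
#'
#' Writes one WAV per requested recording plus a `manifest.csv` with columns
#' `path,label`. The default configuration emulates the reference corpus: 70
#' recordings with per-class counts wheeze 12, rhonchi 9, stridor 10, squawk
#' 8, fine crackle 11, coarse crackle 11, pleural rub 9. Byte-identical
#' output for identical configuration and seed.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @param breath A [breath_model()].
#' @return Path of the written manifest, invisibly.
#' @export
generate_dataset <- function(config = synth_config(), out_dir,
                             breath = breath_model()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  set.seed(config$seed)
  rows <- list()
  for (label in names(config$counts)) {
    k <- config$counts[[label]]
    for (i in seq_len(k)) {
      w <- synthesize_recording(label, breath, config)
      fn <- sprintf("%s_%03d.wav", label, i)
      write_wav(w, file.path(out_dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(path = fn, label = label)
    }
  }
  manifest <- file.path(out_dir, "manifest.csv")
  if (length(rows) == 0L) {
    warning("all counts are zero; writing an empty manifest")
    utils::write.csv(data.frame(path = character(), label = character()),
                     manifest, row.names = FALSE)
  } else {
    utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  }
  invisible(manifest)
}
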