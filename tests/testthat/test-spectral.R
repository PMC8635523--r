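test_that("wave_relations fills derivable fields from any valid pair", {
  p <- wave_relations(velocity = 340, wavelength = 1.7)
  expect_equal(p$frequency, 200)
  expect_equal(p$period, 1 / 200)
  q <- wave_relations(frequency = 0.5, velocity = 10)
  expect_equal(q$period, 2)
  expect_equal(q$wavelength, 20)
  r <- wave_relations(frequency = 4, period = 0.25)  # consistent pair
  expect_true(is.na(r$velocity))
  expect_error(wave_relations(frequency = 4, period = 0.3), "inconsistent")
  expect_error(wave_relations(period = 0, velocity = 3), "non-zero")
  expect_error(wave_relations(frequency = 1), "exactly two")
})

test_that("complete FFT is two-sided and conjugate-symmetric for real input", {
  w <- sine_wave(100, dur = 1, rate = 1000)
  s <- complete_fft(w)
  expect_identical(s$sidedness, "two_sided")
  expect_length(s$magnitudes, 1000)
  top <- s$frequencies[order(s$magnitudes, decreasing = TRUE)[1:2]]
  expect_setequal(top, c(-100, 100))
  pos <- s$magnitudes[s$frequencies > 0 & s$frequencies < 500]
  neg <- rev(s$magnitudes[s$frequencies < 0 & s$frequencies > -500])
  expect_equal(pos, neg, tolerance = 1e-12)
})

test_that("constant signal concentrates at the DC bin", {
  s <- complete_fft(waveform(rep(3, 64), 8000))
  expect_equal(s$magnitudes[s$frequencies == 0], 3 * 64)
  expect_lt(max(s$magnitudes[s$frequencies != 0]), 1e-9)
})

test_that("Parseval equality holds to 1e-9 relative on random signals", {
  set.seed(11)
  for (n in c(63, 256, 1000, 4096)) {
    w <- waveform(rnorm(n), 8000)
    s <- complete_fft(w)
    expect_equal(sum(s$magnitudes^2) / n, sum(w$samples^2),
                 tolerance = 1e-9)
  }
})

test_that("one-sided spectrum has floor(n/2)+1 bins matching the two-sided", {
  set.seed(12)
  for (n in c(17, 100, 1024)) {
    w <- waveform(rnorm(n), 8000)
    one <- positive_fft(w)
    two <- complete_fft(w)
    expect_length(one$magnitudes, floor(n / 2) + 1)
    m <- match(one$frequencies, two$frequencies)
    expect_lt(max(abs(one$magnitudes - two$magnitudes[m])), 1e-9)
  }
  expect_length(positive_fft(waveform(rnorm(1024), 8000))$magnitudes, 513)
})

test_that("peak_frequency ignores DC, breaks ties low, and guards", {
  w <- sine_wave(100, dur = 1, rate = 8000)
  expect_equal(peak_frequency(positive_fft(w)), 100)
  s <- positive_fft(w)
  s$magnitudes[] <- 0
  s$magnitudes[s$frequencies == 200] <- 5
  s$magnitudes[s$frequencies == 400] <- 5
  expect_equal(peak_frequency(s), 200)  # tie -> lower frequency
  s$magnitudes[] <- 0
  expect_error(peak_frequency(s), "non-zero")
  expect_error(peak_frequency(complete_fft(w)), "one-sided")
})

test_that("STFT frame count follows 1 + floor((n - window)/hop) exactly", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(300:2000, 1)
    win <- sample(16:256, 1)
    hop <- sample(seq_len(win), 1)
    w <- waveform(rnorm(n), 8000)
    sp <- stft_spectrogram(w, win, hop)
    expect_equal(nrow(sp$magnitudes), 1 + floor((n - win) / hop))
    expect_equal(ncol(sp$magnitudes), floor(win / 2) + 1)
  }
  w <- waveform(rnorm(256), 8000)
  expect_equal(nrow(stft_spectrogram(w, 256, 128)$magnitudes), 1)  # n == window
  expect_error(stft_spectrogram(w, 512), "pad")
  expect_error(stft_spectrogram(w, 128, 0), "positive")
})

test_that("stationary tones and chirps produce the expected STFT ridges", {
  w <- sine_wave(100, dur = 1, rate = 2000)   # 100 Hz == bin 10 of a
  sp <- stft_spectrogram(w, 200, 100)         # 200-sample window (10 Hz grid)
  peaks <- apply(sp$magnitudes[, -1], 1, function(m) sp$frequencies[-1][which.max(m)])
  expect_true(all(peaks == 100))
  # linear chirp 200 -> 600 Hz: frame-wise peaks (via the one-sided FFT of
  # each windowed frame, an independent path) are non-decreasing
  rate <- 4000
  t <- (0:(2 * rate - 1)) / rate
  chirp <- waveform(sin(2 * pi * (200 * t + 100 * t^2)), rate)
  sp <- stft_spectrogram(chirp, 256, 128, "hann")
  ridge <- numeric(nrow(sp$magnitudes))
  for (fr in seq_along(ridge)) {
    seg <- chirp$samples[((fr - 1) * 128 + 1):((fr - 1) * 128 + 256)]
    frame <- waveform(seg * anaspec:::.window("hann", 256), rate)
    ridge[fr] <- peak_frequency(positive_fft(frame))
    expect_equal(sp$magnitudes[fr, ], positive_fft(frame)$magnitudes,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_true(all(diff(ridge) >= 0))
})

test_that("STFT magnitudes agree with signal::specgram", {
  set.seed(14)
  w <- waveform(rnorm(2048), 8000)
  sp <- stft_spectrogram(w, 256, 128, "rectangular")
  ref <- signal::specgram(w$samples, n = 256, Fs = 8000,
                          window = rep(1, 256), overlap = 128)
  # specgram drops the Nyquist bin and the trailing frame; compare the
  # frames and bins the two framings share
  m <- match(round(ref$f, 6), round(sp$frequencies, 6))
  expect_false(anyNA(m))
  for (fr in seq_len(ncol(ref$S))) {
    expect_equal(sp$magnitudes[fr, m], abs(ref$S[, fr]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("ANA doubles magnitudes, quadruples energy, preserves ratios", {
  s <- positive_fft(sine_wave(100, 0.5))
  s$magnitudes <- c(1, 2, 3, rep(0, length(s$magnitudes) - 3))
  out <- apply_ana(s)
  expect_equal(out$magnitudes[1:3], c(2, 4, 6))
  set.seed(15)
  r <- positive_fft(waveform(rnorm(512), 8000))
  r2 <- apply_ana(r, gain = 2)
  expect_equal(sum(r2$magnitudes^2), 4 * sum(r$magnitudes^2), tolerance = 1e-12)
  nz <- r$magnitudes > 1e-12
  expect_equal(r2$magnitudes[nz] / r$magnitudes[nz],
               rep(2, sum(nz)), tolerance = 1e-12)
  z <- r; z$magnitudes[] <- 0
  expect_equal(apply_ana(z)$magnitudes, z$magnitudes)
  expect_error(apply_ana(r, gain = 0.5), ">= 1")
})

test_that("frequency-domain ANA equals time-domain amplitude doubling", {
  set.seed(16)
  w <- waveform(rnorm(300), 8000)
  doubled <- waveform(2 * w$samples, 8000)
  expect_equal(apply_ana(positive_fft(w), 2)$magnitudes,
               positive_fft(doubled)$magnitudes, tolerance = 1e-9)
})

test_that("envelope support measures event durations", {
  # rectangular burst of known length inside silence
  x <- numeric(800)
  x[101:300] <- sin(2 * pi * 440 * (0:199) / 8000)
  w <- waveform(x, 8000)
  expect_equal(envelope_support(w), 200 / 8000, tolerance = 0.05)
  expect_equal(envelope_support(waveform(numeric(10), 8000)), 0)
})
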