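test_that("class specifications carry the canonical acoustic constants", {
  fc <- class_spec("fine_crackle")
  expect_equal(fc$f0_low, 650)
  expect_equal(fc$event_duration_ms, 5)
  expect_identical(fc$category, "DAS")
  st <- class_spec("stridor")
  expect_gte(st$f0_low, 500)
  expect_gt(st$event_duration_ms, 250)
  expect_error(class_spec("asthma"), "wheeze")  # error lists the vocabulary
  # CAS/DAS duration dichotomy (squawk is the deliberate short-CAS exception)
  for (lb in class_vocabulary()) {
    sp <- class_spec(lb)
    expect_true(sp$f0_low <= sp$f0_high)
    if (sp$category == "DAS") expect_lte(sp$event_duration_ms, 25)
    if (sp$category == "CAS" && lb != "squawk") {
      expect_gte(sp$event_duration_ms, 80)
    }
  }
})

test_that("synthetic events hit their class pitch and duration", {
  for (lb in class_vocabulary()) {
    sp <- class_spec(lb)
    ev <- synthesize_event(sp, 8000, jitter_pct = 0, seed = 0)
    expect_equal(max(abs(ev$samples)), 1, tolerance = 1e-12)
    # pad to 1 s so every class is measured on a 1 Hz frequency grid
    pad <- waveform(c(ev$samples, numeric(max(0, 8000 - length(ev$samples)))),
                    8000)
    pf <- peak_frequency(positive_fft(pad))
    f0 <- (sp$f0_low + sp$f0_high) / 2
    if (lb == "pleural_rub") {
      # burst-train interference combs the spectrum; only the class band holds
      expect_gte(pf, sp$f0_low)
      expect_lte(pf, sp$f0_high)
    } else {
      expect_lt(abs(pf - f0), 0.02 * f0 + 2)
    }
    if (lb != "pleural_rub") {
      sup_ms <- 1000 * envelope_support(ev)
      expect_lt(abs(sup_ms - sp$event_duration_ms),
                0.2 * sp$event_duration_ms)
    }
  }
})

test_that("event envelope support stays within 20% of spec across jitter", {
  set.seed(21)
  for (lb in setdiff(class_vocabulary(), "pleural_rub")) {
    sp <- class_spec(lb)
    for (i in 1:5) {
      ev <- synthesize_event(sp, 8000, jitter_pct = 10)
      sup_ms <- 1000 * envelope_support(ev)
      # jitter moves the target duration itself by up to 10%
      expect_lt(abs(sup_ms - sp$event_duration_ms),
                0.2 * sp$event_duration_ms + 0.1 * sp$event_duration_ms)
    }
  }
})

test_that("pleural rub is a burst train with a low-pitched peak", {
  ev <- synthesize_event(class_spec("pleural_rub"), 8000, jitter_pct = 0,
                         seed = 0)
  expect_lte(peak_frequency(positive_fft(ev)), 350)
  # a train is longer than a single 15 ms burst
  expect_gt(wave_duration(ev), 0.03)
})

test_that("aliasing guard rejects too-low sample rates", {
  expect_error(synthesize_event(class_spec("stridor"), 3000), "4x")
})

test_that("dominant-frequency ordering separates the classes", {
  centre <- function(lb) {
    sp <- class_spec(lb)
    (sp$f0_low + sp$f0_high) / 2
  }
  expect_lt(centre("rhonchi"), centre("squawk"))
  expect_lte(centre("squawk"), centre("coarse_crackle"))
  expect_lt(class_spec("pleural_rub")$f0_high,
            class_spec("wheeze")$f0_low + 1)
  expect_lte(class_spec("wheeze")$f0_low, class_spec("stridor")$f0_low)
  expect_lt(class_spec("stridor")$f0_low, centre("fine_crackle"))
})

test_that("recordings are deterministic and events dominate the background", {
  a <- synthesize_recording("wheeze", seed = 5)
  b <- synthesize_recording("wheeze", seed = 5)
  expect_identical(a$samples, b$samples)
  c <- synthesize_recording("wheeze", seed = 6)
  expect_false(identical(a$samples, c$samples))
  # with background at 0.1 and events at 1, the STFT peak cell must sit in
  # an event's frequency band, not in the broadband background
  sp <- stft_spectrogram(a)
  peak <- arrayInd(which.max(sp$magnitudes), dim(sp$magnitudes))
  f_peak <- sp$frequencies[peak[2]]
  expect_gte(f_peak, class_spec("wheeze")$f0_low * 0.9)
  expect_lte(f_peak, class_spec("wheeze")$f0_high * 1.1)
})

test_that("stridor events fall inside inspiratory windows", {
  br <- breath_model()
  w <- synthesize_recording("stridor", breath = br, seed = 3)
  env <- amplitude_envelope(w)
  cyc <- br$inspiration_s + br$expiration_s
  strong <- which(env > 0.5) / w$sample_rate
  # allow the event's own duration past the inspiratory boundary
  lim <- br$inspiration_s + class_spec("stridor")$event_duration_ms / 1000 * 1.2
  expect_true(all((strong %% cyc) <= lim))
})

test_that("generate_dataset writes the configured corpus and manifest", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(counts = c(fine_crackle = 3, wheeze = 2), n_cycles = 1,
                      seed = 9)
  manifest <- generate_dataset(cfg, dir)
  df <- read.csv(manifest)
  expect_equal(nrow(df), 5)
  expect_equal(sum(df$label == "fine_crackle"), 3)
  expect_true(all(file.exists(file.path(dir, df$path))))
  # fine-crackle recordings keep their 650 Hz signature within jitter
  for (p in df$path[df$label == "fine_crackle"]) {
    w <- read_wav(file.path(dir, p))
    sp <- stft_spectrogram(w)
    peak <- arrayInd(which.max(sp$magnitudes), dim(sp$magnitudes))
    expect_lt(abs(sp$frequencies[peak[2]] - 650), 650 * 0.1 + 32)
  }
})

test_that("generated corpora are byte-identical for identical config + seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- synth_config(counts = c(rhonchi = 2), n_cycles = 1, seed = 4)
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  f1 <- file.path(d1, "rhonchi_002.wav"); f2 <- file.path(d2, "rhonchi_002.wav")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("zero counts produce an empty manifest with a warning", {
  dir <- withr::local_tempdir()
  expect_warning(m <- generate_dataset(synth_config(counts = c(wheeze = 0)),
                                       dir), "empty")
  expect_equal(nrow(read.csv(m)), 0)
})

test_that("synth_config validates counts and jitter", {
  expect_error(synth_config(counts = c(asthma = 2)), "vocabulary")
  expect_error(synth_config(jitter_pct = 80), "jitter")
})
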