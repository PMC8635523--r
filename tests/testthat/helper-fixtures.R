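# Shared fixtures and independent brute-force oracles.

sine_wave <- function(freq, dur = 1, rate = 8000, amp = 1) {
  waveform(amp * sin(2 * pi * freq * (seq_len(round(dur * rate)) - 1) / rate),
           rate)
}

# write a multi-channel 16-bit PCM WAV (the package writer is mono-only)
write_wav_multichannel <- function(channels, rate, path) {
  x <- as.vector(channels)  # interleave: frame-major (column per frame)
  pcm <- as.integer(round(pmin(1, pmax(-1, x)) * 32767))
  nch <- nrow(channels)
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")
  writeBin(nch, con, 2L, endian = "little")
  writeBin(as.integer(rate), con, 4L, endian = "little")
  writeBin(as.integer(rate) * 2L * nch, con, 4L, endian = "little")
  writeBin(2L * nch, con, 2L, endian = "little")
  writeBin(16L, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  path
}

# brute-force valid cross-correlation (nested loops)
xcorr_oracle <- function(img, kern) {
  oh <- nrow(img) - nrow(kern) + 1L
  ow <- ncol(img) - ncol(kern) + 1L
  out <- matrix(0, oh, ow)
  for (i in seq_len(oh)) {
    for (j in seq_len(ow)) {
      acc <- 0
      for (a in seq_len(nrow(kern))) {
        for (b in seq_len(ncol(kern))) {
          acc <- acc + img[i + a - 1L, j + b - 1L] * kern[a, b]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# brute-force classification metrics from an explicit confusion count
report_oracle <- function(truth, pred, vocab) {
  prec <- rec <- f1 <- sup <- numeric(length(vocab))
  for (k in seq_along(vocab)) {
    cls <- vocab[k]
    tp <- sum(truth == cls & pred == cls)
    fp <- sum(truth != cls & pred == cls)
    fn <- sum(truth == cls & pred != cls)
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) {
      2 * prec[k] * rec[k] / (prec[k] + rec[k])
    } else 0
    sup[k] <- sum(truth == cls)
  }
  list(precision = prec, recall = rec, f1 = f1, support = sup,
       accuracy = mean(truth == pred),
       macro = c(mean(prec), mean(rec), mean(f1)),
       weighted = c(sum(prec * sup), sum(rec * sup), sum(f1 * sup)) / sum(sup))
}

# a small flat-field test image carrying a label and id
flat_image <- function(value, h = 8, w = 8, label = "wheeze", id = "img1") {
  spectro_image(array(value, c(h, w, 1)), label = label, source_id = id)
}

# a labeled image set with the full 7-class vocabulary, n per class
tiny_image_set <- function(n_per_class = 2, h = 8, w = 8, seed = 42) {
  set.seed(seed)
  images <- list()
  for (cls in class_vocabulary()) {
    for (i in seq_len(n_per_class)) {
      px <- array(runif(h * w), c(h, w, 1))
      images[[length(images) + 1L]] <-
        spectro_image(px, label = cls, source_id = sprintf("%s_%d", cls, i))
    }
  }
  image_set(images)
}
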