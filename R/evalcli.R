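# Classification reports (per-class precision/recall/F1) and the
# end-to-end pipeline.

.round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Per-class classification report
#'
#' Computes, for each vocabulary class, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and their harmonic mean F1 (all reported as 0 when the
#' denominator vanishes), together with per-class support, overall accuracy,
#' and macro (unweighted) and weighted (support-weighted) averages -- the
#' standard report layout. The weighted recall average always equals the
#' accuracy. Classes absent from the truth vector are kept with zero
#' support and zero metrics and flagged in `zero_support`.
#'
#' @param true_labels,predicted_labels Equal-length character vectors of
#'   class tokens.
#' @param vocabulary Ordered class vocabulary (default [class_vocabulary()]).
#' @return An object of class `rs_report`: list with `per_class` (data frame
#'   `class, precision, recall, f1, support`), `accuracy`, `macro_avg`,
#'   `weighted_avg`, `zero_support`.
#' @export
#' @examples
#' compute_report(c("wheeze", "rhonchi"), c("wheeze", "rhonchi"))$accuracy
compute_report <- function(true_labels, predicted_labels,
                           vocabulary = class_vocabulary()) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length")
  }
  if (length(true_labels) == 0L) stop("label vectors must be non-empty")
  bad <- setdiff(unique(c(true_labels, predicted_labels)), vocabulary)
  if (length(bad) > 0) {
    stop("labels outside the vocabulary: ", paste(bad, collapse = ", "))
  }
  tf <- factor(true_labels, levels = vocabulary)
  pf <- factor(predicted_labels, levels = vocabulary)
  cm <- table(truth = tf, prediction = pf)
  tp <- diag(cm)
  support <- rowSums(cm)
  pred_n <- colSums(cm)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  accuracy <- sum(tp) / length(true_labels)
  wts <- support / sum(support)
  per_class <- data.frame(class = vocabulary,
                          precision = as.numeric(precision),
                          recall = as.numeric(recall),
                          f1 = as.numeric(f1),
                          support = as.integer(support),
                          row.names = NULL)
  structure(
    list(per_class = per_class,
         accuracy = accuracy,
         macro_avg = c(precision = mean(precision), recall = mean(recall),
                       f1 = mean(f1)),
         weighted_avg = c(precision = sum(wts * precision),
                          recall = sum(wts * recall),
                          f1 = sum(wts * f1)),
         zero_support = vocabulary[support == 0],
         confusion = cm),
    class = "rs_report"
  )
}

#' @export
print.rs_report <- function(x, ...) {
  cat(format_report(x))
  invisible(x)
}

#' Format a report in the tabular layout
#'
#' Class rows, then `Accuracy`, `Macro avg` and `Weighted avg`, with values
#' rounded half-up to 2 decimals.
#'
#' @param report An [compute_report()] result.
#' @return A single string.
#' @export
format_report <- function(report) {
  pc <- report$per_class
  fmt <- function(v) sprintf("%.2f", .round_half_up(v))
  lines <- c(
    sprintf("%-16s %9s %9s %9s %9s", "", "Precision", "Recall", "F1-score",
            "Support"),
    sprintf("%-16s %9s %9s %9s %9d", pc$class, fmt(pc$precision),
            fmt(pc$recall), fmt(pc$f1), pc$support),
    sprintf("%-16s %9s %9s %9s %9d", "Accuracy", "", "",
            fmt(report$accuracy), sum(pc$support)),
    sprintf("%-16s %9s %9s %9s %9d", "Macro avg",
            fmt(report$macro_avg["precision"]), fmt(report$macro_avg["recall"]),
            fmt(report$macro_avg["f1"]), sum(pc$support)),
    sprintf("%-16s %9s %9s %9s %9d", "Weighted avg",
            fmt(report$weighted_avg["precision"]),
            fmt(report$weighted_avg["recall"]),
            fmt(report$weighted_avg["f1"]), sum(pc$support))
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Export a classification report
#'
#' @param report An [compute_report()] result.
#' @param path Output path.
#' @param format `"json"` (full precision), `"csv"` (per-class table plus
#'   summary rows, full precision) or `"text"` (the printed table, 2
#'   decimals).
#' @return `path`.
#' @export
export_report <- function(report, path, format = c("json", "csv", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(per_class = report$per_class,
                    accuracy = report$accuracy,
                    macro_avg = as.list(report$macro_avg),
                    weighted_avg = as.list(report$weighted_avg),
                    zero_support = report$zero_support)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else if (format == "csv") {
    pc <- report$per_class
    extra <- data.frame(
      class = c("accuracy", "macro_avg", "weighted_avg"),
      precision = c(NA, report$macro_avg["precision"],
                    report$weighted_avg["precision"]),
      recall = c(NA, report$macro_avg["recall"],
                 report$weighted_avg["recall"]),
      f1 = c(report$accuracy, report$macro_avg["f1"],
             report$weighted_avg["f1"]),
      support = rep(sum(pc$support), 3))
    utils::write.csv(rbind(pc, extra), path, row.names = FALSE)
  } else {
    writeLines(format_report(report), path)
  }
  path
}

#' Import a JSON report written by [export_report()]
#' @param path JSON path.
#' @return An `rs_report` (without the confusion matrix).
#' @export
import_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(per_class = x$per_class, accuracy = x$accuracy,
                 macro_avg = unlist(x$macro_avg),
                 weighted_avg = unlist(x$weighted_avg),
                 zero_support = as.character(x$zero_support %||% character()),
                 confusion = NULL),
            class = "rs_report")
}

#' Pipeline configuration
#'
#' @param synth A [synth_config()] used to generate the corpus, or `NULL`
#'   when `manifest` points at existing WAV files.
#' @param manifest Path to a `path,label` CSV manifest of WAV recordings
#'   (paths relative to the manifest's directory), or `NULL` to synthesize.
#' @param sample_rate Canonical rate all audio is resampled to (default
#'   8000 Hz).
#' @param ana Apply ANA enhancement to every spectrogram (default `TRUE`).
#' @param gain ANA gain (default 2).
#' @param window_length,hop_length,window_kind STFT parameters
#'   (see [stft_spectrogram()]).
#' @param colormap Rendering palette (default `"viridis"`).
#' @param freq_max Upper frequency limit (Hz) of the rendered band (default
#'   2000: all seven class fundamentals and their first harmonics lie below
#'   it, so the image's vertical resolution is spent where the classes
#'   differ; `NULL` renders the full half-band).
#' @param intensity_mode `"fixed"` (default): render against an absolute
#'   ceiling calibrated as the maximum spectrogram magnitude of the training
#'   partition, so ANA genuinely brightens; or `"per_image_max"`.
#' @param image_size Rendered image `c(height, width)`; defaults to the
#'   architecture's input profile.
#' @param architecture,profile,epochs,learning_rate,momentum,batch_size
#'   Training parameters (see [cnn_config()]).
#' @param train_fraction,stratified Split parameters (see
#'   [split_dataset()]).
#' @param augment Apply horizontal-flip doubling to the training partition
#'   (default `TRUE`; the test partition is never augmented).
#' @param seed Master seed for corpus generation, splitting and training.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), manifest = NULL,
                            sample_rate = 8000, ana = TRUE, gain = 2,
                            window_length = 256L,
                            hop_length = window_length %/% 2L,
                            window_kind = "hann", colormap = "viridis",
                            freq_max = 2000,
                            intensity_mode = c("fixed", "per_image_max"),
                            image_size = NULL, architecture = "vgg_small",
                            profile = "fast", epochs = 100L,
                            learning_rate = 1e-3, momentum = 0.9,
                            batch_size = 8L, train_fraction = 0.7,
                            stratified = TRUE, augment = TRUE, seed = 0L) {
  intensity_mode <- match.arg(intensity_mode)
  if (is.null(synth) && is.null(manifest)) {
    stop("config must name either a WAV manifest or the synthetic generator")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

.log_stage <- function(log_path, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 sprintf(fmt, ...))
  message(msg)
  cat(msg, "\n", file = log_path, append = TRUE)
}

# load a manifest of WAVs into waveforms at the canonical rate, dropping
# exact duplicate files (by content hash)
.load_corpus <- function(manifest, sample_rate, log_path) {
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  paths <- ifelse(file.exists(df$path), df$path, file.path(base, df$path))
  hashes <- tools::md5sum(paths)
  dup <- duplicated(hashes)
  if (any(dup)) {
    .log_stage(log_path, "dropping %d duplicate recording(s)", sum(dup))
    df <- df[!dup, , drop = FALSE]
    paths <- paths[!dup]
  }
  lapply(seq_along(paths), function(i) {
    w <- read_wav(paths[i], label = df$label[i])
    if (w$sample_rate != sample_rate) w <- resample_wave(w, sample_rate)
    w <- normalize_peak(w)
    w$source_id <- basename(paths[i])
    w
  })
}

#' Run the end-to-end classification pipeline
#'
#' Synthesize (or load) the corpus, preprocess, compute STFT spectrograms,
#' optionally apply ANA, render images against a training-set-calibrated
#' intensity ceiling, split 70/30 stratified, flip-augment the training
#' partition, train the configured network, and evaluate on the held-out
#' partition. All artifacts (manifests, history CSV, report in JSON and
#' text form, config snapshot and a timestamped log) are written under
#' `out_dir`; the run is reproducible from the config and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Artifact directory (created if needed).
#' @return A list of class `pipeline_result`: `report` (an `rs_report`),
#'   `model` (a `cnn_model`, with `history`), `split`, and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  stage <- "setup"
  result <- tryCatch({
    jsonlite::write_json(config[!vapply(config, is.null, logical(1))],
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, force = TRUE)
    stage <- "synth"
    manifest <- config$manifest
    if (is.null(manifest)) {
      sc <- config$synth
      sc$seed <- config$seed
      wav_dir <- file.path(out_dir, "wav")
      .log_stage(log_path, "synthesizing corpus (seed %d)", config$seed)
      manifest <- generate_dataset(sc, wav_dir)
    }
    stage <- "preprocess"
    waves <- .load_corpus(manifest, config$sample_rate, log_path)
    labels <- vapply(waves, function(w) w$label, character(1))
    .log_stage(log_path, "loaded %d recordings", length(waves))

    stage <- "stft"
    specs <- lapply(waves, function(w) {
      stft_spectrogram(w, config$window_length, config$hop_length,
                       config$window_kind)
    })
    if (isTRUE(config$ana)) {
      stage <- "ana"
      specs <- lapply(specs, apply_ana, gain = config$gain)
      .log_stage(log_path, "applied ANA (gain %g)", config$gain)
    }

    stage <- "split"
    train_idx <- .split_indices(labels, config$train_fraction, config$seed,
                                config$stratified)
    stage <- "render"
    image_size <- config$image_size
    if (is.null(image_size)) {
      image_size <- default_input_size(config$architecture, config$profile)[1:2]
    }
    ref <- if (config$intensity_mode == "fixed") {
      max(vapply(specs[train_idx], function(s) max(s$magnitudes), numeric(1)))
    } else {
      "per_image_max"
    }
    images <- lapply(seq_along(specs), function(i) {
      img <- render_spectrogram_image(specs[[i]], colormap = config$colormap,
                                      intensity_ref = ref,
                                      out_size = image_size,
                                      freq_max = config$freq_max)
      img$label <- labels[i]
      img$source_id <- waves[[i]]$source_id
      img
    })
    all_set <- image_set(images)
    test_idx <- setdiff(seq_along(images), train_idx)
    split <- structure(
      list(train = image_set(images[sort(train_idx)], all_set$vocabulary),
           test = image_set(images[sort(test_idx)], all_set$vocabulary),
           train_fraction = config$train_fraction, seed = config$seed,
           stratified = config$stratified),
      class = "rs_split")
    write_split_manifest(split, file.path(out_dir, "split.csv"))
    .log_stage(log_path, "split: %d train / %d test",
               length(split$train$images), length(split$test$images))

    stage <- "augment"
    if (isTRUE(config$augment)) {
      split$train <- augment_set(split$train)
      .log_stage(log_path, "augmented training partition to %d images",
                 length(split$train$images))
    }

    stage <- "train"
    cfg <- cnn_config(architecture = config$architecture,
                      profile = config$profile,
                      n_classes = length(all_set$vocabulary),
                      epochs = config$epochs,
                      learning_rate = config$learning_rate,
                      momentum = config$momentum,
                      batch_size = config$batch_size, seed = config$seed)
    .log_stage(log_path, "training %s for %d epochs (seed %d)",
               config$architecture, config$epochs, config$seed)
    model <- train_cnn(split, cfg)
    write_history_csv(model, file.path(out_dir, "history.csv"))
    suppressMessages(ggplot2::ggsave(file.path(out_dir, "history.png"),
                                     plot_history(model),
                                     width = 8, height = 4, dpi = 120))

    stage <- "evaluate"
    pred <- predict(model, split$test)
    report <- compute_report(set_labels(split$test), pred$labels,
                             all_set$vocabulary)
    export_report(report, file.path(out_dir, "report.json"), "json")
    export_report(report, file.path(out_dir, "report.txt"), "text")
    .log_stage(log_path, "held-out accuracy %.3f", report$accuracy)
    structure(list(report = report, model = model, split = split,
                   out_dir = out_dir),
              class = "pipeline_result")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s, held-out accuracy %.3f (artifacts: %s)\n",
              x$model$architecture, x$report$accuracy, x$out_dir))
  invisible(x)
}
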