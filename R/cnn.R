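# Architecture registry, shape audit, training and prediction.

.layer <- function(kind, filters = 0L, kernel = c(0L, 0L), stride = c(1L, 1L),
                   padding = "valid", units = 0L, activation = "relu") {
  list(kind = kind, filters = as.integer(filters),
       kernel = as.integer(kernel), stride = as.integer(stride),
       padding = padding, units = as.integer(units), activation = activation)
}

conv_layer <- function(filters, kernel, stride = 1L, padding = "valid") {
  .layer("conv", filters = filters, kernel = rep(kernel, length.out = 2),
         stride = rep(stride, length.out = 2), padding = padding)
}
pool_layer <- function(kernel = 2L, stride = 2L) {
  .layer("maxpool", kernel = rep(kernel, length.out = 2),
         stride = rep(stride, length.out = 2))
}
dense_layer <- function(units, activation = "relu") {
  .layer("dense", units = units, activation = activation)
}

#' Build a registered network architecture
#'
#' Three architectures are registered. `"alexnet_paper"` is the AlexNet
#' variant taken layer-for-layer from its published description: conv(96,
#' 11x11, stride 4, valid) - maxpool(2x2, stride 2) - conv(256, 11x11,
#' stride 2, valid) - maxpool - conv(384, 3x3) - conv(384, 3x3) - conv(256,
#' 3x3) - maxpool - flatten - dense(4096) - dense(4096) - dense(n_classes,
#' softmax). Note the 11x11 stride-2 second convolution (canonical AlexNet
#' uses 5x5 stride 1); the three 3x3 convolutions use same-padding, without
#' which the stack is not constructible on any input. `"lenet5"` is the
#' classical LeNet-5 stack; `"vgg_small"` a compact three-block VGG-style
#' net (2 x conv3x3-32, 2 x conv3x3-64, 2 x conv3x3-128, each block
#' max-pooled, then dense 256).
#'
#' @param name One of `"alexnet_paper"`, `"lenet5"`, `"vgg_small"`.
#' @param n_classes Number of output classes (default 7).
#' @param dense_units Widths of the fully connected hidden layers of
#'   `alexnet_paper` (default `c(4096, 4096)`).
#' @return A list of layer specifications (class `cnn_layers`).
#' @export
#' @examples
#' arch <- build_architecture("alexnet_paper")
#' length(arch)  # 12 layers: 5 conv + 3 pool + flatten + 3 dense
build_architecture <- function(name, n_classes = 7L,
                               dense_units = c(4096L, 4096L)) {
  registry <- c("alexnet_paper", "lenet5", "vgg_small")
  if (!name %in% registry) {
    stop("unknown architecture '", name, "'; registered: ",
         paste(registry, collapse = ", "))
  }
  layers <- switch(name,
    alexnet_paper = list(
      conv_layer(96, 11, 4, "valid"),
      pool_layer(2, 2),
      conv_layer(256, 11, 2, "valid"),
      pool_layer(2, 2),
      conv_layer(384, 3, 1, "same"),
      conv_layer(384, 3, 1, "same"),
      conv_layer(256, 3, 1, "same"),
      pool_layer(2, 2),
      .layer("flatten"),
      dense_layer(dense_units[1]),
      dense_layer(dense_units[2]),
      dense_layer(n_classes, "softmax")
    ),
    lenet5 = list(
      conv_layer(6, 5, 1, "same"),
      pool_layer(2, 2),
      conv_layer(16, 5, 1, "valid"),
      pool_layer(2, 2),
      .layer("flatten"),
      dense_layer(120),
      dense_layer(84),
      dense_layer(n_classes, "softmax")
    ),
    vgg_small = list(
      conv_layer(32, 3, 1, "same"),
      conv_layer(32, 3, 1, "same"),
      pool_layer(2, 2),
      conv_layer(64, 3, 1, "same"),
      conv_layer(64, 3, 1, "same"),
      pool_layer(2, 2),
      conv_layer(128, 3, 1, "same"),
      conv_layer(128, 3, 1, "same"),
      pool_layer(2, 2),
      .layer("flatten"),
      dense_layer(256),
      dense_layer(n_classes, "softmax")
    ))
  structure(layers, class = "cnn_layers", architecture = name)
}

#' Default input sizes per architecture
#'
#' The `"full"` profile uses the canonical 227x227 input for
#' `alexnet_paper` (so its stride-4 11x11 first convolution yields the
#' classical 55x55 map), 32x32 for `lenet5` and 96x96 for `vgg_small`. The
#' `"fast"` profile is the desk-scale (single-CPU) experiment profile:
#' 48x48 for `vgg_small`, 32x32 for `lenet5`, and 144x144 for
#' `alexnet_paper` -- the smallest even input on which its layer stack is
#' constructible (the 11x11 stride-2 second convolution needs a 17x17
#' pooled map to survive the later pools). Under the fast profile,
#' `alexnet_paper` also narrows its two hidden fully connected layers from
#' 4096 to 1024 units (the widths are configurable; see
#' [build_architecture()]).
#'
#' @param name Registered architecture name.
#' @param profile `"full"` or `"fast"`.
#' @param channels Number of image channels (default 3).
#' @return Integer `c(height, width, channels)`.
#' @export
default_input_size <- function(name, profile = c("full", "fast"),
                               channels = 3L) {
  profile <- match.arg(profile)
  hw <- switch(name,
    alexnet_paper = if (profile == "full") 227L else 144L,
    lenet5 = 32L,
    vgg_small = if (profile == "full") 96L else 48L,
    stop("unknown architecture '", name, "'"))
  c(hw, hw, as.integer(channels))
}

#' Per-layer output dimensions
#'
#' Audits a layer stack against an input size using the standard shape
#' arithmetic: valid convolution/pooling gives `floor((in - kernel)/stride)
#' + 1` per axis, same-padding gives `ceil(in/stride)`. An error is raised
#' before any layer would produce a non-positive dimension.
#'
#' @param layers A [build_architecture()] result.
#' @param input_size Integer `c(height, width, channels)`.
#' @return Data frame with one row per stage (input plus each layer):
#'   `layer`, `kind`, `height`, `width`, `channels`.
#' @export
output_shape <- function(layers, input_size) {
  h <- input_size[1]; w <- input_size[2]; c <- input_size[3]
  rows <- data.frame(layer = 0L, kind = "input", height = h, width = w,
                     channels = c)
  for (l in seq_along(layers)) {
    d <- layers[[l]]
    if (d$kind %in% c("conv", "maxpool")) {
      if (d$padding == "same") {
        oh <- ceiling(h / d$stride[1]); ow <- ceiling(w / d$stride[2])
      } else {
        oh <- floor((h - d$kernel[1]) / d$stride[1]) + 1
        ow <- floor((w - d$kernel[2]) / d$stride[2]) + 1
      }
      if (oh < 1 || ow < 1) {
        stop("layer ", l, " (", d$kind, ") produces a non-positive dimension ",
             "on a ", input_size[1], "x", input_size[2], " input")
      }
      h <- oh; w <- ow
      if (d$kind == "conv") c <- d$filters
    } else if (d$kind == "flatten") {
      c <- h * w * c; h <- 1; w <- 1
    } else {
      c <- d$units; h <- 1; w <- 1
    }
    rows <- rbind(rows, data.frame(layer = l, kind = d$kind, height = h,
                                   width = w, channels = c))
  }
  rows
}

#' Training configuration
#'
#' @param architecture Registered architecture name.
#' @param input_size `c(height, width, channels)`; defaults to the
#'   architecture's profile default ([default_input_size()]).
#' @param profile `"full"` or `"fast"` input profile.
#' @param n_classes Number of classes (default 7).
#' @param epochs Training epochs (default 500).
#' @param learning_rate SGD learning rate (default 1e-3).
#' @param momentum SGD momentum (default 0.9).
#' @param batch_size Mini-batch size (default 8).
#' @param seed RNG seed for weight initialization and batch shuffling.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(architecture = "alexnet_paper", input_size = NULL,
                       profile = "fast", n_classes = 7L, epochs = 500L,
                       learning_rate = 1e-3, momentum = 0.9, batch_size = 8L,
                       seed = 0L) {
  if (is.null(input_size)) {
    input_size <- default_input_size(architecture, profile)
  }
  stopifnot(n_classes >= 2, epochs >= 1, learning_rate > 0, batch_size >= 1)
  structure(list(architecture = architecture, profile = profile,
                 input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

# stack an image set into an (h, w, c, N) array, resizing and centering
.set_to_array <- function(set, input_size) {
  n <- length(set$images)
  X <- array(0, c(input_size[1], input_size[2], input_size[3], n))
  for (i in seq_len(n)) {
    px <- set$images[[i]]$pixels
    nc <- dim(px)[3]
    for (ch in seq_len(input_size[3])) {
      src <- px[, , min(ch, nc)]
      X[, , ch, i] <- .resize2d(src, input_size[1], input_size[2])
    }
  }
  X - 0.5  # center pixel intensities
}

#' Train a convolutional network on a dataset split
#'
#' Minimizes the multi-class cross-entropy with mini-batch stochastic
#' gradient descent with momentum, recording training and held-out accuracy
#' and loss every epoch. Deterministic for a fixed seed (the backend is
#' single-threaded single-precision).
#'
#' @param split An [split_dataset()] result (train images are fitted;
#'   test images provide the per-epoch validation curve).
#' @param config A [cnn_config()].
#' @param layers Layer stack; defaults to
#'   `build_architecture(config$architecture, config$n_classes)`.
#' @return A list of class `cnn_model` with `weights`, `layers`,
#'   `architecture`, `vocabulary`, `config` and `history` (a data frame
#'   `epoch, train_accuracy, train_loss, val_accuracy, val_loss`).
#' @export
train_cnn <- function(split, config, layers = NULL) {
  stopifnot(inherits(split, "rs_split"), inherits(config, "cnn_config"))
  if (is.null(layers)) {
    dense_units <- if (identical(config$architecture, "alexnet_paper") &&
                         identical(config$profile, "fast")) {
      c(1024L, 1024L)
    } else {
      c(4096L, 4096L)
    }
    layers <- build_architecture(config$architecture, config$n_classes,
                                 dense_units = dense_units)
  }
  vocab <- split$train$vocabulary
  ytr <- match(set_labels(split$train), vocab) - 1L
  yte <- match(set_labels(split$test), vocab) - 1L
  missing_cls <- setdiff(vocab, set_labels(split$train))
  if (length(missing_cls) > 0 && length(missing_cls) < length(vocab)) {
    stop("classes absent from the training partition: ",
         paste(missing_cls, collapse = ", "))
  }
  Xtr <- .set_to_array(split$train, config$input_size)
  Xte <- .set_to_array(split$test, config$input_size)
  fit <- cnn_train_cpp(unclass(layers), Xtr, ytr, Xte, yte,
                       config$n_classes, config$epochs, config$learning_rate,
                       config$momentum, config$batch_size, config$seed)
  history <- data.frame(epoch = seq_len(config$epochs),
                        train_accuracy = fit$train_accuracy,
                        train_loss = fit$train_loss,
                        val_accuracy = fit$val_accuracy,
                        val_loss = fit$val_loss)
  structure(list(weights = fit$weights, layers = layers,
                 architecture = config$architecture, vocabulary = vocab,
                 config = config, history = history),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  h <- x$history
  cat(sprintf(paste0("<cnn_model> %s, %d epochs; final train acc %.3f, ",
                     "held-out acc %.3f\n"),
              x$architecture, nrow(h), h$train_accuracy[nrow(h)],
              h$val_accuracy[nrow(h)]))
  invisible(x)
}

#' Predict class probabilities for spectrogram images
#'
#' @param object A [train_cnn()] model.
#' @param newdata A single [spectro_image()], a list of them, or an
#'   [image_set()].
#' @param ... Unused.
#' @return A list with `labels` (predicted class tokens, the per-row argmax)
#'   and `probabilities` (matrix, rows summing to 1 over the vocabulary).
#' @export
predict.cnn_model <- function(object, newdata, ...) {
  images <- if (inherits(newdata, "rs_image")) list(newdata)
            else if (inherits(newdata, "rs_image_set")) newdata$images
            else newdata
  dummy <- list(images = images, vocabulary = object$vocabulary)
  X <- .set_to_array(dummy, object$config$input_size)
  probs <- cnn_predict_cpp(unclass(object$layers), object$weights, X)
  colnames(probs) <- object$vocabulary
  list(labels = object$vocabulary[max.col(probs, ties.method = "first")],
       probabilities = probs)
}

#' Runtime shape audit of a layer stack
#'
#' Executes one real forward pass through the training backend and returns
#' the tensor dimensions it actually produced, for cross-checking against
#' [output_shape()].
#'
#' @inheritParams output_shape
#' @return Data frame like [output_shape()]'s.
#' @export
backend_shapes <- function(layers, input_size) {
  m <- cnn_shapes_cpp(unclass(layers), input_size[1], input_size[2],
                      input_size[3])
  data.frame(layer = seq_len(nrow(m)) - 1L,
             kind = c("input", vapply(layers, `[[`, "", "kind")),
             height = m[, 1], width = m[, 2], channels = m[, 3])
}

#' Export a training history as CSV
#'
#' @param model A [train_cnn()] model (or a history data frame).
#' @param path Output CSV path.
#' @return `path`.
#' @export
write_history_csv <- function(model, path) {
  h <- if (inherits(model, "cnn_model")) model$history else model
  utils::write.csv(h, path, row.names = FALSE)
  path
}

#' Plot accuracy and loss training curves
#'
#' Mirrors the usual paired "model accuracy" / "model loss" panels: per-epoch
#' training and validation accuracy, and the same for loss.
#'
#' @param model A [train_cnn()] model (or a history data frame).
#' @return A ggplot object (two facets: accuracy and loss).
#' @export
plot_history <- function(model) {
  h <- if (inherits(model, "cnn_model")) model$history else model
  long <- rbind(
    data.frame(epoch = h$epoch, panel = "accuracy", series = "train",
               value = h$train_accuracy),
    data.frame(epoch = h$epoch, panel = "accuracy", series = "validation",
               value = h$val_accuracy),
    data.frame(epoch = h$epoch, panel = "loss", series = "train",
               value = h$train_loss),
    data.frame(epoch = h$epoch, panel = "loss", series = "validation",
               value = h$val_loss)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = epoch, y = value,
                                     colour = series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Save / load a trained model
#'
#' The fitted parameters are serialized with [saveRDS()]; a human-readable
#' JSON sidecar (`<path>.json`) records the architecture name, class
#' vocabulary and training configuration.
#'
#' @param model A [train_cnn()] model.
#' @param path Output `.rds` path.
#' @return `path` (for `save_model`); the restored `cnn_model` (for
#'   `load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cnn_model"))
  saveRDS(model, path)
  sidecar <- list(architecture = model$architecture,
                  class_vocabulary = model$vocabulary,
                  config = model$config[c("input_size", "n_classes", "epochs",
                                          "learning_rate", "momentum",
                                          "batch_size", "seed")])
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  path
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cnn_model")) stop("not a saved cnn_model: ", path)
  model
}
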