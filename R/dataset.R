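# Labeled image sets, augmentation and the stratified train/test split.

#' Construct a labeled spectrogram-image set
#'
#' @param images List of [spectro_image()] objects; each must carry a label
#'   from `vocabulary` and a unique `source_id`.
#' @param vocabulary Ordered class vocabulary (default [class_vocabulary()]).
#' @return An object of class `rs_image_set`.
#' @export
image_set <- function(images, vocabulary = class_vocabulary()) {
  labels <- vapply(images, function(x) x$label %||% NA_character_, character(1))
  ids <- vapply(images, function(x) x$source_id %||% NA_character_, character(1))
  if (anyNA(labels) || !all(labels %in% vocabulary)) {
    stop("every image must carry a label from the vocabulary")
  }
  if (anyNA(ids) || anyDuplicated(ids)) {
    stop("every image must carry a unique source_id")
  }
  structure(list(images = images, vocabulary = vocabulary),
            class = "rs_image_set")
}

#' @export
print.rs_image_set <- function(x, ...) {
  tab <- table(factor(set_labels(x), levels = x$vocabulary))
  cat(sprintf("<rs_image_set> %d images: %s\n", length(x$images),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Labels of an image set
#' @param set An [image_set()].
#' @return Character vector of class tokens, one per image.
#' @export
set_labels <- function(set) {
  vapply(set$images, function(x) x$label, character(1))
}

#' Source identifiers of an image set
#' @param set An [image_set()].
#' @return Character vector of `source_id`s.
#' @export
set_source_ids <- function(set) {
  vapply(set$images, function(x) x$source_id, character(1))
}

#' Flip a spectrogram image left-to-right
#'
#' Reverses the pixel columns (the time axis) and toggles the `flipped`
#' flag; dimensions and all other metadata are unchanged. Applying the flip
#' twice restores the original image.
#'
#' @param image An [spectro_image()].
#' @return The flipped `rs_image`.
#' @export
horizontal_flip <- function(image) {
  stopifnot(inherits(image, "rs_image"))
  image$pixels <- image$pixels[, rev(seq_len(dim(image$pixels)[2])), , drop = FALSE]
  image$flipped <- !isTRUE(image$flipped)
  image
}

#' Augment an image set by horizontal flipping
#'
#' Returns the original images plus one horizontally flipped copy of each,
#' exactly doubling the cardinality; labels are preserved and flipped copies
#' carry derived source ids (`<id>#flip`). Intended for the training
#' partition only -- augmenting the test partition would inflate metrics.
#'
#' @param set A non-empty [image_set()].
#' @param mode `"all"` (default, deterministic doubling) or `"random"`:
#'   append a flipped copy of each image independently with probability 1/2.
#' @return The augmented `rs_image_set`.
#' @export
augment_set <- function(set, mode = c("all", "random")) {
  stopifnot(inherits(set, "rs_image_set"))
  mode <- match.arg(mode)
  if (length(set$images) == 0L) stop("cannot augment an empty set")
  keep <- if (mode == "all") rep(TRUE, length(set$images))
          else stats::runif(length(set$images)) < 0.5
  flipped <- lapply(set$images[keep], function(img) {
    out <- horizontal_flip(img)
    out$source_id <- paste0(img$source_id, "#flip")
    out
  })
  image_set(c(set$images, flipped), set$vocabulary)
}

# seeded index-level split shared by split_dataset() and the pipeline
.split_indices <- function(labels, train_fraction, seed, stratified) {
  set.seed(seed)
  if (stratified) {
    train_idx <- integer(0)
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < 2L) {
        stop("class '", cls, "' has fewer than 2 items; cannot stratify")
      }
      n_train <- floor(length(idx) * train_fraction + 0.5)  # round half up
      n_train <- min(n_train, length(idx) - 1L)             # >= 1 test item
      n_train <- max(n_train, 1L)
      train_idx <- c(train_idx, sample(idx)[seq_len(n_train)])
    }
    train_idx
  } else {
    n_train <- floor(length(labels) * train_fraction + 0.5)
    n_train <- min(max(n_train, 1L), length(labels) - 1L)
    sample(seq_along(labels))[seq_len(n_train)]
  }
}

#' Stratified train/test split
#'
#' Splits per class: `round(count * train_fraction)` items (round-half-up)
#' go to training, the remainder to test, with at least one test item per
#' class enforced; membership is chosen by a seeded shuffle. With the
#' default 70-recording corpus and `train_fraction = 0.7` this yields the
#' canonical 49/21 partition. Set `stratified = FALSE` for a plain random
#' split of the pooled items.
#'
#' @param set An [image_set()]; under stratification every class present
#'   must have at least 2 items.
#' @param train_fraction Proportion of items assigned to training, in
#'   (0, 1) (default 0.7).
#' @param seed RNG seed for the shuffle.
#' @param stratified Stratify by class (default `TRUE`).
#' @return A list of class `rs_split` with `train` and `test`
#'   [image_set()]s, plus the split parameters.
#' @export
split_dataset <- function(set, train_fraction = 0.7, seed = 0,
                          stratified = TRUE) {
  stopifnot(inherits(set, "rs_image_set"))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  labels <- set_labels(set)
  train_idx <- .split_indices(labels, train_fraction, seed, stratified)
  test_idx <- setdiff(seq_along(labels), train_idx)
  structure(
    list(train = image_set(set$images[sort(train_idx)], set$vocabulary),
         test = image_set(set$images[sort(test_idx)], set$vocabulary),
         train_fraction = train_fraction, seed = seed,
         stratified = stratified),
    class = "rs_split"
  )
}

#' @export
print.rs_split <- function(x, ...) {
  cat(sprintf("<rs_split> %d train / %d test (fraction %.2f, %s)\n",
              length(x$train$images), length(x$test$images),
              x$train_fraction,
              if (x$stratified) "stratified" else "unstratified"))
  invisible(x)
}

#' Write a split membership manifest
#'
#' @param split An [split_dataset()] result.
#' @param path Output CSV path (columns `source_id,label,partition`).
#' @return `path`.
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "rs_split"))
  df <- rbind(
    data.frame(source_id = set_source_ids(split$train),
               label = set_labels(split$train), partition = "train"),
    data.frame(source_id = set_source_ids(split$test),
               label = set_labels(split$test), partition = "test")
  )
  utils::write.csv(df, path, row.names = FALSE)
  path
}
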