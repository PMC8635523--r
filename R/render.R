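# Spectrogram image rendering and image-domain feature operations.

#' Construct a spectrogram image object
#'
#' @param pixels Numeric array `height x width x channels` with intensities
#'   in \[0, 1\] (a matrix is treated as a single channel).
#' @param colormap Name of the colormap used (or `"gray"`).
#' @param intensity_ref Either the absolute magnitude ceiling the image was
#'   rendered against, or the string `"per_image_max"`.
#' @param flipped Whether the image has been horizontally flipped.
#' @param label,source_id Optional class token and provenance string.
#' @return An object of class `rs_image`.
#' @export
spectro_image <- function(pixels, colormap = "gray",
                          intensity_ref = "per_image_max",
                          flipped = FALSE, label = NULL, source_id = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  stopifnot(length(dim(pixels)) == 3L, all(dim(pixels) > 0L))
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9) {
    stop("pixel intensities must lie in [0, 1]")
  }
  structure(list(pixels = pixels, colormap = colormap,
                 intensity_ref = intensity_ref, flipped = flipped,
                 label = label, source_id = source_id),
            class = "rs_image")
}

#' @export
print.rs_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rs_image> %dx%dx%d (%s)%s%s\n", d[1], d[2], d[3], x$colormap,
              if (isTRUE(x$flipped)) " flipped" else "",
              if (is.null(x$label)) "" else paste0(" label=", x$label)))
  invisible(x)
}

# bilinear 2-D resize of a matrix (delegates to EBImage)
.resize2d <- function(m, out_h, out_w) {
  if (nrow(m) == out_h && ncol(m) == out_w) return(m)
  as.matrix(EBImage::resize(m, w = out_h, h = out_w, filter = "bilinear"))
}

.colormap_lut <- function(name, n = 256L) {
  cols <- if (identical(name, "gray")) grDevices::gray(seq(0, 1, length.out = n))
          else grDevices::hcl.colors(n, palette = name)
  t(grDevices::col2rgb(cols) / 255)
}

#' Render a spectrogram as an image
#'
#' Magnitudes are log-scaled (`20*log10`, floored 80 dB below the ceiling),
#' mapped to \[0, 1\] against `intensity_ref`, colored, and bilinearly
#' resized. Time runs left to right and frequency bottom to top.
#'
#' `intensity_ref` controls how ANA-enhanced spectrograms render: under the
#' default per-image maximum, rendering is invariant to any overall gain
#' (ANA is annihilated); under a fixed absolute ceiling -- the pipeline's
#' choice, calibrated on the training set -- a gained spectrogram renders
#' pointwise at least as bright.
#'
#' @param spec An `rs_spectrogram` (from [stft_spectrogram()]).
#' @param colormap A palette name accepted by [grDevices::hcl.colors()], or
#'   `"gray"` (default `"viridis"`).
#' @param intensity_ref `"per_image_max"` (default) or a positive number:
#'   the absolute magnitude rendered as full intensity (values above are
#'   clipped).
#' @param out_size Target `c(height, width)` in pixels.
#' @param dynamic_range_db Dynamic range below the ceiling (default 80).
#' @param freq_max Optional upper frequency limit (Hz): bins above it are
#'   dropped before rendering, concentrating the vertical resolution on the
#'   informative band. `NULL` (default) renders the full `[0, rate/2]` axis.
#' @return An [spectro_image()] with 3 channels.
#' @export
render_spectrogram_image <- function(spec, colormap = "viridis",
                                     intensity_ref = "per_image_max",
                                     out_size = c(96L, 96L),
                                     dynamic_range_db = 80,
                                     freq_max = NULL) {
  stopifnot(inherits(spec, "rs_spectrogram"))
  if (any(out_size < 1)) stop("out_size must be positive")
  mags <- spec$magnitudes                       # frames x bins
  if (!is.null(freq_max)) {
    keep <- spec$frequencies <= freq_max
    if (!any(keep)) stop("freq_max is below the first frequency bin")
    mags <- mags[, keep, drop = FALSE]
  }
  ref <- if (identical(intensity_ref, "per_image_max")) max(mags)
         else as.numeric(intensity_ref)
  if (!is.finite(ref) || ref <= 0) ref <- 1e-10
  eps <- 1e-10
  db <- 20 * log10(pmax(mags, eps))
  ceil_db <- 20 * log10(max(ref, eps))
  z <- (db - (ceil_db - dynamic_range_db)) / dynamic_range_db
  z <- pmax(pmin(z, 1), 0)
  # orient: rows = frequency (top = high), columns = time
  m <- t(z)[rev(seq_len(ncol(z))), , drop = FALSE]
  lut <- .colormap_lut(colormap)
  idx <- matrix(pmin(256L, 1L + as.integer(m * 255)), nrow(m), ncol(m))
  rgb <- array(0, c(nrow(m), ncol(m), 3L))
  for (ch in 1:3) rgb[, , ch] <- matrix(lut[idx, ch], nrow(m), ncol(m))
  out <- array(0, c(out_size[1], out_size[2], 3L))
  for (ch in 1:3) {
    out[, , ch] <- pmin(1, pmax(0, .resize2d(rgb[, , ch], out_size[1], out_size[2])))
  }
  spectro_image(out, colormap = colormap, intensity_ref = intensity_ref)
}

#' Write a spectrogram image to a PNG file
#' @param image An [spectro_image()].
#' @param path Output path.
#' @return `path`.
#' @export
write_image_png <- function(image, path) {
  stopifnot(inherits(image, "rs_image"))
  png::writePNG(image$pixels, path)
  path
}

.grayscale <- function(image) {
  px <- image$pixels
  if (dim(px)[3] == 1L) {
    matrix(px[, , 1], dim(px)[1], dim(px)[2])
  } else {
    apply(px, c(1, 2), mean)
  }
}

#' Texture descriptors of a spectrogram image
#'
#' A fixed-length summary of perceived texture, computed on the grayscale
#' image: `mean`; `variance`; `contrast_h`, the mean squared difference of
#' horizontally adjacent pixels (along time); `contrast_v`, the same along
#' frequency; `energy`, the sum of squared probabilities of a 32-bin
#' intensity histogram; and `entropy`, the Shannon entropy (bits) of that
#' histogram. All six are invariant under horizontal flipping.
#'
#' @param image An [spectro_image()] larger than 1x1.
#' @return Named numeric vector of the six descriptors, in the order above.
#' @export
texture_metrics <- function(image) {
  stopifnot(inherits(image, "rs_image"))
  g <- .grayscale(image)
  if (nrow(g) < 2L && ncol(g) < 2L) {
    stop("image too small for texture analysis (need more than 1x1)")
  }
  dh <- if (ncol(g) > 1L) mean((g[, -1L, drop = FALSE] -
                                g[, -ncol(g), drop = FALSE])^2) else 0
  dv <- if (nrow(g) > 1L) mean((g[-1L, , drop = FALSE] -
                                g[-nrow(g), , drop = FALSE])^2) else 0
  breaks <- seq(0, 1, length.out = 33L)
  p <- tabulate(findInterval(g, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), 32L) / length(g)
  c(mean = mean(g), variance = stats::var(as.vector(g)) * (length(g) - 1) / length(g),
    contrast_h = dh, contrast_v = dv,
    energy = sum(p^2),
    entropy = -sum(ifelse(p > 0, p * log2(p), 0)))
}

#' Feature maps by 2-D cross-correlation
#'
#' Applies each kernel to the grayscale image as a valid (no padding)
#' cross-correlation, the feature-extraction primitive of a convolutional
#' layer; output spatial dimensions are `input - kernel + 1` per axis.
#'
#' @param image An [spectro_image()].
#' @param filters A list of numeric kernel matrices, each no larger than the
#'   image.
#' @return List of activation-map matrices, one per kernel.
#' @export
feature_maps <- function(image, filters) {
  stopifnot(inherits(image, "rs_image"))
  if (is.matrix(filters)) filters <- list(filters)
  g <- .grayscale(image)
  lapply(filters, function(k) {
    k <- as.matrix(k)
    kh <- nrow(k); kw <- ncol(k)
    oh <- nrow(g) - kh + 1L; ow <- ncol(g) - kw + 1L
    if (oh < 1L || ow < 1L) {
      stop("kernel (", kh, "x", kw, ") larger than image (",
           nrow(g), "x", ncol(g), ")")
    }
    out <- matrix(0, oh, ow)
    for (i in seq_len(kh)) {
      for (j in seq_len(kw)) {
        out <- out + k[i, j] * g[i:(i + oh - 1L), j:(j + ow - 1L), drop = FALSE]
      }
    }
    out
  })
}
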