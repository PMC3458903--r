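#' Grayscale raster images
#'
#' A `gray_image` is a plain numeric matrix (rows = image rows, columns =
#' image columns) carrying the source bit depth as an attribute. All pipeline
#' stages operate on this representation; intensities are stored as doubles
#' regardless of the on-disk bit depth.
#'
#' @param pixels Numeric matrix of intensities.
#' @param bit_depth Bits per pixel of the source data (e.g. 8 or 16).
#' @return A `gray_image` object.
#' @export
gray_image <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    abort("Image intensities must be finite and non-negative.")
  }
  structure(pixels, bit_depth = as.integer(bit_depth), class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d, %d-bit, range [%g, %g]\n",
    nrow(x), ncol(x), attr(x, "bit_depth"), min(x), max(x)
  ))
  invisible(x)
}

#' Load a grayscale image from disk
#'
#' Reads PNG or TIFF images. Multi-channel images are collapsed to a single
#' channel: by default the green channel of an RGB image (the conventional
#' high-contrast channel for fundus photographs), otherwise the channel mean.
#' Intensities are returned on their native integer scale (0..2^bit_depth - 1).
#'
#' @param path Path to a PNG or TIFF file.
#' @param channel Collapse rule for multi-channel input: `"green"` (default)
#'   uses channel 2 of a 3/4-channel image, `"mean"` averages all channels.
#' @return A [gray_image()].
#' @export
load_gray <- function(path, channel = c("green", "mean")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) {
    abort(sprintf("Image file does not exist: '%s'", path))
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, info = TRUE),
    abort(sprintf(
      "Unsupported image format '.%s' for '%s' (supported: PNG, TIFF).",
      ext, path
    ))
  )
  # readPNG/readTIFF return values scaled to [0, 1]; recover the integer scale
  bit_depth <- if (ext == "png") {
    hdr <- readBin(path, "raw", n = 26L)
    as.integer(hdr[25L])               # PNG IHDR bit-depth byte
  } else {
    as.integer(attr(arr, "bits.per.sample") %||% 8L)
  }
  if (length(dim(arr)) == 3L) {
    if (channel == "green" && dim(arr)[3] >= 3L) {
      arr <- arr[, , 2L]
    } else {
      arr <- apply(arr, c(1L, 2L), mean)
    }
  }
  scale <- 2^bit_depth - 1
  pixels <- round(arr * scale)
  attributes(pixels) <- list(dim = dim(pixels))   # drop reader metadata
  gray_image(pixels, bit_depth = bit_depth)
}

#' Write a grayscale image to disk
#'
#' Writes PNG (8-bit) or TIFF (8- or 16-bit; high-bit-depth rasters such as
#' angle maps use 16-bit TIFF). Intensities are clipped to the target range;
#' values are assumed to live on the target integer scale.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param path Output path; format chosen from the extension (.png / .tif).
#' @param bit_depth Output bit depth: 8 (PNG or TIFF) or 16 (TIFF only;
#'   default 8 for PNG, 16 for TIFF).
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path, bit_depth = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (is.null(bit_depth)) bit_depth <- if (ext == "png") 8L else 16L
  scale <- 2^bit_depth - 1
  m <- pmin(pmax(unclass(img), 0), scale) / scale
  attributes(m) <- list(dim = dim(m))
  switch(ext,
    png = {
      if (bit_depth != 8L) {
        abort("PNG output is 8-bit; use a .tif path for 16-bit rasters.")
      }
      png::writePNG(m, path, dpi = NULL)
    },
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = as.integer(bit_depth)),
    abort(sprintf("Unsupported output format '.%s' for '%s'.", ext, path))
  )
  invisible(path)
}

# shift a matrix by (dr, dc) with replicate borders
shift_replicate <- function(m, dr, dc) {
  M <- nrow(m); N <- ncol(m)
  ri <- pmin(pmax(seq_len(M) + dr, 1L), M)
  ci <- pmin(pmax(seq_len(N) + dc, 1L), N)
  m[ri, ci, drop = FALSE]
}

#' 3x3 median prefilter
#'
#' Replaces every pixel by the median of its 3x3 neighbourhood, the standard
#' impulse-noise prefilter for angiographic frames. Borders are handled by
#' edge replication so the output has the same dimensions as the input.
#'
#' The median of the nine shifted rasters is computed with a fully vectorised
#' compare-exchange network, so the result is the exact selection median for
#' arbitrary numeric intensities.
#'
#' @param img A [gray_image()] or numeric matrix, at least 3x3.
#' @return A filtered image of the same class and dimensions.
#' @export
median3x3 <- function(img) {
  m <- unclass(img)
  if (nrow(m) < 3L || ncol(m) < 3L) {
    abort("median3x3() needs an image of at least 3x3 pixels.")
  }
  n <- nrow(m) * ncol(m)
  p <- vector("list", 9L)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    p[[k]] <- as.vector(shift_replicate(m, dr, dc))
  }
  # bubble compare-exchange network: exact median of 9 per pixel
  for (i in 1:8) for (j in 1:(9 - i)) {
    lo <- pmin(p[[j]], p[[j + 1L]])
    hi <- pmax(p[[j]], p[[j + 1L]])
    p[[j]] <- lo
    p[[j + 1L]] <- hi
  }
  out <- matrix(p[[5L]], nrow(m), ncol(m))
  if (inherits(img, "gray_image")) gray_image(out, attr(img, "bit_depth")) else out
}

#' Optional background flattening
#'
#' Subtracts a large-window (default 101x101) median estimate of the slowly
#' varying background, then restores the original mean level and clips at
#' zero. Intended to suppress uneven illumination; disabled by default in the
#' analysis pipeline.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param window Odd window edge length in pixels (default 101; clipped at the
#'   image border).
#' @return A flattened image of the same class and dimensions.
#' @export
flatten_background <- function(img, window = 101L) {
  m <- unclass(img)
  radius <- min((window - 1L) %/% 2L, nrow(m) - 1L, ncol(m) - 1L)
  top <- max(max(m), 1)
  bg <- EBImage::medianFilter(m / top, size = radius) * top
  out <- pmax(m - bg + mean(bg), 0)
  if (inherits(img, "gray_image")) gray_image(out, attr(img, "bit_depth")) else out
}
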