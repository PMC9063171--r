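#' Construct a raster image
#'
#' The package's in-memory image container: 8-bit intensities stored as a
#' numeric `height x width` matrix (grayscale) or `height x width x 3` array
#' (RGB), values in `[0, 255]`, rows running top to bottom. An optional
#' physical scale (mm per pixel) travels with the image and is adjusted by
#' [upscale_bicubic()].
#'
#' @param pixels numeric matrix (grayscale) or 3-channel array, values in
#'   `[0, 255]`.
#' @param scale optional mm-per-pixel scale, a positive scalar.
#' @return an object of class `raster_image` with fields `pixels`, `height`,
#'   `width`, `channels`, `scale`.
#' @export
raster_image <- function(pixels, scale = NULL) {
  if (is.matrix(pixels)) {
    channels <- 1L
  } else if (is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3) {
    channels <- 3L
  } else {
    stop("`pixels` must be a matrix or a height x width x 3 array")
  }
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1) {
    stop("image must have height >= 1 and width >= 1")
  }
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255) {
    stop("intensities must be finite and within [0, 255]")
  }
  if (!is.null(scale)) {
    stopifnot(is.numeric(scale), length(scale) == 1, scale > 0)
  }
  structure(
    list(pixels = pixels, height = dim(pixels)[1], width = dim(pixels)[2],
         channels = channels, scale = scale),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px, %d channel(s)%s\n",
              x$width, x$height, x$channels,
              if (is.null(x$scale)) "" else sprintf(", %.6g mm/px", x$scale)))
  invisible(x)
}

#' Read an image file
#'
#' Reads a PNG, TIFF or JPEG file into a [raster_image()]. Grayscale files
#' are replicated to three identical channels; an alpha channel, if
#' present, is dropped.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @param scale optional mm-per-pixel scale to attach.
#' @return a `raster_image`.
#' @export
read_image <- function(path, scale = NULL) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  dat <- EBImage::imageData(img) * 255
  nd <- length(dim(dat))
  if (nd == 2) {
    px <- array(t(dat), c(dim(dat)[2], dim(dat)[1], 3))
  } else {
    nch <- dim(dat)[3]
    if (nch >= 3) {
      px <- array(0, c(dim(dat)[2], dim(dat)[1], 3))
      for (k in 1:3) px[, , k] <- t(dat[, , k])
    } else {
      px <- array(t(dat[, , 1]), c(dim(dat)[2], dim(dat)[1], 3))  # gray + alpha
    }
  }
  px[px < 0] <- 0
  px[px > 255] <- 255
  raster_image(px, scale = scale)
}

#' Write an image file
#'
#' @param image a [raster_image()].
#' @param path output path; format chosen from the extension
#'   (.png/.tif/.tiff/.jpg/.jpeg).
#' @return the path, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "raster_image"))
  px <- image$pixels / 255
  dat <- if (image$channels == 1L) t(px) else {
    out <- array(0, c(image$width, image$height, 3))
    for (k in 1:3) out[, , k] <- t(px[, , k])
    out
  }
  ebi <- EBImage::Image(dat, colormode = if (image$channels == 1L) "Grayscale" else "Color")
  EBImage::writeImage(ebi, path)
  invisible(path)
}

#' Bicubic resolution enhancement
#'
#' Upscales both image dimensions by an integer factor using separable
#' bicubic (Catmull-Rom, a = -0.5) convolution, the interpolation used
#' before segmentation to reduce discretisation error in shape descriptors.
#' Intensities are clipped back to `[0, 255]` (cubic convolution can
#' overshoot near edges); the mm-per-pixel scale, if present, is divided by
#' the factor so physical units are preserved.
#'
#' @param image a [raster_image()].
#' @param factor integer scale factor `>= 1`; the method's reference setting
#'   is 10.
#' @return a `raster_image` of size `factor * height` by `factor * width`.
#' @export
upscale_bicubic <- function(image, factor) {
  stopifnot(inherits(image, "raster_image"))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != round(factor)) {
    stop("`factor` must be a single integer >= 1")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  if (image$channels == 1L) {
    px <- bicubic_upscale_cpp(image$pixels, factor, 0, 255)
  } else {
    px <- array(0, c(image$height * factor, image$width * factor, 3))
    for (k in 1:3) px[, , k] <- bicubic_upscale_cpp(image$pixels[, , k], factor, 0, 255)
  }
  raster_image(px, scale = if (is.null(image$scale)) NULL else image$scale / factor)
}

#' Read or write a measurement table
#'
#' Measurement tables are plain CSV (comma separator, header row, UTF-8,
#' `.` decimal). Values round-trip at full double precision; column names
#' are preserved verbatim (including `Perim.` style names).
#'
#' @param table a data.frame of measurements.
#' @param path CSV file path.
#' @return `read_table()` returns a data.frame; `write_table()` returns the
#'   path invisibly.
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("cannot read table: no such file: ", path)
  out <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("malformed CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  out
}

# Brightness plane of an image: the HSB "B" channel, i.e. max(R, G, B).
brightness_channel <- function(image) {
  stopifnot(inherits(image, "raster_image"))
  if (image$channels == 1L) return(image$pixels)
  pmax(image$pixels[, , 1], image$pixels[, , 2], image$pixels[, , 3])
}

# Mean-of-channels grayscale plane, used for intensity statistics.
gray_channel <- function(image) {
  stopifnot(inherits(image, "raster_image"))
  if (image$channels == 1L) return(image$pixels)
  (image$pixels[, , 1] + image$pixels[, , 2] + image$pixels[, , 3]) / 3
}
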