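#' Luminance image with visual-angle calibration
#'
#' Light-weight container for a square greyscale image. Pixel values are
#' luminances in \[0, 1\] and `pixels_per_degree` ties the raster to degrees of
#' visual angle, which is what the spatial-frequency filters and the Gabor
#' bank are calibrated in (cycles/degree).
#'
#' @param pixels Square numeric matrix of luminances in \[0, 1\].
#' @param pixels_per_degree Positive scalar; raster resolution in pixels per
#'   degree of visual angle.
#' @param category Optional category token (`"face"` or `"house"`).
#' @param filter_label Optional filter token (`"none"`, `"low"`, `"high"`,
#'   `"horizontal"`, `"vertical"`).
#' @return An object of class `"vt_image"`: a list with elements `pixels`,
#'   `pixels_per_degree`, `category`, `filter_label`.
#' @export
vt_image <- function(pixels, pixels_per_degree, category = NULL,
                     filter_label = "none") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) != ncol(pixels))
    stop("image raster must be square")
  if (!all(is.finite(pixels)))
    stop("image contains non-finite values")
  if (!is.numeric(pixels_per_degree) || length(pixels_per_degree) != 1L ||
      pixels_per_degree <= 0)
    stop("`pixels_per_degree` must be a positive scalar")
  if (!is.null(category))
    category <- match.arg(category, c("face", "house"))
  filter_label <- match.arg(filter_label,
                            c("none", "low", "high", "horizontal", "vertical"))
  structure(
    list(pixels = pixels, pixels_per_degree = pixels_per_degree,
         category = category, filter_label = filter_label),
    class = "vt_image")
}

#' @export
print.vt_image <- function(x, ...) {
  cat(sprintf("<vt_image> %dx%d px, %.2f px/deg, category=%s, filter=%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixels_per_degree,
              if (is.null(x$category)) "?" else x$category, x$filter_label))
  invisible(x)
}

#' Nyquist frequency of an image in cycles/degree
#' @param img A [vt_image()].
#' @return Scalar, `pixels_per_degree / 2`.
#' @export
nyquist_cpd <- function(img) img$pixels_per_degree / 2

#' Read or write a greyscale image as PNG
#'
#' Convenience I/O for the stimulus stages. Colour PNGs are collapsed to
#' luminance by channel averaging. Writing stores the raster as 8-bit grey
#' (use [write_image_tiff()] for 16-bit).
#'
#' @param path File path.
#' @param pixels_per_degree Calibration attached to the image on read.
#' @param category,filter_label Optional tokens attached on read.
#' @return `read_image_png()` returns a [vt_image()]; `write_image_png()`
#'   returns `path` invisibly.
#' @export
read_image_png <- function(path, pixels_per_degree, category = NULL,
                           filter_label = "none") {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])),
                                         drop = FALSE], c(1, 2), mean)
  vt_image(a, pixels_per_degree, category, filter_label)
}

#' @rdname read_image_png
#' @param img A [vt_image()] to write.
#' @export
write_image_png <- function(img, path) {
  stopifnot(inherits(img, "vt_image"))
  png::writePNG(pmin(pmax(img$pixels, 0), 1), target = path)
  invisible(path)
}
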