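#' Fluorescence field image
#'
#' A `field_image` is the unit of analysis throughout the package: a single
#' 2D intensity array for one channel, carrying the pixel size (in microns
#' per pixel) needed to express areas, diameters and lengths in physical
#' units. Intensities are in arbitrary detector units (ADU).
#'
#' The pixel grid follows the usual image convention: the first array index
#' is the row (y, increasing downwards), the second the column (x). The
#' centre of pixel `[i, j]` sits at physical coordinates
#' `x = (j - 0.5) * pixel_size_um`, `y = (i - 0.5) * pixel_size_um`.
#'
#' @param data Numeric matrix of intensities (rows = y, columns = x).
#' @param pixel_size_um Pixel size in microns per pixel; must be positive.
#' @param channel Optional channel label (e.g. `"green"`, `"red"`).
#'
#' @return An object of class `field_image`.
#' @export
#' @examples
#' img <- field_image(matrix(100, 64, 64), pixel_size_um = 0.065)
#' img
field_image <- function(data, pixel_size_um, channel = "green") {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric matrix.")
  }
  if (missing(pixel_size_um) || is.null(pixel_size_um) ||
      !is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number; no default is assumed.")
  }
  structure(
    list(data = data, pixel_size_um = as.numeric(pixel_size_um),
         channel = channel),
    class = "field_image"
  )
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf(
    "<field_image> %d x %d px (%.3f x %.3f um), pixel %.4f um, channel %s\n",
    nrow(x$data), ncol(x$data),
    ncol(x$data) * x$pixel_size_um, nrow(x$data) * x$pixel_size_um,
    x$pixel_size_um, x$channel))
  cat(sprintf("  intensity range [%.1f, %.1f] ADU\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.field_image <- function(x) dim(x$data)

is_field_image <- function(x) inherits(x, "field_image")

assert_field_image <- function(x, arg = "image") {
  if (!is_field_image(x)) abort(sprintf("`%s` must be a field_image.", arg))
  if (length(x$data) == 0) abort(sprintf("`%s` is empty.", arg))
  invisible(x)
}

#' Pixel area of a field image in square microns
#' @param image A [field_image].
#' @return Scalar pixel area (um^2).
#' @export
pixel_area_um2 <- function(image) {
  assert_field_image(image)
  image$pixel_size_um^2
}

#' Total imaged area in square microns
#' @param image A [field_image].
#' @return Scalar field area (um^2).
#' @export
field_area_um2 <- function(image) {
  assert_field_image(image)
  length(image$data) * image$pixel_size_um^2
}

# physical coordinates of every pixel centre, as two matrices
pixel_coords <- function(image) {
  px <- image$pixel_size_um
  nr <- nrow(image$data); nc <- ncol(image$data)
  list(
    x = matrix(rep((seq_len(nc) - 0.5) * px, each = nr), nr, nc),
    y = matrix(rep((seq_len(nr) - 0.5) * px, times = nc), nr, nc)
  )
}

#' Read a grayscale TIFF as one or more field images
#'
#' Reads single- or multi-page grayscale TIFF files. Multi-page files are
#' returned as a list of [field_image]s in page order (channels or time
#' frames, per the caller's convention). The TIFF format this package writes
#' stores intensities scaled to the 16-bit range; values are returned in ADU
#' by undoing that scaling with `scale_max`.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um Pixel size in um/pixel. Required: there is no silent
#'   default when the file carries no resolution metadata.
#' @param channel Channel label to attach.
#' @param scale_max Intensity value mapped to the top of the 16-bit range
#'   when the file was written (see [write_field_tiff()]).
#' @return A [field_image], or a list of them for a multi-page file.
#' @export
read_field_tiff <- function(path, pixel_size_um = NULL, channel = "green",
                            scale_max = 65535) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.null(pixel_size_um)) {
    abort("`pixel_size_um` must be supplied: the pixel size is never defaulted silently.")
  }
  imgs <- purrr::map(pages, function(p) {
    if (length(dim(p)) == 3) {
      abort("RGB/multi-sample TIFF is not supported; supply one grayscale TIFF per channel.")
    }
    field_image(p * scale_max, pixel_size_um = pixel_size_um, channel = channel)
  })
  if (length(imgs) == 1) imgs[[1]] else imgs
}

#' Write field images to a 16-bit grayscale TIFF
#'
#' Intensities are scaled by `scale_max` into the unit range expected by the
#' TIFF writer and stored at 16 bits per sample. A list of images is written
#' as a multi-page file.
#'
#' @param image A [field_image] or list of them.
#' @param path Output path.
#' @param scale_max ADU value mapped to the top of the 16-bit range.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(image, path, scale_max = 65535) {
  imgs <- if (is_field_image(image)) list(image) else image
  mats <- purrr::map(imgs, function(im) {
    assert_field_image(im)
    pmin(pmax(im$data / scale_max, 0), 1)
  })
  tiff::writeTIFF(mats, path, bits.per.sample = 16)
  invisible(path)
}
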