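#' Construct a stained-section image
#'
#' A `stained_image` wraps an 8-bit RGB raster of a histological section
#' together with the stain that was applied (hematoxylin/eosin or von Kossa)
#' and, optionally, the physical pixel size. The stain tag is what the
#' segmentation rules use to refuse images of the wrong modality: the
#' mineral rule is defined on von Kossa sections and the matrix rule on
#' HE sections.
#'
#' @param pixels numeric or integer array of dimension `height x width x 3`
#'   holding R, G, B channel intensities on the 0--255 scale.
#' @param stain one of `"HE"` or `"VON_KOSSA"`.
#' @param pixel_size optional physical edge length of one pixel (e.g. in
#'   micrometres); carried through to area statistics when present.
#' @return An object of class `stained_image`.
#' @examples
#' px <- array(200, dim = c(8, 8, 3))
#' img <- stained_image(px, "HE")
#' dim(img)
#' @export
stained_image <- function(pixels, stain = c("HE", "VON_KOSSA"),
                          pixel_size = NULL) {
  stain <- match.arg(stain)
  stop_unless(is.array(pixels) && length(dim(pixels)) == 3L &&
                dim(pixels)[3] == 3L,
              "'pixels' must be a height x width x 3 array")
  stop_unless(dim(pixels)[1] > 0L && dim(pixels)[2] > 0L,
              "image raster must be non-empty")
  stop_unless(all(is.finite(pixels)) && min(pixels) >= 0 && max(pixels) <= 255,
              "channel values must lie in [0, 255]")
  if (!is.null(pixel_size))
    stop_unless(is_number(pixel_size) && pixel_size > 0,
                "'pixel_size' must be a positive number")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, stain = stain, pixel_size = pixel_size),
            class = "stained_image")
}

#' @export
dim.stained_image <- function(x) dim(x$pixels)[1:2]

#' @export
print.stained_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<stained_image> %s, %d x %d px", x$stain, d[1], d[2]))
  if (!is.null(x$pixel_size))
    cat(sprintf(", pixel size %g", x$pixel_size))
  cat("\n")
  invisible(x)
}

#' Read a stained-section image from PNG or TIFF
#'
#' @param path path to an RGB PNG or TIFF file (8 bit per channel).
#' @inheritParams stained_image
#' @return A [stained_image].
#' @export
read_stained_image <- function(path, stain = c("HE", "VON_KOSSA"),
                               pixel_size = NULL) {
  stain <- match.arg(stain)
  stop_unless(file.exists(path), sprintf("no such file: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(raw)) == 2L)
    raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  stained_image(round(raw * 255), stain = stain, pixel_size = pixel_size)
}

#' Write a stained-section image as an 8-bit RGB PNG
#'
#' @param image a [stained_image].
#' @param path output path; directories must exist.
#' @return `path`, invisibly.
#' @export
write_stained_image <- function(image, path) {
  stop_unless(inherits(image, "stained_image"), "'image' must be a stained_image")
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Write a component mask as a single-channel PNG (0/255)
#'
#' @param mask a [component_mask] or logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- as_mask_matrix(mask)
  png::writePNG(m * 1, path)
  invisible(path)
}

#' Read a single-channel 0/255 PNG as a component mask
#'
#' Pixels with intensity above half scale are foreground.
#'
#' @param path path to a PNG mask.
#' @param component component class carried on the mask
#'   (`"MINERAL"`, `"MATRIX"`, `"NUCLEUS"` or `"GENERIC"`).
#' @return A [component_mask].
#' @export
read_mask <- function(path, component = "GENERIC") {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  component_mask(raw > 0.5, component = component)
}
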