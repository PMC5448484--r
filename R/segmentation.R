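#' RGB-ratio classification thresholds
#'
#' Bundle of the channel-ratio thresholds used to classify stained-section
#' pixels. The mineral rule on von Kossa sections is
#' `B/G < mineral_bg_max` and `R/G > mineral_rg_min`; the matrix rule on HE
#' sections is `matrix_red_low < R < matrix_red_high`; nuclei are detected on
#' either stain where `B/G > nucleus_bg_min`. All inequalities are strict.
#' The mineral and matrix defaults are the published ones; `nucleus_bg_min`
#' has no published value (the blue/green ratio is only named as the nuclear
#' indicator), so it is an explicit, overridable parameter.
#'
#' @param mineral_bg_max upper blue/green ratio for mineral (default 0.85).
#' @param mineral_rg_min lower red/green ratio for mineral (default 1.02).
#' @param matrix_red_low,matrix_red_high open red-intensity interval for
#'   eosin-stained matrix (defaults 210 and 225 on the 0--255 scale).
#' @param nucleus_bg_min lower blue/green ratio for nuclei (default 1.05).
#' @return An object of class `rgb_thresholds`.
#' @examples
#' rgb_thresholds()
#' rgb_thresholds(nucleus_bg_min = 1.10)
#' @export
rgb_thresholds <- function(mineral_bg_max = 0.85, mineral_rg_min = 1.02,
                           matrix_red_low = 210, matrix_red_high = 225,
                           nucleus_bg_min = 1.05) {
  for (v in list(mineral_bg_max, mineral_rg_min, matrix_red_low,
                 matrix_red_high, nucleus_bg_min))
    stop_unless(is_number(v) && v > 0, "all thresholds must be positive numbers")
  stop_unless(matrix_red_low < matrix_red_high,
              "'matrix_red_low' must be below 'matrix_red_high'")
  structure(list(mineral_bg_max = mineral_bg_max,
                 mineral_rg_min = mineral_rg_min,
                 matrix_red_low = matrix_red_low,
                 matrix_red_high = matrix_red_high,
                 nucleus_bg_min = nucleus_bg_min),
            class = "rgb_thresholds")
}

#' @export
print.rgb_thresholds <- function(x, ...) {
  cat("<rgb_thresholds>\n")
  cat(sprintf("  mineral : B/G < %g and R/G > %g\n",
              x$mineral_bg_max, x$mineral_rg_min))
  cat(sprintf("  matrix  : %g < R < %g\n", x$matrix_red_low, x$matrix_red_high))
  cat(sprintf("  nucleus : B/G > %g\n", x$nucleus_bg_min))
  invisible(x)
}

#' Construct a component mask
#'
#' A logical raster marking the pixels of one component class, carrying the
#' class and (when known) the stain it was derived from.
#'
#' @param mask logical matrix.
#' @param component `"MINERAL"`, `"MATRIX"`, `"NUCLEUS"` or `"GENERIC"`.
#' @param source_stain optional stain tag of the source image.
#' @return An object of class `component_mask` (a logical matrix with
#'   attributes; `sum()`, `mean()` etc. work as usual).
#' @export
component_mask <- function(mask,
                           component = c("GENERIC", "MINERAL", "MATRIX",
                                         "NUCLEUS"),
                           source_stain = NULL) {
  component <- match.arg(component)
  stop_unless(is.matrix(mask) && is.logical(mask),
              "'mask' must be a logical matrix")
  stop_unless(!anyNA(mask), "'mask' must not contain NA")
  structure(mask, component = component, source_stain = source_stain,
            class = c("component_mask", class(mask)))
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "component_mask")) {
    m <- unclass(mask)
    attr(m, "component") <- NULL
    attr(m, "source_stain") <- NULL
    attr(m, "g_zero_pixels") <- NULL
    return(m)
  }
  stop_unless(is.matrix(mask) && is.logical(mask),
              "expected a component_mask or logical matrix")
  mask
}

#' @export
print.component_mask <- function(x, ...) {
  cat(sprintf("<component_mask> %s, %d x %d px, %d foreground (%.2f%%)\n",
              attr(x, "component"), nrow(x), ncol(x), sum(x),
              100 * mean(x)))
  invisible(x)
}

# Channel plane as a matrix (extraction must not drop dims on 1-px rasters).
channel <- function(image, k) {
  d <- dim(image$pixels)
  matrix(image$pixels[, , k], d[1], d[2])
}

# Channel-ratio raster. Pixels with G = 0 have no defined ratio and are
# returned as NA; the classifiers treat them as negative and report a count.
ratio_raster <- function(num, den) {
  out <- matrix(NA_real_, nrow(den), ncol(den))
  ok <- den != 0L
  out[ok] <- num[ok] / den[ok]
  out
}

check_stain <- function(image, expected, what) {
  stop_unless(inherits(image, "stained_image"),
              "'image' must be a stained_image")
  if (image$stain != expected)
    stop(sprintf("%s is defined on %s-stained images, got stain '%s'",
                 what, expected, image$stain), call. = FALSE)
  invisible(TRUE)
}

finish_mask <- function(mask, g_zero, component, stain) {
  out <- component_mask(mask, component = component, source_stain = stain)
  attr(out, "g_zero_pixels") <- g_zero
  if (g_zero > 0)
    message(sprintf("%d pixel(s) with G = 0 classified as non-%s",
                    g_zero, tolower(component)))
  out
}

#' Segment mineral deposits on a von Kossa-stained section
#'
#' Marks brown silver-stained mineral: pixels where blue/green < 0.85 and
#' red/green > 1.02 (strict inequalities, raw 0--255 integers). Pixels with
#' G = 0 have undefined ratios and are conservatively classified as
#' non-mineral; their count is attached as attribute `g_zero_pixels` and
#' reported via [message()] when nonzero.
#'
#' @param image a [stained_image] with stain `"VON_KOSSA"`.
#' @param thresholds an [rgb_thresholds] bundle.
#' @return A [component_mask] of class MINERAL, same dimensions as `image`.
#' @examples
#' ph <- generate_stain_phantom(phantom_spec(64, 64, mineral_fraction = 0.2,
#'                                           stain = "VON_KOSSA"))
#' m <- segment_mineral(ph$image)
#' area_fraction(m)
#' @export
segment_mineral <- function(image, thresholds = rgb_thresholds()) {
  check_stain(image, "VON_KOSSA", "mineral segmentation")
  R <- channel(image, 1); G <- channel(image, 2); B <- channel(image, 3)
  bg <- ratio_raster(B, G); rg <- ratio_raster(R, G)
  mask <- !is.na(bg) & !is.na(rg) &
    bg < thresholds$mineral_bg_max & rg > thresholds$mineral_rg_min
  finish_mask(mask, sum(G == 0L), "MINERAL", image$stain)
}

#' Segment eosin-stained matrix on an HE-stained section
#'
#' Marks protein-matrix pixels whose red channel lies strictly inside the
#' open interval (210, 225) on the 0--255 scale.
#'
#' @param image a [stained_image] with stain `"HE"`.
#' @inheritParams segment_mineral
#' @return A [component_mask] of class MATRIX.
#' @export
segment_matrix <- function(image, thresholds = rgb_thresholds()) {
  check_stain(image, "HE", "matrix segmentation")
  R <- channel(image, 1)
  mask <- R > thresholds$matrix_red_low & R < thresholds$matrix_red_high
  component_mask(mask, component = "MATRIX", source_stain = image$stain)
}

#' Segment nuclei by elevated blue/green ratio
#'
#' Hematoxylin (HE) and the unstained nuclear region on von Kossa sections
#' both present an elevated blue/green ratio relative to their surroundings;
#' pixels with `B/G > nucleus_bg_min` are marked. Applicable to either stain.
#'
#' @param image a [stained_image] (any stain).
#' @inheritParams segment_mineral
#' @return A [component_mask] of class NUCLEUS.
#' @export
segment_nuclei <- function(image, thresholds = rgb_thresholds()) {
  stop_unless(inherits(image, "stained_image"),
              "'image' must be a stained_image")
  G <- channel(image, 2); B <- channel(image, 3)
  bg <- ratio_raster(B, G)
  mask <- !is.na(bg) & bg > thresholds$nucleus_bg_min
  finish_mask(mask, sum(G == 0L), "NUCLEUS", image$stain)
}

#' Extract a horizontal line profile of channel ratios
#'
#' Returns the per-position red/green and blue/green ratios along one image
#' row, the readout used to localise mineral deposition (R/G) and the cell
#' nucleus (B/G) across a single cell. Positions run left to right.
#' Positions with G = 0 carry `NA` ratios.
#'
#' @param image a [stained_image].
#' @param row 1-based row index of the horizontal line.
#' @return An object of class `line_profile`: a data frame with columns
#'   `position`, `rg_ratio`, `bg_ratio`.
#' @examples
#' ph <- generate_stain_phantom(phantom_spec(64, 64, mineral_fraction = 0.2,
#'                                           nucleus_count = 1,
#'                                           stain = "VON_KOSSA"))
#' lp <- extract_line_profile(ph$image, row = 32)
#' head(lp)
#' @export
extract_line_profile <- function(image, row) {
  stop_unless(inherits(image, "stained_image"),
              "'image' must be a stained_image")
  h <- dim(image)[1]
  stop_unless(is_count(row) && row >= 1 && row <= h,
              sprintf("'row' must be an integer in [1, %d]", h))
  R <- image$pixels[row, , 1]; G <- image$pixels[row, , 2]
  B <- image$pixels[row, , 3]
  rg <- ifelse(G == 0L, NA_real_, R / G)
  bg <- ifelse(G == 0L, NA_real_, B / G)
  structure(data.frame(position = seq_along(rg), rg_ratio = rg,
                       bg_ratio = bg),
            row = row, stain = image$stain,
            class = c("line_profile", "data.frame"))
}

#' @export
plot.line_profile <- function(x, thresholds = rgb_thresholds(), ...) {
  rng <- range(c(x$rg_ratio, x$bg_ratio), na.rm = TRUE)
  graphics::plot(x$position, x$rg_ratio, type = "l", col = "red3",
                 ylim = rng, xlab = "position (px)", ylab = "channel ratio",
                 main = sprintf("Line profile (row %d)", attr(x, "row")), ...)
  graphics::lines(x$position, x$bg_ratio, col = "blue3")
  graphics::abline(h = thresholds$mineral_rg_min, lty = 3, col = "red3")
  graphics::abline(h = thresholds$nucleus_bg_min, lty = 3, col = "blue3")
  graphics::legend("topright", legend = c("R/G (mineral)", "B/G (nucleus)"),
                   col = c("red3", "blue3"), lty = 1, bty = "n")
  invisible(x)
}

#' Area fraction of a component mask
#'
#' Percentage of foreground pixels, optionally restricted to a region of
#' interest. Under the Delesse principle this area fraction on random
#' sections estimates the component's volume fraction, which is what feeds
#' the composition equations.
#'
#' @param mask a [component_mask] or logical matrix.
#' @param roi optional logical matrix of the same dimensions; when given,
#'   the denominator is the ROI pixel count and only foreground inside the
#'   ROI is counted. Defaults to the full raster.
#' @return Area fraction as a percentage in \[0, 100\].
#' @examples
#' m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' area_fraction(m)  # 50
#' @export
area_fraction <- function(mask, roi = NULL) {
  m <- as_mask_matrix(mask)
  if (is.null(roi)) return(100 * sum(m) / length(m))
  r <- as_mask_matrix(roi)
  stop_unless(all(dim(r) == dim(m)), "'roi' must match the mask dimensions")
  n <- sum(r)
  stop_unless(n > 0, "ROI is empty: area fraction undefined")
  100 * sum(m & r) / n
}
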