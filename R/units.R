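#' Convert physical lengths and areas to pixel units and back
#'
#' All analysis parameters are specified in micrometres and converted to pixel
#' units at run time using the calibration of the image at hand. Conversions
#' are exact (no rounding); rounding to integer pixel radii or areas is the
#' caller's documented decision.
#'
#' @param length_um Length in micrometres.
#' @param pixel_size Pixel size in micrometres per pixel (> 0).
#' @return `um_to_px()`: length in pixels (double). `px_to_um()`: length in
#'   micrometres. `area_um2_to_px()`: area in square pixels.
#'   `px_area_to_um2()`: area in square micrometres.
#' @examples
#' um_to_px(1.75, 0.25) # 7 px
#' px_area_to_um2(1440, 0.25) # 90 um^2
#' @export
um_to_px <- function(length_um, pixel_size) {
  check_pixel_size(pixel_size)
  length_um / pixel_size
}

#' @rdname um_to_px
#' @param length_px Length in pixels.
#' @export
px_to_um <- function(length_px, pixel_size) {
  check_pixel_size(pixel_size)
  length_px * pixel_size
}

#' @rdname um_to_px
#' @param area_um2 Area in square micrometres.
#' @export
area_um2_to_px <- function(area_um2, pixel_size) {
  check_pixel_size(pixel_size)
  area_um2 / pixel_size^2
}

#' @rdname um_to_px
#' @param px_count Number of pixels (area in px^2).
#' @export
px_area_to_um2 <- function(px_count, pixel_size) {
  check_pixel_size(pixel_size)
  px_count * pixel_size^2
}

check_pixel_size <- function(pixel_size) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive finite number (um/px).",
         call. = FALSE)
  }
  invisible(pixel_size)
}

#' Default pixel calibration
#'
#' Default pixel size used when an image carries no calibration metadata,
#' corresponding to the 40x objective class typically used for fixed-culture
#' high-content imaging. Always overridable; every micrometre-parameterised
#' operation reports the pixel value it actually used.
#'
#' @return Pixel size in micrometres per pixel.
#' @export
default_pixel_size <- function() 0.325
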