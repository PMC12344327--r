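#' Screen and viewing geometry
#'
#' Describes the stimulus screen (pixel and physical dimensions) and the
#' nominal viewing distance, which together define the mapping between pixel
#' coordinates and degrees of visual angle. Anisotropic pixels are allowed:
#' the pixel and physical aspect ratios need not agree.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param width_mm,height_mm Physical screen size in millimetres.
#' @param viewing_distance_mm Eye-to-screen distance in millimetres
#'   (nominally ~600 mm for a remote tracker).
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry(1920, 1080, 510, 287, 600)
#' pixels_to_degrees(960, 540, geom)  # screen centre -> (0, 0)
#' @export
screen_geometry <- function(width_px, height_px, width_mm, height_mm,
                            viewing_distance_mm = 600) {
  vals <- c(width_px = width_px, height_px = height_px,
            width_mm = width_mm, height_mm = height_mm,
            viewing_distance_mm = viewing_distance_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen_geometry fields must be positive and finite")
  }
  structure(as.list(vals), class = "screen_geometry")
}

#' @method print screen_geometry
#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, %.0f x %.0f mm, viewing distance %.0f mm\n",
              x$width_px, x$height_px, x$width_mm, x$height_mm,
              x$viewing_distance_mm))
  invisible(x)
}

#' Convert between pixel coordinates and degrees of visual angle
#'
#' Angles are computed per axis as `atan(offset_mm / viewing_distance_mm)`,
#' where the offset is measured from the screen centre. The convention is
#' x rightward, y downward, origin at the screen centre. Non-finite inputs
#' propagate to `NA`.
#'
#' @param x_px,y_px Pixel coordinates (x rightward, y downward, origin at the
#'   top-left pixel edge, so the screen centre is at `(width_px/2, height_px/2)`).
#' @param x_deg,y_deg Degrees of visual angle relative to the screen centre.
#' @param geometry A [screen_geometry()].
#'
#' @return A list with components `x_deg`/`y_deg` (or `x_px`/`y_px` for the
#'   inverse), vectorised over the inputs.
#' @export
pixels_to_degrees <- function(x_px, y_px, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  mmx <- geometry$width_mm / geometry$width_px
  mmy <- geometry$height_mm / geometry$height_px
  dx <- (x_px - geometry$width_px / 2) * mmx
  dy <- (y_px - geometry$height_px / 2) * mmy
  d <- geometry$viewing_distance_mm
  list(x_deg = atan(dx / d) * 180 / pi,
       y_deg = atan(dy / d) * 180 / pi)
}

#' @rdname pixels_to_degrees
#' @export
degrees_to_pixels <- function(x_deg, y_deg, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  mmx <- geometry$width_mm / geometry$width_px
  mmy <- geometry$height_mm / geometry$height_px
  d <- geometry$viewing_distance_mm
  list(x_px = tan(x_deg * pi / 180) * d / mmx + geometry$width_px / 2,
       y_px = tan(y_deg * pi / 180) * d / mmy + geometry$height_px / 2)
}
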