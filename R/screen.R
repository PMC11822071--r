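#' Screen and viewing geometry
#'
#' Describes the stimulus monitor and viewing distance so that visual angles
#' can be converted to on-screen pixels. Defaults correspond to a 21.5-inch
#' 1920 x 1080 display viewed from 570 mm, for which one degree of visual
#' angle is roughly 40 px.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param diagonal_in Physical diagonal of the display, inches.
#' @param distance_mm Viewing distance, millimetres.
#' @return An object of class `cogload_screen`: a list with the inputs plus
#'   `px_per_mm` and `px_per_deg` conversion factors.
#' @examples
#' scr <- screen_geometry()
#' deg_to_px(1, scr) # about 40 px
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            diagonal_in = 21.5, distance_mm = 570) {
  stopifnot(width_px > 0, height_px > 0, diagonal_in > 0, distance_mm > 0)
  diag_mm <- diagonal_in * 25.4
  aspect <- width_px / height_px
  width_mm <- diag_mm * aspect / sqrt(1 + aspect^2)
  px_per_mm <- width_px / width_mm
  mm_per_deg <- 2 * distance_mm * tan(pi / 360)
  structure(
    list(width_px = width_px, height_px = height_px,
         diagonal_in = diagonal_in, distance_mm = distance_mm,
         px_per_mm = px_per_mm, px_per_deg = px_per_mm * mm_per_deg),
    class = "cogload_screen"
  )
}

#' Convert degrees of visual angle to pixels
#'
#' @param deg Angle(s) in degrees.
#' @param screen A [screen_geometry()] object.
#' @return Length(s) in pixels.
#' @export
deg_to_px <- function(deg, screen = screen_geometry()) {
  stopifnot(inherits(screen, "cogload_screen"))
  deg * screen$px_per_deg
}
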