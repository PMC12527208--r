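#' Map heading angle to its lateral velocity component and back
#'
#' All observer models operate on a single lateral-velocity axis (deg/s)
#' so that vestibular and visual signals are commensurate. A heading angle
#' (degrees from vertically upward, positive rightward) is mapped to the
#' lateral component of the platform's peak velocity:
#' `lateral = reference_speed * sin(angle)`. The inverse clamps its
#' argument to the unit interval before the arcsine, so estimates whose
#' magnitude exceeds `reference_speed` report a +/-90 degree heading.
#'
#' @param angle Heading angle(s) in degrees.
#' @param lateral Lateral velocity component(s) in deg/s.
#' @param reference_speed Peak self-motion speed (deg/s), default 8.5.
#' @return Numeric vector (deg/s for `heading_to_lateral()`, degrees for
#'   `lateral_to_heading()`).
#' @examples
#' heading_to_lateral(45)                # 8.5 * sin(45 deg) ~ 6.01
#' lateral_to_heading(heading_to_lateral(-30))  # -30
#' @export
heading_to_lateral <- function(angle, reference_speed = 8.5) {
  stopifnot(reference_speed > 0)
  reference_speed * sin(angle * pi / 180)
}

#' @rdname heading_to_lateral
#' @export
lateral_to_heading <- function(lateral, reference_speed = 8.5) {
  stopifnot(reference_speed > 0)
  asin(pmin(1, pmax(-1, lateral / reference_speed))) * 180 / pi
}
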