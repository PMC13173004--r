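#' Arc geometry
#'
#' Defines a coplanar gantry arc by its start angle, span, and control-point
#' spacing. The number of control points is `round(arc_span / cp_spacing)`;
#' control points sit at `start_angle + (0:(n-1)) * cp_spacing` (modulo 360),
#' so consecutive increments equal `cp_spacing` exactly and the closing gap
#' back to the start absorbs any rounding (a 360 deg arc at 5.07 deg spacing
#' gives 71 control points).
#'
#' Gantry-angle convention (IEC-like, documented here and used throughout):
#' 0 deg = beam entering from the anterior (+y) side travelling along -y;
#' angles increase clockwise when viewed from the patient's feet, so 90 deg
#' enters from the patient-left (+x) side. Beam direction for gantry angle
#' theta is `(-sin(theta), -cos(theta), 0)` ... see [beam_direction()].
#' Beams are modeled as parallel (infinite SAD).
#'
#' @param start_angle degrees.
#' @param arc_span degrees, > 0.
#' @param cp_spacing degrees, > 0.
#' @param isocenter mm triple.
#' @return object of class `arc_geometry`.
#' @export
arc_geometry <- function(start_angle = 0, arc_span = 360, cp_spacing = 5.07,
                         isocenter = c(0, 0, 0)) {
  if (!is.finite(arc_span) || arc_span <= 0)
    stop("arc_geometry: arc_span must be > 0")
  if (!is.finite(cp_spacing) || cp_spacing <= 0)
    stop("arc_geometry: cp_spacing must be > 0")
  n <- round(arc_span / cp_spacing)
  if (n < 1) stop("arc_geometry: spacing larger than the arc span")
  structure(list(start_angle = start_angle, arc_span = arc_span,
                 cp_spacing = cp_spacing, isocenter = as.numeric(isocenter),
                 n_cp = as.integer(n), type = "arc"),
            class = "arc_geometry")
}

#' Unit beam direction for a gantry angle
#'
#' @param theta gantry angle in degrees (see [arc_geometry()] for the
#'   convention).
#' @return unit length-3 vector in the image mm frame.
#' @export
beam_direction <- function(theta) {
  t <- theta * pi / 180
  c(-sin(t), -cos(t), 0)
}

#' Beam's-eye-view basis for a gantry angle
#'
#' Returns two orthonormal lateral vectors (u, v) with u in the axial plane,
#' v along +z (superior), forming a right-handed triad `u x v = direction`.
#' The basis is continuous in theta (no flips between adjacent control
#' points).
#'
#' @param theta gantry angle in degrees.
#' @return list(u, v) of unit vectors.
#' @export
bev_basis <- function(theta) {
  t <- theta * pi / 180
  list(u = c(cos(t), -sin(t), 0), v = c(0, 0, 1))
}

new_control_point <- function(index, theta, isocenter) {
  b <- bev_basis(theta)
  structure(list(index = as.integer(index),
                 gantry_angle = theta %% 360,
                 direction = beam_direction(theta),
                 u = b$u, v = b$v,
                 isocenter = as.numeric(isocenter)),
            class = "control_point")
}

#' Discretize an arc into control points
#'
#' @param geometry an [arc_geometry()].
#' @return list of `control_point` objects ordered by delivery sequence.
#' @export
make_arc <- function(geometry) {
  stopifnot(inherits(geometry, "arc_geometry"))
  angles <- geometry$start_angle + (seq_len(geometry$n_cp) - 1) * geometry$cp_spacing
  lapply(seq_along(angles), function(i)
    new_control_point(i, angles[i], geometry$isocenter))
}

#' Static beams sharing the arc BEV conventions
#'
#' One control point per gantry angle, used for the IMPT comparator.
#'
#' @param angles non-empty numeric vector of gantry angles (degrees).
#' @param isocenter mm triple.
#' @return list of `control_point` objects.
#' @export
make_static_beams <- function(angles, isocenter = c(0, 0, 0)) {
  if (length(angles) == 0) stop("make_static_beams: empty angle list")
  lapply(seq_along(angles), function(i)
    new_control_point(i, angles[i], isocenter))
}
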