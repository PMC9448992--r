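#' Eye geometry for retinal coordinate modeling
#'
#' Defines the retinal coordinate frame used throughout the package: distances
#' in micrometers on the retinal surface, fovea at the origin, positive x
#' toward the optic disc (nasal retina) for a right eye, positive y superior.
#' The optic disc sits by default 15 degrees nasal and 2 degrees superior to
#' the fovea, converted at 288 um per degree of visual angle. Visual-field
#' renderings flip the y axis; stored data are always retinal.
#'
#' @param optic_disc_deg position of the optic-disc center relative to the
#'   fovea, in degrees of visual angle `c(nasal, superior)`.
#' @param raphe_angle_deg angle of the horizontal raphe below the horizontal
#'   through the optic-disc center, in degrees (typically 15).
#' @param um_per_degree retinal distance corresponding to one degree of visual
#'   angle (um).
#' @param eye `"right"` or `"left"`; a left eye mirrors the x axis.
#' @param optic_disc_radius_um modeled radius of the optic-disc circle at which
#'   axon bundles terminate (um).
#' @return An object of class `"eye_geometry"`.
#' @examples
#' eye <- eye_geometry()
#' eye$optic_disc_um
#' @export
eye_geometry <- function(optic_disc_deg = c(15, 2),
                         raphe_angle_deg = 15,
                         um_per_degree = 288,
                         eye = c("right", "left"),
                         optic_disc_radius_um = 4 * 288) {
  eye <- match.arg(eye)
  if (!is.numeric(um_per_degree) || length(um_per_degree) != 1 ||
      !is.finite(um_per_degree) || um_per_degree <= 0) {
    stop("'um_per_degree' must be a single positive number")
  }
  if (length(optic_disc_deg) != 2 || !all(is.finite(optic_disc_deg))) {
    stop("'optic_disc_deg' must be two finite numbers")
  }
  side <- if (eye == "right") 1 else -1
  od_um <- c(side * optic_disc_deg[1], optic_disc_deg[2]) * um_per_degree
  if (sqrt(sum(od_um^2)) < 1e-6) {
    stop("optic disc cannot coincide with the fovea")
  }
  structure(list(
    fovea_um = c(0, 0),
    optic_disc_um = od_um,
    raphe_angle_deg = raphe_angle_deg,
    um_per_degree = um_per_degree,
    eye = eye,
    optic_disc_radius_um = optic_disc_radius_um
  ), class = "eye_geometry")
}

#' @export
print.eye_geometry <- function(x, ...) {
  cat("Eye geometry (", x$eye, " eye)\n", sep = "")
  cat(sprintf("  optic disc at (%.0f, %.0f) um [%.1f deg nasal, %.1f deg superior]\n",
              x$optic_disc_um[1], x$optic_disc_um[2],
              abs(x$optic_disc_um[1]) / x$um_per_degree,
              x$optic_disc_um[2] / x$um_per_degree))
  cat(sprintf("  raphe angle: %.1f deg inferior; scale: %.0f um/deg\n",
              x$raphe_angle_deg, x$um_per_degree))
  invisible(x)
}

#' Convert retinal distance to degrees of visual angle
#'
#' @param distance_um retinal distance in micrometers.
#' @param um_per_degree conversion factor (um per degree), default 288.
#' @return Distance in degrees of visual angle.
#' @examples
#' um_to_deg(288)      # 1
#' um_to_deg(2393.66)  # about 8.31
#' @export
um_to_deg <- function(distance_um, um_per_degree = 288) {
  if (!is.numeric(um_per_degree) || any(um_per_degree <= 0)) {
    stop("'um_per_degree' must be positive")
  }
  distance_um / um_per_degree
}

#' @rdname um_to_deg
#' @param distance_deg distance in degrees of visual angle.
#' @export
deg_to_um <- function(distance_deg, um_per_degree = 288) {
  if (!is.numeric(um_per_degree) || any(um_per_degree <= 0)) {
    stop("'um_per_degree' must be positive")
  }
  distance_deg * um_per_degree
}

# Disc-frame unit vectors: abscissa points from the disc toward the temporal
# retina (through the fovea region), rotated raphe_angle_deg inferiorly;
# ordinate is superior. The frame mirrors between eyes.
disc_frame <- function(eye) {
  a <- eye$raphe_angle_deg * pi / 180
  s <- if (eye$eye == "right") -1 else 1  # temporal direction along x
  list(xhat = c(s * cos(a), -sin(a)),
       yhat = c(s * sin(a), cos(a)),
       origin = eye$optic_disc_um)
}

# retinal (n x 2) -> disc frame coordinates (um)
to_disc_frame <- function(xy, eye) {
  fr <- disc_frame(eye)
  xy <- matrix(xy, ncol = 2)
  dx <- xy[, 1] - fr$origin[1]
  dy <- xy[, 2] - fr$origin[2]
  cbind(dx * fr$xhat[1] + dy * fr$xhat[2],
        dx * fr$yhat[1] + dy * fr$yhat[2])
}

# disc frame (n x 2) -> retinal coordinates (um)
from_disc_frame <- function(uv, eye) {
  fr <- disc_frame(eye)
  uv <- matrix(uv, ncol = 2)
  cbind(fr$origin[1] + uv[, 1] * fr$xhat[1] + uv[, 2] * fr$yhat[1],
        fr$origin[2] + uv[, 1] * fr$xhat[2] + uv[, 2] * fr$yhat[2])
}
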