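#' Fit the raphe parabola for an eye geometry
#'
#' The horizontal raphe -- the seam temporal to the fovea that retinal axon
#' bundles do not cross -- is modeled as a parabola with its vertex at the
#' optic-disc center and its axis of symmetry along the abscissa of the
#' disc-centered frame. That abscissa points from the disc toward the
#' temporal retina and is rotated `raphe_angle_deg` below the horizontal, so
#' the extended raphe lies inferior to the fovea latitude for the typical
#' 15-degree angle. In the disc frame the parabola is `u = curvature * v^2`
#' (u along the axis toward the fovea, v perpendicular); the wedge between the
#' two branches is the raphe zone that separates superior from inferior
#' bundles.
#'
#' @param eye an [eye_geometry()] object.
#' @param curvature parabola curvature in 1/um; larger values narrow the
#'   temporal wedge.
#' @return An object of class `"raphe_parabola"` with the vertex (retinal um),
#'   axis angle and curvature.
#' @examples
#' rp <- fit_raphe(eye_geometry())
#' raphe_side(rp, rbind(c(0, 2000), c(0, -2000)))
#' @export
fit_raphe <- function(eye, curvature = 0.013) {
  if (!inherits(eye, "eye_geometry")) stop("'eye' must be an eye_geometry object")
  if (sqrt(sum(eye$optic_disc_um^2)) < 1e-6) {
    stop("degenerate geometry: optic disc at the fovea")
  }
  if (!is.finite(curvature) || curvature <= 0) stop("'curvature' must be positive")
  fr <- disc_frame(eye)
  axis_angle <- atan2(fr$xhat[2], fr$xhat[1]) * 180 / pi
  structure(list(
    vertex_um = eye$optic_disc_um,
    axis_angle_deg = axis_angle,
    curvature = curvature,
    eye = eye
  ), class = "raphe_parabola")
}

#' @export
print.raphe_parabola <- function(x, ...) {
  cat(sprintf("Raphe parabola: vertex (%.0f, %.0f) um, axis %.1f deg, curvature %.4g /um\n",
              x$vertex_um[1], x$vertex_um[2], x$axis_angle_deg, x$curvature))
  invisible(x)
}

#' Classify retinal points relative to the raphe parabola
#'
#' @param raphe a [fit_raphe()] object.
#' @param xy matrix (n x 2) of retinal coordinates in um.
#' @return Integer vector: `+1` superior side, `-1` inferior side, `0` inside
#'   the temporal raphe wedge.
#' @export
raphe_side <- function(raphe, xy) {
  uv <- to_disc_frame(xy, raphe$eye)
  inside <- uv[, 1] > raphe$curvature * uv[, 2]^2
  out <- ifelse(inside, 0L, ifelse(uv[, 2] >= 0, 1L, -1L))
  as.integer(out)
}
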