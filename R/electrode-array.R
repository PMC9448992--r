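#' Place a 6x10 epiretinal electrode array on the retina
#'
#' Builds the canonical 6x10 grid of disk electrodes (rows A-F superior to
#' inferior, columns 1-10) with the given pitch, then applies a rigid
#' transform: rotation about the array center followed by translation of the
#' center to `center_offset` relative to the fovea.
#'
#' @param center_offset retinal `c(x, y)` position of the array center (um).
#' @param rotation_deg rotation of the array relative to the horizontal
#'   (degrees, counterclockwise).
#' @param pitch_um center-to-center electrode separation (um).
#' @param diameter_um electrode disk diameter (um).
#' @return An object of class `"electrode_array"` with `labels` and
#'   `positions` (60 x 2 matrix, retinal um).
#' @examples
#' arr <- electrode_array()
#' electrode_position(arr, "A1")
#' @export
electrode_array <- function(center_offset = c(0, 0), rotation_deg = 0,
                            pitch_um = 575, diameter_um = 225) {
  if (!all(is.finite(center_offset)) || length(center_offset) != 2) {
    stop("'center_offset' must be two finite numbers")
  }
  if (!is.finite(rotation_deg)) stop("'rotation_deg' must be finite")
  if (pitch_um <= 0 || diameter_um <= 0) stop("pitch and diameter must be positive")
  rows <- LETTERS[1:6]
  grid <- expand.grid(col = 1:10, row = 1:6)
  labels <- paste0(rows[grid$row], grid$col)
  # canonical grid centered on the origin; row A superior
  x0 <- (grid$col - 5.5) * pitch_um
  y0 <- (3.5 - grid$row) * pitch_um
  th <- rotation_deg * pi / 180
  pos <- cbind(x0 * cos(th) - y0 * sin(th) + center_offset[1],
               x0 * sin(th) + y0 * cos(th) + center_offset[2])
  rownames(pos) <- labels
  structure(list(labels = labels, positions = pos, pitch_um = pitch_um,
                 diameter_um = diameter_um, center_offset = center_offset,
                 rotation_deg = rotation_deg),
            class = "electrode_array")
}

#' @rdname electrode_array
#' @param array an existing `electrode_array` (its pitch and diameter are
#'   kept).
#' @export
place_array <- function(array, center_offset = c(0, 0), rotation_deg = 0) {
  if (!inherits(array, "electrode_array")) stop("'array' must be an electrode_array")
  electrode_array(center_offset, rotation_deg, array$pitch_um, array$diameter_um)
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("6x10 electrode array: pitch %.0f um, diameter %.0f um\n",
              x$pitch_um, x$diameter_um))
  cat(sprintf("  center (%.0f, %.0f) um, rotation %.1f deg\n",
              x$center_offset[1], x$center_offset[2], x$rotation_deg))
  invisible(x)
}

#' @rdname electrode_array
#' @param label electrode label such as `"A1"` or `"F10"`.
#' @export
electrode_position <- function(array, label) {
  if (!label %in% array$labels) stop("unknown electrode label: ", label)
  array$positions[label, ]
}
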