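#' Current-spread model parameters
#'
#' Parameter set for the disk-electrode current-spread ("scoreboard")
#' simulator. Current at a retinal point falls off with the distance `r`
#' (in mm) from the electrode as `I = I0 / (1 + (k * r)^a)`. The measured
#' single-electrode threshold is factored multiplicatively as
#' `I0 = theta_lift * theta_rd * theta_baseline`: a lift factor (the extra
#' current needed because the electrode sits above the retinal surface), a
#' retinal-damage factor, and the 50 uA baseline for a flush electrode over
#' undamaged retina.
#'
#' @param a current-decay exponent (unitless, plausible range 1-3).
#' @param k current-decay scale (per mm, plausible range 6-20).
#' @param theta_rd retinal damage factor (>= 1).
#' @param lift_um electrode height above the retinal plane (0-1000 um).
#' @param theta_baseline_uA baseline flush-electrode threshold (uA).
#' @param dip_criterion_pct dip value taken to yield 75% two-point
#'   discrimination performance (must exceed 20).
#' @param distance_convention how the distance `r` from a point to the disk
#'   electrode is measured: `"center"` (3D distance to the disk center; the
#'   calibrated default), `"disk_surface"` (nearest point of the disk) or
#'   `"rim"` (nearest point of the rim circle).
#' @param electrode_radius_um disk radius (um).
#' @return Object of class `"spread_params"`.
#' @export
spread_params <- function(a = 1.5, k = 15, theta_rd = 1, lift_um = 0,
                          theta_baseline_uA = 50, dip_criterion_pct = 25,
                          distance_convention = c("center", "disk_surface", "rim"),
                          electrode_radius_um = 112.5) {
  distance_convention <- match.arg(distance_convention)
  if (!is.finite(a) || a < 1 || a > 3) stop("'a' must be in [1, 3]")
  if (!is.finite(k) || k < 6 || k > 20) stop("'k' must be in [6, 20]")
  if (!is.finite(lift_um) || lift_um < 0 || lift_um > 1000) {
    stop("'lift_um' must be in [0, 1000]")
  }
  if (!is.finite(theta_rd) || theta_rd < 1) stop("'theta_rd' must be >= 1")
  if (!is.finite(dip_criterion_pct) || dip_criterion_pct <= 20 ||
      dip_criterion_pct > 100) {
    stop("'dip_criterion_pct' must be in (20, 100]")
  }
  structure(list(a = a, k = k, theta_rd = theta_rd, lift_um = lift_um,
                 theta_baseline_uA = theta_baseline_uA,
                 dip_criterion_pct = dip_criterion_pct,
                 distance_convention = distance_convention,
                 electrode_radius_um = electrode_radius_um),
            class = "spread_params")
}

#' @export
print.spread_params <- function(x, ...) {
  cat(sprintf(
    "Current-spread parameters: a=%.2f, k=%.1f /mm, lift=%.0f um, theta_rd=%.2f\n",
    x$a, x$k, x$lift_um, x$theta_rd))
  cat(sprintf("  baseline %.0f uA, dip criterion %.0f%%, distance convention '%s'\n",
              x$theta_baseline_uA, x$dip_criterion_pct, x$distance_convention))
  invisible(x)
}

# distance (um) from 3D points (n x 3) to a disk electrode centered at
# (cx, cy, lift), per convention
electrode_distance_um <- function(pts, center_xy, lift_um, convention,
                                  radius_um = 112.5) {
  pts <- matrix(pts, ncol = 3)
  rho <- sqrt((pts[, 1] - center_xy[1])^2 + (pts[, 2] - center_xy[2])^2)
  dz <- pts[, 3] - lift_um
  switch(convention,
    center = sqrt(rho^2 + dz^2),
    disk_surface = ifelse(rho <= radius_um, abs(dz),
                          sqrt((rho - radius_um)^2 + dz^2)),
    rim = sqrt((rho - radius_um)^2 + dz^2))
}

#' Current from one disk electrode at arbitrary points
#'
#' Evaluates `I = I0 / (1 + (k * r)^a)` with `r` in mm computed from each 3D
#' point to the electrode disk under the chosen distance convention.
#'
#' @param points n x 3 matrix of points (um; a 2-column matrix is taken as
#'   points on the retinal plane, z = 0).
#' @param electrode_xy electrode center on the retinal plane, `c(x, y)` um.
#' @param lift_um electrode height above the plane (um).
#' @param I0_uA stimulating current (uA).
#' @param a,k current-spread parameters (`k` per mm).
#' @param convention distance convention (see [spread_params()]).
#' @param radius_um electrode disk radius (um).
#' @return Current in uA at each point.
#' @examples
#' current_at_point(cbind(0, 0, 0), c(0, 0), lift_um = 150, I0_uA = 1,
#'                  a = 1.5, k = 15)  # 1/4.375
#' @export
current_at_point <- function(points, electrode_xy, lift_um, I0_uA, a, k,
                             convention = "center", radius_um = 112.5) {
  if (I0_uA < 0) stop("'I0_uA' must be non-negative")
  points <- as.matrix(points)
  if (ncol(points) == 2) points <- cbind(points, 0)
  r_mm <- electrode_distance_um(points, electrode_xy, lift_um, convention,
                                radius_um) / 1000
  I0_uA / (1 + (k * r_mm)^a)
}

# peak on-plane attenuation (unit current) of a single electrode; the peak is
# found numerically over the radial profile
peak_plane_attenuation <- function(params) {
  f <- function(rho) {
    current_at_point(cbind(rho, 0, 0), c(0, 0), params$lift_um, 1,
                     params$a, params$k, params$distance_convention,
                     params$electrode_radius_um)
  }
  upper <- params$electrode_radius_um * 2 + params$lift_um + 500
  opt <- stats::optimize(f, c(0, upper), maximum = TRUE, tol = 1e-4)
  max(opt$objective, f(0))
}

#' Lift factor of the threshold model
#'
#' The multiplicative current increase required so that the peak retinal
#' current of an electrode lifted `lift_um` above the plane equals that of a
#' flush electrode: the reciprocal of the peak on-plane attenuation.
#' Monotonically increasing in lift, with curvature set by `a` and `k`.
#'
#' @param lift_um electrode height (um).
#' @param a,k current-spread parameters.
#' @param convention distance convention.
#' @param radius_um disk radius (um).
#' @return Lift factor (1 at lift 0).
#' @examples
#' theta_lift(150, a = 1.5, k = 15)  # 4.375
#' @export
theta_lift <- function(lift_um, a, k, convention = "center",
                       radius_um = 112.5) {
  vapply(lift_um, function(h) {
    p <- list(a = a, k = k, lift_um = h, distance_convention = convention,
              electrode_radius_um = radius_um)
    1 / peak_plane_attenuation(p)
  }, numeric(1))
}

#' Single-electrode detection threshold under the factor model
#'
#' Numerically solves for the electrode current `I0` at which the peak
#' retinal current equals `theta_rd * theta_baseline` -- the retinal current
#' required for detection over (possibly damaged) retina. Because the peak
#' retinal current is proportional to `I0`, the solution equals
#' `theta_lift * theta_rd * theta_baseline`.
#'
#' @param params a [spread_params()] object.
#' @return Threshold current in uA.
#' @examples
#' find_threshold(spread_params(lift_um = 0, theta_rd = 1))  # 50
#' @export
find_threshold <- function(params) {
  stopifnot(inherits(params, "spread_params"))
  g <- peak_plane_attenuation(params)
  if (!is.finite(g) || g <= 0) {
    stop("threshold solver failed for a=", params$a, ", k=", params$k,
         ", lift=", params$lift_um)
  }
  target <- params$theta_rd * params$theta_baseline_uA
  # least-squares solve of peak(I0) = target in I0 (linear, so exact)
  obj <- function(I0) (I0 * g - target)^2
  up <- 2 * target / g
  sol <- stats::optimize(obj, c(0, up), tol = 1e-6)$minimum
  if (abs(sol * g - target) > 0.01) {
    stop("threshold solver did not converge for a=", params$a, ", k=",
         params$k, ", lift=", params$lift_um)
  }
  sol
}

#' Summed retinal current field of an electrode pair
#'
#' Evaluates the linear superposition of the two electrodes' current spreads
#' on a grid over the retinal plane. Both electrodes carry the same amplitude
#' and lift; they sit at `(-separation/2, 0)` and `(+separation/2, 0)`. The
#' field maximum is refined from the best grid point by continuous local
#' optimization; the midpoint current is evaluated exactly at the
#' inter-electrode midpoint.
#'
#' @param separation_um center-to-center electrode separation (um).
#' @param params a [spread_params()].
#' @param stim_uA per-electrode stimulation amplitude (uA, at most 660).
#' @param grid_step_um grid resolution (um).
#' @param padding_um grid margin beyond the electrodes (um).
#' @param xlim,ylim optional explicit grid ranges (um); must cover both
#'   electrodes.
#' @return Object of class `"retinal_field"`: grid vectors `x`, `y`, current
#'   matrix `I` (uA), `I_max`, `I_mid`, and the inputs.
#' @export
pair_field <- function(separation_um, params, stim_uA,
                       grid_step_um = 10, padding_um = 1200,
                       xlim = NULL, ylim = NULL) {
  stopifnot(inherits(params, "spread_params"))
  if (separation_um <= 0) stop("'separation_um' must be positive")
  if (stim_uA > 660) stop("'stim_uA' exceeds the 660 uA safety cap")
  e1 <- c(-separation_um / 2, 0)
  e2 <- c(separation_um / 2, 0)
  if (is.null(xlim)) xlim <- c(e1[1] - padding_um, e2[1] + padding_um)
  if (is.null(ylim)) ylim <- c(-padding_um, padding_um)
  if (xlim[1] > e1[1] || xlim[2] < e2[1] || ylim[1] > 0 || ylim[2] < 0) {
    stop("grid does not cover both electrodes")
  }
  x <- seq(xlim[1], xlim[2], by = grid_step_um)
  y <- seq(ylim[1], ylim[2], by = grid_step_um)
  pts <- cbind(rep(x, times = length(y)), rep(y, each = length(x)), 0)
  I <- current_at_point(pts, e1, params$lift_um, stim_uA, params$a, params$k,
                        params$distance_convention, params$electrode_radius_um) +
       current_at_point(pts, e2, params$lift_um, stim_uA, params$a, params$k,
                        params$distance_convention, params$electrode_radius_um)
  Im <- matrix(I, nrow = length(x))
  # refine the maximum around the best grid point
  ij <- arrayInd(which.max(Im), dim(Im))
  fxy <- function(p) {
    -sum(current_at_point(rbind(c(p, 0)), e1, params$lift_um, stim_uA,
                          params$a, params$k, params$distance_convention,
                          params$electrode_radius_um),
         current_at_point(rbind(c(p, 0)), e2, params$lift_um, stim_uA,
                          params$a, params$k, params$distance_convention,
                          params$electrode_radius_um))
  }
  opt <- stats::optim(c(x[ij[1]], y[ij[2]]), fxy, method = "Nelder-Mead",
                      control = list(reltol = 1e-10))
  I_max <- max(-opt$value, max(Im))
  I_mid <- current_at_point(cbind(0, 0, 0), e1, params$lift_um, stim_uA,
                            params$a, params$k, params$distance_convention,
                            params$electrode_radius_um) +
           current_at_point(cbind(0, 0, 0), e2, params$lift_um, stim_uA,
                            params$a, params$k, params$distance_convention,
                            params$electrode_radius_um)
  structure(list(x = x, y = y, I = Im, I_max = I_max, I_mid = unname(I_mid),
                 stim_uA = stim_uA, separation_um = separation_um,
                 params = params),
            class = "retinal_field")
}

#' @export
print.retinal_field <- function(x, ...) {
  cat(sprintf("Retinal current field: d=%.0f um, stim %.1f uA/electrode\n",
              x$separation_um, x$stim_uA))
  cat(sprintf("  I_max = %.2f uA, I_mid = %.2f uA, dip = %.1f%%\n",
              x$I_max, x$I_mid, dip(x)))
  invisible(x)
}

#' Midpoint current dip of a two-electrode field
#'
#' `dip = 100 * (I_max - I_mid) / I_max`: the percentage drop of retinal
#' current at the inter-electrode midpoint relative to the field peak. The
#' dip is invariant to scaling both electrode currents by a common factor.
#'
#' @param field a [pair_field()] result.
#' @return Dip in percent, in `[0, 100]`.
#' @export
dip <- function(field) {
  stopifnot(inherits(field, "retinal_field"))
  if (field$I_max <= 0) stop("zero field: dip undefined")
  100 * (field$I_max - field$I_mid) / field$I_max
}

#' @rdname dip
#' @param separation_um electrode separation (um).
#' @param params a [spread_params()].
#' @details `pair_dip()` computes the same statistic without building a 2-D
#'   grid: for equal-amplitude electrodes the summed field's on-plane maximum
#'   lies on the inter-electrode axis (moving a point toward the axis
#'   shortens the distance to both disks), so a 1-D line search suffices.
#' @export
pair_dip <- function(separation_um, params) {
  stopifnot(inherits(params, "spread_params"))
  a <- params$a; k <- params$k; h <- params$lift_um
  conv <- params$distance_convention; R <- params$electrode_radius_um
  f <- function(rho_um) {
    r <- switch(conv,
      center = sqrt(rho_um^2 + h^2),
      disk_surface = ifelse(rho_um <= R, h, sqrt((rho_um - R)^2 + h^2)),
      rim = sqrt((rho_um - R)^2 + h^2)) / 1000
    1 / (1 + (k * r)^a)
  }
  d <- separation_um
  g <- function(x) f(abs(x)) + f(abs(d - x))
  xs <- seq(0, d / 2, length.out = 121)
  v <- g(xs)
  i <- which.max(v)
  lo <- xs[max(1, i - 1)]; hi <- xs[min(length(xs), i + 1)]
  gmax <- if (hi > lo) {
    max(stats::optimize(g, c(lo, hi), maximum = TRUE, tol = 1e-3)$objective, v[i])
  } else v[i]
  100 * (1 - g(d / 2) / gmax)
}

#' Separation at which the dip reaches a criterion
#'
#' Smallest electrode separation in `[250, 8000]` um at which the midpoint
#' dip reaches `criterion_pct`, found by bisection on the monotone
#' dip-versus-distance curve (tolerance 1 um). The dip does not depend on the
#' stimulation amplitude (common scaling leaves it unchanged), so the
#' criterion distance is a pure function of `a`, `k` and lift.
#'
#' @param params a [spread_params()].
#' @param criterion_pct dip criterion in percent (0, 100).
#' @param range_um search range (um).
#' @param tol_um bisection tolerance (um).
#' @return Separation in um, or `NA` with attribute `unreachable = TRUE` when
#'   the criterion is not reached within the range.
#' @export
dip_distance <- function(params, criterion_pct = params$dip_criterion_pct,
                         range_um = c(250, 8000), tol_um = 1) {
  stopifnot(inherits(params, "spread_params"))
  if (criterion_pct <= 0 || criterion_pct >= 100) {
    stop("'criterion_pct' must be in (0, 100)")
  }
  lo <- range_um[1]; hi <- range_um[2]
  if (pair_dip(hi, params) < criterion_pct) {
    return(structure(NA_real_, unreachable = TRUE))
  }
  if (pair_dip(lo, params) >= criterion_pct) return(lo)
  while (hi - lo > tol_um) {
    mid <- (lo + hi) / 2
    if (pair_dip(mid, params) >= criterion_pct) hi <- mid else lo <- mid
  }
  hi
}
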