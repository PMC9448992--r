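#' Build spiral axon-bundle trajectories around the optic disc
#'
#' Simulates retinal ganglion-cell axon bundles as spirals in a modified polar
#' coordinate system `(r, phi)` centered on the optic disc, following the
#' published nerve-fiber trajectory parameterization: each bundle starts on a
#' circle of radius `r0_deg` around the disc at angular position `phi0` and
#' follows `phi(r) = phi0 + b * (r - r0)^c`, where `b` and `c` are smooth
#' functions of `phi0` that differ between the superior and inferior retina.
#' The angular coordinate is measured from the nasal horizontal of the
#' (raphe-rotated) disc frame, positive superior, so the temporal raphe lies
#' at +/-180 degrees. Bundles are clipped so that
#' no polyline crosses the raphe parabola, resampled to a uniform arc-length
#' step, and ordered from the peripheral start toward the optic disc.
#'
#' @param eye an [eye_geometry()] object.
#' @param n_bundles number of bundles (default 400, which leaves an axon
#'   bundle beneath every electrode of a macular 6x10 array).
#' @param trajectory_params list of spiral constants: `beta_sup`, `beta_inf`
#'   (log-scale curvature offsets for the superior/inferior retina), `r0_deg`
#'   (starting circle radius, degrees), `r_max_deg` (peripheral extent,
#'   degrees), `raphe_curvature` (1/um, passed to [fit_raphe()]).
#' @param sampling_step_um arc-length spacing of polyline vertices (um).
#' @return An object of class `"axon_bundle_map"`: a list with `bundles` (list
#'   of n x 2 matrices, retinal um, periphery first), `phi0_deg`, `eye`,
#'   `raphe`, `sampling_step_um` and `params`.
#' @examples
#' map <- build_axon_map(eye_geometry(), n_bundles = 50, sampling_step_um = 50)
#' length(map$bundles)
#' @export
build_axon_map <- function(eye,
                           n_bundles = 400,
                           trajectory_params = list(),
                           sampling_step_um = 10) {
  if (!inherits(eye, "eye_geometry")) stop("'eye' must be an eye_geometry object")
  if (!is.numeric(n_bundles) || n_bundles < 1) stop("'n_bundles' must be >= 1")
  n_bundles <- as.integer(n_bundles)
  tp <- utils::modifyList(list(beta_sup = -1.9, beta_inf = 0.5,
                               r0_deg = 4, r_max_deg = 28,
                               raphe_curvature = 0.013), trajectory_params)
  num_ok <- vapply(tp[c("beta_sup", "beta_inf", "r0_deg", "r_max_deg",
                        "raphe_curvature")],
                   function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                   logical(1))
  if (!all(num_ok)) stop("configuration error: non-finite trajectory parameter")
  if (abs(tp$beta_sup) > 10 || abs(tp$beta_inf) > 10) {
    stop("configuration error: spiral curvature parameter out of published range")
  }
  if (tp$r0_deg <= 0 || tp$r_max_deg <= tp$r0_deg) {
    stop("configuration error: need 0 < r0_deg < r_max_deg")
  }
  if (sampling_step_um <= 0) stop("'sampling_step_um' must be positive")

  raphe <- fit_raphe(eye, curvature = tp$raphe_curvature)
  # angular start positions, open interval, never exactly on the raphe axis
  phi0 <- seq(-180, 180, length.out = n_bundles + 2)[seq_len(n_bundles) + 1]
  phi0[abs(phi0) < 1e-6] <- 1e-3

  bundles <- vector("list", n_bundles)
  for (i in seq_len(n_bundles)) {
    bundles[[i]] <- grow_bundle(phi0[i], eye, tp, raphe, sampling_step_um)
  }
  structure(list(bundles = bundles, phi0_deg = phi0, eye = eye, raphe = raphe,
                 sampling_step_um = sampling_step_um, params = tp),
            class = "axon_bundle_map")
}

#' @export
print.axon_bundle_map <- function(x, ...) {
  nv <- vapply(x$bundles, nrow, integer(1))
  cat(sprintf("Axon bundle map: %d bundles, %d vertices (step %.0f um), r in [%.0f, %.0f] deg\n",
              length(x$bundles), sum(nv), x$sampling_step_um,
              x$params$r0_deg, x$params$r_max_deg))
  invisible(x)
}

# spiral constants b, c as functions of the angular start position (degrees)
spiral_bc <- function(phi0, tp) {
  if (phi0 > 0) {
    b <- exp(tp$beta_sup + 3.9 * tanh(-(phi0 - 121) / 14))
    c <- 1.9 + 1.4 * tanh((phi0 - 121) / 14)
  } else {
    b <- -exp(tp$beta_inf + 1.5 * tanh(-(-phi0 - 90) / 25))
    c <- 1.0 + 0.5 * tanh((-phi0 - 90) / 25)
  }
  list(b = b, c = c)
}

grow_bundle <- function(phi0, eye, tp, raphe, step_um) {
  upd <- eye$um_per_degree
  bc <- spiral_bc(phi0, tp)
  # dense radial sampling; resampled to uniform arc length below
  dr <- (step_um / 2) / upd
  r <- seq(tp$r_max_deg, tp$r0_deg, by = -dr)
  if (r[length(r)] > tp$r0_deg) r <- c(r, tp$r0_deg)
  phi <- phi0 + bc$b * (r - tp$r0_deg)^bc$c
  # keep the near-disc part where the angular sweep stays bounded
  ok <- abs(phi - phi0) <= 180
  r <- r[ok]; phi <- phi[ok]
  # phi is measured from the nasal horizontal (the temporal raphe lies at
  # +/-180 degrees); the disc-frame abscissa points temporally
  ph <- phi * pi / 180
  uv <- cbind(-r * cos(ph), r * sin(ph)) * upd
  xy <- from_disc_frame(uv, eye)

  # clip at the raphe: walk from the disc outward, stop before the polyline
  # would acquire vertices on both signed sides of the parabola
  cls <- raphe_side(raphe, xy)
  n <- nrow(xy)
  seen_pos <- FALSE; seen_neg <- FALSE
  first_keep <- 1L
  for (i in seq(n, 1L)) {
    sp <- seen_pos || cls[i] == 1L
    sn <- seen_neg || cls[i] == -1L
    if (sp && sn) { first_keep <- i + 1L; break }
    seen_pos <- sp; seen_neg <- sn
  }
  xy <- xy[first_keep:n, , drop = FALSE]
  resample_polyline(xy, step_um)
}

# resample a polyline (ordered n x 2) to uniform arc-length spacing
resample_polyline <- function(xy, step_um) {
  if (nrow(xy) < 2) return(xy)
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L < step_um) return(xy[c(1, nrow(xy)), , drop = FALSE])
  si <- unique(c(seq(0, L, by = step_um), L))
  cbind(stats::approx(s, xy[, 1], xout = si)$y,
        stats::approx(s, xy[, 2], xout = si)$y)
}

#' Nearest bundle to a retinal point
#'
#' Vertex-based nearest-bundle query: the distance to a bundle is the minimum
#' Euclidean distance to any of its polyline vertices. Ties break to the
#' lowest bundle index.
#'
#' @param map an [build_axon_map()] object.
#' @param xy retinal point `c(x, y)` in um.
#' @return List with `index` of the nearest bundle and `distance_um`.
#' @export
nearest_bundle <- function(map, xy) {
  d <- vapply(map$bundles, function(b) {
    min((b[, 1] - xy[1])^2 + (b[, 2] - xy[2])^2)
  }, numeric(1))
  i <- which.min(d)
  list(index = i, distance_um = sqrt(d[i]))
}

# min distance from point to the vertices of one bundle
point_bundle_dist <- function(b, xy) {
  sqrt(min((b[, 1] - xy[1])^2 + (b[, 2] - xy[2])^2))
}
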