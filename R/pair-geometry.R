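#' Inter-electrode distance measures over the axon-bundle map
#'
#' Computes the three distance measures used as regressors in the two-point
#' discrimination model for one electrode pair:
#' \describe{
#'   \item{physical_um}{Euclidean center-to-center distance between the two
#'     electrodes on the retinal surface.}
#'   \item{to_axon_um}{Each electrode is assigned the bundle beneath it (the
#'     nearest bundle to its center). `d_e1a2` is the minimum distance from
#'     electrode 1's center to any vertex of electrode 2's bundle, and vice
#'     versa; the reported value is `min(d_e1a2, d_e2a1)`.}
#'   \item{along_axon_um}{For the electrode attaining the to-axon minimum
#'     (say electrode 1, nearest to bundle 2): the arc length along bundle 2
#'     from the foot of that minimum to the vertex beneath electrode 2. With
#'     to-axon roughly orthogonal to the gently curving bundles, the three
#'     measures form an approximate right triangle with the physical distance
#'     as hypotenuse.}
#' }
#' All queries are vertex-based; accuracy is set by the polyline sampling step
#' of the map.
#'
#' @param e1,e2 electrode labels.
#' @param array an [electrode_array()].
#' @param map an [build_axon_map()] object.
#' @param max_coverage_um an electrode whose nearest bundle is farther than
#'   this is considered outside bundle coverage (error).
#' @param along_mode `"attaining"` reports the arc length for the electrode
#'   that attained the to-axon minimum (electrode 1 on ties); `"min_both"`
#'   reports the minimum over both electrodes.
#' @return A one-row data.frame with columns `electrode_1`, `electrode_2`,
#'   `physical_um`, `to_axon_um`, `along_axon_um`.
#' @export
pair_distances <- function(e1, e2, array, map,
                           max_coverage_um = 250,
                           along_mode = c("attaining", "min_both")) {
  along_mode <- match.arg(along_mode)
  p1 <- electrode_position(array, e1)
  p2 <- electrode_position(array, e2)
  if (identical(e1, e2)) {
    return(data.frame(electrode_1 = e1, electrode_2 = e2, physical_um = 0,
                      to_axon_um = 0, along_axon_um = 0,
                      stringsAsFactors = FALSE))
  }
  nb1 <- nearest_bundle(map, p1)
  nb2 <- nearest_bundle(map, p2)
  if (nb1$distance_um > max_coverage_um) {
    stop("electrode ", e1, " lies outside axon-bundle coverage (nearest bundle ",
         round(nb1$distance_um), " um away)")
  }
  if (nb2$distance_um > max_coverage_um) {
    stop("electrode ", e2, " lies outside axon-bundle coverage (nearest bundle ",
         round(nb2$distance_um), " um away)")
  }
  a1 <- map$bundles[[nb1$index]]
  a2 <- map$bundles[[nb2$index]]

  physical <- sqrt(sum((p1 - p2)^2))
  d_e1a2 <- point_bundle_dist(a2, p1)
  d_e2a1 <- point_bundle_dist(a1, p2)
  to_axon <- min(d_e1a2, d_e2a1)

  # arc along the fellow bundle between the to-axon foot point (closest to
  # the attaining electrode p_near) and the vertex beneath the fellow
  # electrode p_fellow
  along_for <- function(fellow_bundle, p_near, p_fellow) {
    i <- which.min((fellow_bundle[, 1] - p_near[1])^2 +
                     (fellow_bundle[, 2] - p_near[2])^2)
    j <- which.min((fellow_bundle[, 1] - p_fellow[1])^2 +
                     (fellow_bundle[, 2] - p_fellow[2])^2)
    s <- cumul_arc(fellow_bundle)
    abs(s[j] - s[i])
  }
  if (along_mode == "attaining") {
    along <- if (d_e1a2 <= d_e2a1) along_for(a2, p1, p2) else along_for(a1, p2, p1)
  } else {
    along <- min(along_for(a2, p1, p2), along_for(a1, p2, p1))
  }
  data.frame(electrode_1 = e1, electrode_2 = e2, physical_um = physical,
             to_axon_um = to_axon, along_axon_um = along,
             stringsAsFactors = FALSE)
}

cumul_arc <- function(b) {
  c(0, cumsum(sqrt(diff(b[, 1])^2 + diff(b[, 2])^2)))
}

#' All pairwise distance measures for a set of electrodes
#'
#' @param array an [electrode_array()].
#' @param map an [build_axon_map()] object.
#' @param electrodes labels to include (default: all 60).
#' @param ... passed to [pair_distances()].
#' @return data.frame with one row per unordered pair.
#' @export
all_pair_distances <- function(array, map, electrodes = NULL, ...) {
  if (is.null(electrodes)) electrodes <- array$labels
  cmb <- utils::combn(electrodes, 2)
  out <- vector("list", ncol(cmb))
  for (i in seq_len(ncol(cmb))) {
    out[[i]] <- pair_distances(cmb[1, i], cmb[2, i], array, map, ...)
  }
  do.call(rbind, out)
}

#' Pairwise correlation of the three distance measures
#'
#' @param pairs data.frame from [all_pair_distances()] (needs at least 3
#'   rows).
#' @return 3 x 3 symmetric Pearson correlation matrix over `physical_um`,
#'   `to_axon_um`, `along_axon_um`. Constant columns yield `NA` entries with a
#'   warning.
#' @export
distance_correlation_report <- function(pairs) {
  cols <- c("physical_um", "to_axon_um", "along_axon_um")
  if (!all(cols %in% names(pairs))) stop("'pairs' must have the three distance columns")
  if (nrow(pairs) < 3) stop("need at least 3 pairs for a correlation report")
  m <- as.matrix(pairs[, cols])
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant distance column(s): ", paste(cols[sds == 0], collapse = ", "),
            "; correlations undefined (NA)")
  }
  suppressWarnings(stats::cor(m))
}
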