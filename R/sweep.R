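#' Iso-dip contour over a lift grid
#'
#' For one current-spread parameterization (`a`, `k`, `theta_rd`, dip
#' criterion), sweeps the electrode lift and records, at each lift, the
#' single-electrode detection threshold and the separation at which the dip
#' reaches the criterion. The resulting (threshold, distance) curve is the
#' simulator's analogue of a psychophysical iso-performance contour: more
#' lift raises the threshold and broadens current spread. Scaling `theta_rd`
#' slides the contour along the threshold axis and leaves the distances
#' unchanged (the dip is scale-invariant in current).
#'
#' @param a,k current-spread parameters.
#' @param theta_rd retinal damage factor.
#' @param criterion_pct dip criterion (percent).
#' @param lift_grid_um lift values (um, within 0-1000).
#' @param convention distance convention.
#' @param theta_baseline_uA flush baseline threshold (uA).
#' @return data.frame with columns `lift_um`, `threshold_uA`, `distance_um`,
#'   sorted by threshold; unreachable criterion distances are `NA`.
#' @export
iso_dip_contour <- function(a, k, theta_rd = 1, criterion_pct = 25,
                            lift_grid_um = seq(0, 1000, by = 50),
                            convention = "center", theta_baseline_uA = 50) {
  if (!length(lift_grid_um)) stop("empty lift grid")
  if (any(lift_grid_um < 0 | lift_grid_um > 1000)) {
    stop("lift grid must lie within 0-1000 um")
  }
  rows <- lapply(lift_grid_um, function(h) {
    p <- spread_params(a = a, k = k, theta_rd = theta_rd, lift_um = h,
                       theta_baseline_uA = theta_baseline_uA,
                       dip_criterion_pct = max(criterion_pct, 20.5),
                       distance_convention = convention)
    data.frame(lift_um = h, threshold_uA = find_threshold(p),
               distance_um = as.numeric(dip_distance(p, criterion_pct)))
  })
  out <- do.call(rbind, rows)
  out[order(out$threshold_uA), , drop = FALSE]
}

#' Amplitude error between a simulated contour and a reference contour
#'
#' Interpolates both contours to amplitude-as-a-function-of-distance on a
#' common distance grid over their overlapping support and returns the
#' root-mean-square amplitude residual in uA (or the literal mean of squares
#' with `stat = "mse"`).
#'
#' @param contour data.frame with `threshold_uA` and `distance_um` (an
#'   [iso_dip_contour()] result).
#' @param reference an [iso_performance_contour()] (columns `amplitude_uA`,
#'   `distance_um`).
#' @param stat `"rmse"` (default) or `"mse"`.
#' @param n_grid number of common-grid points.
#' @return Error statistic in uA (squared uA for `"mse"`).
#' @export
contour_mse <- function(contour, reference, stat = c("rmse", "mse"),
                        n_grid = 50) {
  stat <- match.arg(stat)
  cc <- contour[is.finite(contour$distance_um) & is.finite(contour$threshold_uA), ]
  if (nrow(cc) < 2) stop("contour has fewer than 2 finite points")
  lo <- max(min(cc$distance_um), min(reference$distance_um))
  hi <- min(max(cc$distance_um), max(reference$distance_um))
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    stop("contours have no overlapping distance support")
  }
  grid <- seq(lo, hi, length.out = n_grid)
  amp_c <- stats::approx(cc$distance_um, cc$threshold_uA, xout = grid,
                         ties = mean)$y
  amp_r <- stats::approx(reference$distance_um, reference$amplitude_uA,
                         xout = grid, ties = mean)$y
  res2 <- mean((amp_c - amp_r)^2)
  if (stat == "rmse") sqrt(res2) else res2
}

#' Parameter sweep of the current-spread model
#'
#' Simulates every combination of decay exponent `a`, decay scale `k`,
#' damage factor `theta_rd`, lift and dip criterion; for each combination
#' records the single-electrode threshold, the stimulation amplitude
#' `min(2 * threshold, 660)` uA, the criterion distance, and the amplitude
#' error of the parameterization's iso-dip contour (over the lift grid)
#' against the reference iso-performance contour. A record is accepted when
#' its threshold lies within `threshold_range` and its contour error is below
#' `mse_bound`.
#'
#' @param grid named list of sweep values: `a`, `k`, `theta_rd`, `lift_um`,
#'   `criterion_pct`. Defaults span the plausible ranges: `a` 1-3 (step
#'   0.25), `k` 6-20 (step 1), criterion 25-95% (step 10); the two
#'   continuous threshold factors are stepped finely (lift 0-1000 um step
#'   25, `theta_rd` 1-13 step 0.25) because the hard acceptance rules
#'   otherwise quantize which parameterizations align with the reference.
#' @param reference an [iso_performance_contour()] used for sub-selection.
#' @param convention distance convention.
#' @param mse_bound contour-error acceptance bound (uA).
#' @param threshold_range acceptable single-electrode threshold range (uA).
#' @param theta_baseline_uA flush baseline threshold (uA).
#' @return Object of class `"tpd_sweep"`: `records` data.frame (one row per
#'   grid point with `accepted` flag) plus the acceptance rules.
#' @export
run_sweep <- function(grid = list(), reference, convention = "center",
                      mse_bound = 20, threshold_range = c(177, 660),
                      theta_baseline_uA = 50) {
  g <- utils::modifyList(list(
    a = seq(1, 3, by = 0.25),
    k = seq(6, 20, by = 1),
    theta_rd = seq(1, 13, by = 0.25),
    lift_um = seq(0, 1000, by = 25),
    criterion_pct = seq(25, 95, by = 10)), grid)
  if (!all(lengths(g) > 0)) {
    return(structure(list(records = empty_sweep_records(), grid = g,
                          mse_bound = mse_bound,
                          threshold_range = threshold_range),
                     class = "tpd_sweep"))
  }

  # stage 1: theta_lift and criterion distances depend only on (a, k, lift
  # [, criterion]); compute once per combination
  ak <- expand.grid(a = g$a, k = g$k, KEEP.OUT.ATTRS = FALSE)
  nl <- length(g$lift_um); nc <- length(g$criterion_pct)
  tl <- matrix(NA_real_, nrow(ak), nl)           # theta_lift
  d75 <- array(NA_real_, c(nrow(ak), nl, nc))    # criterion distance
  for (i in seq_len(nrow(ak))) {
    for (j in seq_len(nl)) {
      p <- spread_params(a = ak$a[i], k = ak$k[i], lift_um = g$lift_um[j],
                         theta_baseline_uA = theta_baseline_uA,
                         distance_convention = convention)
      tl[i, j] <- 1 / peak_plane_attenuation(p)
      for (m in seq_len(nc)) {
        d75[i, j, m] <- as.numeric(dip_distance(p, g$criterion_pct[m]))
      }
    }
  }

  # stage 2: contour error per (a, k, criterion, theta_rd); theta_rd only
  # rescales the contour's threshold axis
  nfam <- nrow(ak) * nc * length(g$theta_rd)
  col_a <- col_k <- col_rd <- col_crit <- numeric(nfam * nl)
  col_lift <- col_thr <- col_d75 <- col_err <- numeric(nfam * nl)
  pos <- 0L
  for (i in seq_len(nrow(ak))) {
    for (m in seq_len(nc)) {
      dists <- d75[i, , m]
      for (t in seq_along(g$theta_rd)) {
        thr <- tl[i, ] * g$theta_rd[t] * theta_baseline_uA
        contour <- data.frame(threshold_uA = thr, distance_um = dists)
        err <- tryCatch(contour_mse(contour, reference),
                        error = function(e) Inf)
        sl <- pos + seq_len(nl)
        col_a[sl] <- ak$a[i]; col_k[sl] <- ak$k[i]
        col_rd[sl] <- g$theta_rd[t]; col_crit[sl] <- g$criterion_pct[m]
        col_lift[sl] <- g$lift_um; col_thr[sl] <- thr
        col_d75[sl] <- dists; col_err[sl] <- err
        pos <- pos + nl
      }
    }
  }
  rec <- data.frame(a = col_a, k = col_k, theta_rd = col_rd,
                    lift_um = col_lift, criterion_pct = col_crit,
                    threshold_uA = col_thr, stim_uA = pmin(2 * col_thr, 660),
                    d75_um = col_d75, contour_mse = col_err)
  rec$accepted <- is.finite(rec$d75_um) &
    rec$threshold_uA >= threshold_range[1] &
    rec$threshold_uA <= threshold_range[2] &
    rec$contour_mse < mse_bound
  rownames(rec) <- NULL
  structure(list(records = rec, grid = g, mse_bound = mse_bound,
                 threshold_range = threshold_range,
                 convention = convention,
                 theta_baseline_uA = theta_baseline_uA,
                 reference = reference),
            class = "tpd_sweep")
}

empty_sweep_records <- function() {
  data.frame(a = numeric(0), k = numeric(0), theta_rd = numeric(0),
             lift_um = numeric(0), criterion_pct = numeric(0),
             threshold_uA = numeric(0), stim_uA = numeric(0),
             d75_um = numeric(0), contour_mse = numeric(0),
             accepted = logical(0))
}

#' @export
print.tpd_sweep <- function(x, ...) {
  r <- x$records
  cat(sprintf("Current-spread sweep: %d parameterizations, %d accepted\n",
              nrow(r), sum(r$accepted)))
  cat(sprintf("  rules: threshold in [%.0f, %.0f] uA, contour error < %.0f uA\n",
              x$threshold_range[1], x$threshold_range[2], x$mse_bound))
  invisible(x)
}

#' Ablate threshold factors and summarize predicted two-point thresholds
#'
#' Recomputes, for every accepted sweep record, the predicted 75% two-point
#' discrimination distance after neutralizing the chosen threshold factor(s):
#' `"no_damage"` sets the damage factor to 1 (thresholds drop, criterion
#' distances unchanged because the dip is scale-invariant), `"no_lift"` sets
#' the electrode flush to the retina (thresholds drop and the criterion
#' distance is recomputed at lift 0), `"neither"` does both. Stimulation
#' amplitude is re-derived as `min(2 * threshold, 660)` uA.
#'
#' @param sweep a [run_sweep()] result (or its accepted `records`).
#' @param ablation one of `"none"`, `"no_damage"`, `"no_lift"`, `"neither"`.
#' @param um_per_degree conversion used for the degree-valued summary.
#' @return Object of class `"ensemble_summary"`: the d75 distribution's
#'   median, interquartile range and central 95% range (um and degrees), the
#'   per-record values, and the ablation label.
#' @export
ablate_and_summarize <- function(sweep,
                                 ablation = c("none", "no_damage", "no_lift",
                                              "neither"),
                                 um_per_degree = 288) {
  ablation <- match.arg(ablation)
  rec <- if (inherits(sweep, "tpd_sweep")) sweep$records else sweep
  conv <- if (inherits(sweep, "tpd_sweep")) sweep$convention else "center"
  base <- if (inherits(sweep, "tpd_sweep")) sweep$theta_baseline_uA else 50
  rec <- rec[rec$accepted, , drop = FALSE]
  if (!nrow(rec)) stop("no accepted sweep records to summarize")

  no_lift <- ablation %in% c("no_lift", "neither")
  no_damage <- ablation %in% c("no_damage", "neither")
  lift <- if (no_lift) rep(0, nrow(rec)) else rec$lift_um
  theta_rd <- if (no_damage) rep(1, nrow(rec)) else rec$theta_rd

  # recompute threshold and criterion distance per unique configuration
  key <- paste(rec$a, rec$k, lift, rec$criterion_pct, theta_rd)
  uk <- !duplicated(key)
  lut <- new.env(parent = emptyenv())
  for (i in which(uk)) {
    p <- spread_params(a = rec$a[i], k = rec$k[i], theta_rd = theta_rd[i],
                       lift_um = lift[i], theta_baseline_uA = base,
                       distance_convention = conv)
    assign(key[i], c(thr = find_threshold(p),
                     d75 = as.numeric(dip_distance(p, rec$criterion_pct[i]))),
           envir = lut)
  }
  vals <- t(vapply(key, function(kk) get(kk, envir = lut), numeric(2)))
  d75 <- vals[, "d75"]
  thr <- vals[, "thr"]
  d75 <- d75[is.finite(d75)]
  qs <- stats::quantile(d75, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  structure(list(
    ablation = ablation,
    n = length(d75),
    median_um = qs[3],
    iqr_um = c(qs[2], qs[4]),
    ci95_um = c(qs[1], qs[5]),
    median_deg = qs[3] / um_per_degree,
    d75_um = d75,
    threshold_uA = thr,
    stim_uA = pmin(2 * thr, 660)
  ), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Predicted 75%% two-point thresholds (ablation: %s, n = %d)\n",
              x$ablation, x$n))
  cat(sprintf("  median %.0f um (%.1f deg); IQR [%.0f, %.0f]; 95%% [%.0f, %.0f] um\n",
              x$median_um, x$median_deg, x$iqr_um[1], x$iqr_um[2],
              x$ci95_um[1], x$ci95_um[2]))
  invisible(x)
}
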