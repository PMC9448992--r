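#' Study-condition defaults: detection thresholds and electrode sets
#'
#' Published per-participant study conditions used as defaults by the
#' synthetic-data generators: the median and interquartile range of the 50%
#' current-amplitude detection thresholds, and the electrode subsets tested
#' in each session of the two-point discrimination experiment.
#'
#' @return `study_thresholds()`: data.frame with `participant`, `median_uA`,
#'   `q1_uA`, `q3_uA`. `study_electrode_sets()`: nested list
#'   `[[participant]][[session]]` of electrode labels.
#' @export
study_thresholds <- function() {
  data.frame(participant = c("S1", "S2", "S3"),
             median_uA = c(274, 476, 210),
             q1_uA = c(218, 355, 177),
             q3_uA = c(331, 621, 280),
             stringsAsFactors = FALSE)
}

#' @rdname study_thresholds
#' @export
study_electrode_sets <- function() {
  list(
    S1 = list(session1 = c("A4", "A8", "D1", "E10", "F2"),
              session2 = c("A2", "A4", "A8", "B3", "B6", "D1", "D8", "E10",
                           "E3", "F2", "F7")),
    S2 = list(session1 = c("B6", "B9", "F7", "F9"),
              session2 = c("A10", "B10", "B5", "B6", "B9", "F7", "F9")),
    S3 = list(session1 = c("A8", "B10", "B4", "C6", "C8", "C9", "D6", "E9",
                           "F10"),
              session2 = c("A6", "A8", "B10", "B9", "D6", "F10")))
}

#' Configuration for the synthetic-data generators
#'
#' @param seed integer seed; required, drives every stochastic call.
#' @param n_reps_per_pair repetitions of each electrode pair per session
#'   (default 3, the per-run repetition count of the task).
#' @param catch_fraction fraction of all trials that are no-stimulation catch
#'   trials (default 0.25).
#' @param true_coefficients generating logistic coefficients (default: the
#'   published two-factor weights, [tpd_coefficients()]).
#' @param rate_zero probability that a response is replaced by "0" (no
#'   percept) as an independent nuisance overlay.
#' @param rate_three probability that a would-be "2" response is reported as
#'   "3".
#' @param false_alarm probability of reporting a percept on a catch trial.
#' @param placement_bounds list with `offset_um` (c(min, max), applied to x
#'   and y) and `rotation_deg` ranges for array placements.
#' @return Object of class `"generator_config"`.
#' @export
generator_config <- function(seed,
                             n_reps_per_pair = 3,
                             catch_fraction = 0.25,
                             true_coefficients = tpd_coefficients("two_factor"),
                             rate_zero = 0.02,
                             rate_three = 0.03,
                             false_alarm = 0.05,
                             placement_bounds = list(
                               offset_um = c(-600, 600),
                               rotation_deg = c(-50, -20))) {
  if (missing(seed) || !is.finite(seed)) stop("a seed is required")
  probs <- c(catch_fraction, rate_zero, rate_three, false_alarm)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (catch_fraction >= 1) stop("'catch_fraction' must be < 1")
  if (n_reps_per_pair < 1) stop("'n_reps_per_pair' must be >= 1")
  structure(list(seed = as.integer(seed), n_reps_per_pair = n_reps_per_pair,
                 catch_fraction = catch_fraction,
                 true_coefficients = true_coefficients,
                 rate_zero = rate_zero, rate_three = rate_three,
                 false_alarm = false_alarm,
                 placement_bounds = placement_bounds),
            class = "generator_config")
}

# run code under a local RNG state derived from (seed, salt)
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic small-integer salt from a string id
id_salt <- function(id) {
  v <- utf8ToInt(as.character(id))
  as.integer(sum(v * seq_along(v)) %% 10000L)
}

#' Draw a per-participant array placement
#'
#' Deterministic for a given (config seed, participant id): center offset and
#' rotation uniform within the configured bounds.
#'
#' @param config a [generator_config()].
#' @param participant_id participant identifier (string).
#' @return List with `center_offset_um` (length 2) and `rotation_deg`.
#' @export
gen_array_placement <- function(config, participant_id) {
  stopifnot(inherits(config, "generator_config"))
  b <- config$placement_bounds
  with_seed(config$seed + id_salt(participant_id), {
    list(center_offset_um = stats::runif(2, b$offset_um[1], b$offset_um[2]),
         rotation_deg = stats::runif(1, b$rotation_deg[1], b$rotation_deg[2]))
  })
}

#' Generate a synthetic two-point discrimination trial set
#'
#' For each supplied electrode pair, generates `n_reps_per_pair` trials whose
#' reported percept count is 2 with the probability given by the generating
#' logistic model (else 1), overlaid with small nuisance rates of "0" and
#' "3" reports, plus randomly interspersed no-stimulation catch trials at
#' `catch_fraction` of the total trial count.
#'
#' @param config a [generator_config()].
#' @param pairs data.frame with columns `electrode_1`, `electrode_2`,
#'   `mean_amplitude_uA`, `physical_um`, `to_axon_um` (and optionally
#'   `participant`, `session`).
#' @param salt integer offset added to the seed (used to decorrelate
#'   multiple sets from one config).
#' @return data.frame of trial records: `participant`, `session`,
#'   `electrode_1`, `electrode_2`, `mean_amplitude_uA`, `physical_um`,
#'   `to_axon_um`, `reported_count`, `is_catch`.
#' @export
gen_trial_set <- function(config, pairs, salt = 0L) {
  stopifnot(inherits(config, "generator_config"), is.data.frame(pairs),
            nrow(pairs) > 0)
  need <- c("electrode_1", "electrode_2", "mean_amplitude_uA", "physical_um",
            "to_axon_um")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("pairs missing column(s): ", paste(miss, collapse = ", "))
  model <- as_tpd_logit(config$true_coefficients)
  reps <- pairs[rep(seq_len(nrow(pairs)), each = config$n_reps_per_pair), ,
                drop = FALSE]
  p2 <- predict_p2(model, reps$mean_amplitude_uA, reps$physical_um,
                   to_axon_um = reps$to_axon_um)
  n_stim <- nrow(reps)
  n_catch <- round(n_stim * config$catch_fraction / (1 - config$catch_fraction))
  with_seed(config$seed + 7L + salt, {
    base <- ifelse(stats::runif(n_stim) < p2, 2L, 1L)
    u0 <- stats::runif(n_stim) < config$rate_zero
    u3 <- stats::runif(n_stim) < config$rate_three
    cnt <- base
    cnt[base == 2L & u3] <- 3L
    cnt[u0] <- 0L
    stim <- data.frame(
      participant = if ("participant" %in% names(reps)) reps$participant else "S0",
      session = if ("session" %in% names(reps)) reps$session else 1L,
      electrode_1 = reps$electrode_1, electrode_2 = reps$electrode_2,
      mean_amplitude_uA = reps$mean_amplitude_uA,
      physical_um = reps$physical_um, to_axon_um = reps$to_axon_um,
      reported_count = cnt, is_catch = FALSE, stringsAsFactors = FALSE)
    if (n_catch > 0) {
      catch <- data.frame(
        participant = stim$participant[1], session = stim$session[1],
        electrode_1 = NA_character_, electrode_2 = NA_character_,
        mean_amplitude_uA = NA_real_, physical_um = NA_real_,
        to_axon_um = NA_real_,
        reported_count = as.integer(stats::runif(n_catch) < config$false_alarm),
        is_catch = TRUE, stringsAsFactors = FALSE)
      stim <- rbind(stim, catch)
    }
    out <- stim[sample.int(nrow(stim)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a yes/no detection staircase
#'
#' Simple 1-up-1-down staircase around a logistic psychometric function:
#' detection at each presented amplitude is Bernoulli with probability
#' `logistic(slope * (amplitude - true_threshold))`; a detection lowers the
#' next amplitude by one step, a miss raises it.
#'
#' @param config a [generator_config()] (seed source).
#' @param true_threshold_uA true 50% detection threshold (uA).
#' @param slope psychometric slope (logit per uA).
#' @param n_trials number of staircase trials.
#' @param start_uA starting amplitude (uA).
#' @param step_uA staircase step size (uA).
#' @param salt integer offset added to the seed.
#' @return data.frame with `amplitude_uA`, `detected`.
#' @export
gen_yesno_staircase <- function(config, true_threshold_uA = 274, slope = 0.03,
                                n_trials = 60, start_uA = 100, step_uA = 20,
                                salt = 0L) {
  stopifnot(inherits(config, "generator_config"))
  if (slope <= 0) stop("'slope' must be positive")
  with_seed(config$seed + 23L + salt, {
    amp <- numeric(n_trials)
    det <- logical(n_trials)
    a <- start_uA
    for (i in seq_len(n_trials)) {
      amp[i] <- a
      p <- logistic(slope * (a - true_threshold_uA))
      det[i] <- stats::runif(1) < p
      a <- max(0, a + if (det[i]) -step_uA else step_uA)
    }
    data.frame(amplitude_uA = amp, detected = det)
  })
}

#' Synthesize a full multi-participant study dataset
#'
#' Builds the complete synthetic study emulated by the generators: an axon
#' bundle map, one array placement per participant, per-session electrode
#' sets, per-electrode detection thresholds drawn uniformly within each
#' participant's published interquartile range, pair geometry from the map,
#' and trial sets per session.
#'
#' @param config a [generator_config()]; its `true_coefficients` drive the
#'   response generation (supply the three-factor set to include axonal
#'   effects).
#' @param eye an [eye_geometry()].
#' @param n_bundles bundle count for the axon map.
#' @param sampling_step_um polyline step for the map (um).
#' @param participants participant ids (default: the three study
#'   participants).
#' @param electrode_sets nested list `[[participant]][[session]]` of labels;
#'   default [study_electrode_sets()].
#' @param thresholds data.frame as [study_thresholds()].
#' @return List with `trials` (all participants/sessions combined), `pairs`
#'   (geometry + amplitude per pair), `placements`, `map`, `arrays`.
#' @export
synthesize_study <- function(config,
                             eye = eye_geometry(),
                             n_bundles = 400,
                             sampling_step_um = 20,
                             participants = c("S1", "S2", "S3"),
                             electrode_sets = study_electrode_sets(),
                             thresholds = study_thresholds()) {
  stopifnot(inherits(config, "generator_config"))
  map <- build_axon_map(eye, n_bundles = n_bundles,
                        sampling_step_um = sampling_step_um)
  placements <- lapply(stats::setNames(participants, participants),
                       function(p) gen_array_placement(config, p))
  arrays <- lapply(placements, function(pl) {
    electrode_array(center_offset = pl$center_offset_um,
                    rotation_deg = pl$rotation_deg)
  })
  all_trials <- list()
  all_pairs <- list()
  for (p in participants) {
    arr <- arrays[[p]]
    th <- thresholds[thresholds$participant == p, ]
    if (!nrow(th)) stop("no threshold row for participant ", p)
    sets <- electrode_sets[[p]]
    if (is.null(sets)) stop("no electrode set for participant ", p)
    electrodes <- sort(unique(unlist(sets)))
    elec_thr <- with_seed(config$seed + 101L + id_salt(p), {
      stats::setNames(stats::runif(length(electrodes), th$q1_uA, th$q3_uA),
                      electrodes)
    })
    geom <- all_pair_distances(arr, map, electrodes = electrodes)
    key <- paste(geom$electrode_1, geom$electrode_2)
    for (s in seq_along(sets)) {
      set_s <- sets[[s]]
      if (length(set_s) < 2) next
      cmb <- utils::combn(sort(set_s), 2)
      pk <- paste(cmb[1, ], cmb[2, ])
      gi <- match(pk, key)
      pairs <- geom[gi, , drop = FALSE]
      pairs$mean_amplitude_uA <-
        (elec_thr[pairs$electrode_1] + elec_thr[pairs$electrode_2]) / 2
      pairs$participant <- p
      pairs$session <- s
      all_pairs[[paste(p, s)]] <- pairs
      all_trials[[paste(p, s)]] <-
        gen_trial_set(config, pairs, salt = 977L * s + id_salt(p))
    }
  }
  trials <- do.call(rbind, all_trials)
  rownames(trials) <- NULL
  pairs <- do.call(rbind, all_pairs)
  rownames(pairs) <- NULL
  list(trials = trials, pairs = pairs, placements = placements,
       map = map, arrays = arrays)
}
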