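#' Pipeline configuration
#'
#' Assembles the configuration list that drives the orchestration functions
#' ([pipeline_distances()], [pipeline_fit()], [pipeline_sweep()],
#' [pipeline_synth()]). Any field can be overridden; `read_pipeline_config()`
#' loads the same structure from a YAML or JSON file.
#'
#' @param ... overrides of the defaults.
#' @return A classed list of settings.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = "tpd-output",
    participants = c("S1", "S2", "S3"),
    electrode_sets = study_electrode_sets(),
    thresholds = study_thresholds(),
    placements = NULL,            # NULL: generated from the seed
    n_bundles = 400,
    sampling_step_um = 20,
    coeff_source = "two_factor",
    p_target = 0.75,
    amplitude_range_uA = c(177, 660),
    reference_replicates = 15,
    sweep_grid = list(),
    mse_bound = 20,
    threshold_range = c(177, 660),
    convention = "center",
    ablations = c("none", "no_damage", "no_lift", "neither"))
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  cfg <- utils::modifyList(cfg, over)
  if (cfg$p_target <= 0 || cfg$p_target >= 1) stop("p_target must be in (0,1)")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  pipeline_config(raw)
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg[sort(names(cfg))]), collapse = "")
  v <- utf8ToInt(s)
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2^31
  sprintf("%08x", h)
}

write_csv_meta <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tpdiscrim %s; config_hash=%s",
                     as.character(utils::packageVersion("tpdiscrim")),
                     config_hash(cfg)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

resolve_placement <- function(cfg, gc, participant) {
  if (is.null(cfg$placements)) return(gen_array_placement(gc, participant))
  pl <- cfg$placements[[participant]]
  if (is.null(pl)) stop("no array placement configured for participant ",
                        participant)
  pl
}

#' Compute per-pair distance tables
#'
#' Builds the axon map and one placed array per participant, computes the
#' three distance measures for every electrode pair of that participant's
#' tested set, and writes one CSV per participant plus a combined table.
#'
#' @param config a [pipeline_config()].
#' @return Combined data.frame of pair distances (invisibly).
#' @export
pipeline_distances <- function(config = pipeline_config()) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  gc <- generator_config(seed = cfg$seed)
  eye <- eye_geometry()
  map <- build_axon_map(eye, n_bundles = cfg$n_bundles,
                        sampling_step_um = cfg$sampling_step_um)
  out <- list()
  for (p in cfg$participants) {
    pl <- resolve_placement(cfg, gc, p)
    arr <- electrode_array(center_offset = pl$center_offset_um,
                           rotation_deg = pl$rotation_deg)
    electrodes <- sort(unique(unlist(cfg$electrode_sets[[p]])))
    d <- all_pair_distances(arr, map, electrodes = electrodes)
    d$participant <- p
    message(sprintf("[distances] %s: %d electrodes, %d pairs", p,
                    length(electrodes), nrow(d)))
    write_csv_meta(d, file.path(cfg$out_dir, paste0("distances_", p, ".csv")),
                   cfg)
    out[[p]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  write_csv_meta(res, file.path(cfg$out_dir, "distances.csv"), cfg)
  invisible(res)
}

#' Reference contour: 75% iso-performance under minimal axonal stimulation
#'
#' Reproduces the frozen-weight analysis at the population level: electrode
#' pairs are laid out over package-built axon geometry (placements and
#' per-electrode detection thresholds drawn from the study conditions and
#' pooled over `n_replicates` independent draws), the expected probability of
#' reporting two percepts is computed from the published three-factor
#' coefficients, the two-factor weights are frozen at the chosen source
#' values, the to-axon coefficient is refit against those expected
#' frequencies, and the model is inverted with the to-axon distance tied to
#' the physical distance (minimal axonal stimulation). Fitting expected
#' frequencies rather than sampled responses removes trial-level noise from
#' the reference, which otherwise propagates through the sweep's hard
#' acceptance rules; the pooling averages over placement variability.
#'
#' @param config a [pipeline_config()].
#' @param n_replicates number of placement/threshold draws pooled into the
#'   pair design.
#' @return An [iso_performance_contour()]; attributes `model` (the augmented
#'   fit) and `axon_coefficient`.
#' @export
minimal_axon_reference <- function(config = pipeline_config(),
                                   n_replicates = NULL) {
  cfg <- config
  if (is.null(n_replicates)) {
    n_replicates <- if (is.null(cfg$reference_replicates)) 15 else
      cfg$reference_replicates
  }
  cohorts <- lapply(seq_len(n_replicates), function(r) {
    gc <- generator_config(seed = cfg$seed + 9973L * (r - 1L),
                           n_reps_per_pair = 1,
                           true_coefficients = tpd_coefficients("three_factor"))
    synthesize_study(gc, n_bundles = cfg$n_bundles,
                     sampling_step_um = cfg$sampling_step_um,
                     participants = cfg$participants,
                     electrode_sets = cfg$electrode_sets,
                     thresholds = cfg$thresholds)$pairs
  })
  design <- do.call(rbind, cohorts)
  truth <- as_tpd_logit(tpd_coefficients("three_factor"))
  design$outcome <- predict_p2(truth, design$mean_amplitude_uA,
                               design$physical_um, design$to_axon_um)
  base <- as_tpd_logit(tpd_coefficients(cfg$coeff_source))
  aug <- fixed_weight_augment(base, design, new_factor = "to_axon_um")
  amps <- seq(cfg$amplitude_range_uA[1], cfg$amplitude_range_uA[2], by = 1)
  ref <- iso_performance_contour(aug, amplitudes_uA = amps,
                                 p_target = cfg$p_target,
                                 axon = "equal_physical")
  attr(ref, "model") <- aug
  attr(ref, "axon_coefficient") <- unname(coef(aug)["to_axon_um"])
  ref
}

#' Fit and invert the two-point discrimination model
#'
#' Builds the model from the configured coefficient source (`"two_factor"`,
#' `"two_factor_rounded"`, `"three_factor"`, or `"fit"` to fit from supplied trials), writes the
#' model JSON, the iso-performance contour, and the predicted two-point
#' discrimination thresholds (um and degrees) at each participant's median
#' detection threshold amplitude.
#'
#' @param config a [pipeline_config()].
#' @param trials optional trial data.frame (required for
#'   `coeff_source = "fit"`).
#' @return List with `model`, `thresholds` (data.frame), `contour`
#'   (invisibly).
#' @export
pipeline_fit <- function(config = pipeline_config(), trials = NULL) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- if (identical(cfg$coeff_source, "fit")) {
    if (is.null(trials)) stop("coeff_source='fit' requires trials")
    fit_logistic(preprocess_trials(trials))
  } else {
    as_tpd_logit(tpd_coefficients(cfg$coeff_source))
  }
  th <- cfg$thresholds
  d <- iso_distance(model, th$median_uA, p_target = cfg$p_target)
  thresholds <- data.frame(participant = th$participant,
                           amplitude_uA = th$median_uA,
                           threshold_um = round(d),
                           threshold_deg = round(um_to_deg(d), 1))
  message(sprintf("[fit] %s model; %d%% thresholds: %s", cfg$coeff_source,
                  round(100 * cfg$p_target),
                  paste(sprintf("%s=%d um", thresholds$participant,
                                thresholds$threshold_um), collapse = ", ")))
  amps <- seq(cfg$amplitude_range_uA[1], cfg$amplitude_range_uA[2], by = 1)
  contour <- iso_performance_contour(model, amps, p_target = cfg$p_target)
  jsonlite::write_json(
    list(coefficients = as.list(coef(model)), frozen = model$frozen,
         log_likelihood = model$log_likelihood, n_obs = model$n_obs,
         convergence = model$convergence, config_hash = config_hash(cfg)),
    file.path(cfg$out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
  write_csv_meta(thresholds, file.path(cfg$out_dir, "thresholds.csv"), cfg)
  write_csv_meta(contour, file.path(cfg$out_dir, "iso_contour.csv"), cfg)
  invisible(list(model = model, thresholds = thresholds, contour = contour))
}

#' Run the current-spread sweep and ablation summaries
#'
#' Builds the minimal-axon reference contour, runs the full parameter sweep,
#' applies the acceptance rules, and writes the sweep records plus one
#' ensemble summary per configured ablation.
#'
#' @param config a [pipeline_config()].
#' @param reference optional precomputed reference contour (default:
#'   [minimal_axon_reference()]).
#' @return List with `sweep` and `summaries` (invisibly).
#' @export
pipeline_sweep <- function(config = pipeline_config(), reference = NULL) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(reference)) reference <- minimal_axon_reference(cfg)
  sweep <- run_sweep(grid = cfg$sweep_grid, reference = reference,
                     convention = cfg$convention, mse_bound = cfg$mse_bound,
                     threshold_range = cfg$threshold_range)
  rec <- sweep$records
  message(sprintf("[sweep] %d records, %d accepted (threshold rule: %d, contour rule: %d)",
                  nrow(rec), sum(rec$accepted),
                  sum(rec$threshold_uA >= cfg$threshold_range[1] &
                      rec$threshold_uA <= cfg$threshold_range[2]),
                  sum(rec$contour_mse < cfg$mse_bound)))
  write_csv_meta(rec, file.path(cfg$out_dir, "sweep_records.csv"), cfg)
  summaries <- list()
  if (!sum(rec$accepted)) {
    warning("no sweep parameterization was accepted; summaries are empty")
    jsonlite::write_json(list(empty = TRUE, n_accepted = 0,
                              config_hash = config_hash(cfg)),
                         file.path(cfg$out_dir, "sweep_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    for (ab in cfg$ablations) {
      s <- ablate_and_summarize(sweep, ablation = ab)
      summaries[[ab]] <- list(
        ablation = ab, n = s$n, median_um = s$median_um,
        median_deg = s$median_deg, iqr_um = s$iqr_um, ci95_um = s$ci95_um)
      message(sprintf("[sweep] ablation %-9s median %.0f um (%.1f deg)",
                      ab, s$median_um, s$median_deg))
    }
    jsonlite::write_json(list(summaries = summaries,
                              config_hash = config_hash(cfg)),
                         file.path(cfg$out_dir, "sweep_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(sweep = sweep, summaries = summaries))
}

#' Generate synthetic fixture CSVs
#'
#' Synthesizes a study-shaped dataset at the configured seed and writes the
#' trial and pair tables.
#'
#' @param config a [pipeline_config()].
#' @param n_reps_per_pair repetitions per pair per session (default 3, the
#'   study condition).
#' @return List with `trials` and `pairs` (invisibly).
#' @export
pipeline_synth <- function(config = pipeline_config(), n_reps_per_pair = 3) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  gc <- generator_config(seed = cfg$seed, n_reps_per_pair = n_reps_per_pair)
  study <- synthesize_study(gc, n_bundles = cfg$n_bundles,
                            sampling_step_um = cfg$sampling_step_um,
                            participants = cfg$participants,
                            electrode_sets = cfg$electrode_sets,
                            thresholds = cfg$thresholds)
  message(sprintf("[synth] %d trials (%d catch) over %d pairs",
                  nrow(study$trials), sum(study$trials$is_catch),
                  nrow(study$pairs)))
  write_csv_meta(study$trials, file.path(cfg$out_dir, "trials.csv"), cfg)
  write_csv_meta(study$pairs, file.path(cfg$out_dir, "pairs.csv"), cfg)
  invisible(study)
}
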