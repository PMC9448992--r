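# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# full-size axon map (400 bundles); cheap enough to share across files
test_map <- function() {
  if (is.null(.fixture_env$map)) {
    .fixture_env$map <- build_axon_map(eye_geometry(), n_bundles = 400,
                                       sampling_step_um = 20)
  }
  .fixture_env$map
}

test_array <- function() {
  electrode_array(center_offset = c(-300, 200), rotation_deg = -35)
}

# ten spread-out electrodes used for geometry checks
test_electrodes <- c("A1", "A8", "B3", "C6", "C9", "D1", "D6", "E10", "F2", "F7")

# synthetic trial design with no geometry: uniform amplitudes and distances,
# to-axon uniform below the physical distance
make_design <- function(n, seed) {
  set.seed(seed)
  d <- data.frame(
    electrode_1 = sprintf("P%04d", seq_len(n)),
    electrode_2 = sprintf("Q%04d", seq_len(n)),
    mean_amplitude_uA = runif(n, 177, 660),
    physical_um = runif(n, 575, 5750),
    stringsAsFactors = FALSE)
  d$to_axon_um <- runif(n, 0, d$physical_um)
  d
}

# clean Bernoulli trials from a coefficient vector over a design
make_trials <- function(coefs, n, seed) {
  design <- make_design(n, seed)
  cfg <- generator_config(seed = seed, n_reps_per_pair = 1,
                          catch_fraction = 0, true_coefficients = coefs,
                          rate_zero = 0, rate_three = 0)
  preprocess_trials(gen_trial_set(cfg, design))
}

# brute-force oracle: nearest bundle and vertex distances by plain loops
oracle_nearest_bundle <- function(map, p) {
  best <- Inf; bi <- NA_integer_
  for (i in seq_along(map$bundles)) {
    b <- map$bundles[[i]]
    for (v in seq_len(nrow(b))) {
      dd <- (b[v, 1] - p[1])^2 + (b[v, 2] - p[2])^2
      if (dd < best) { best <- dd; bi <- i }
    }
  }
  list(index = bi, distance_um = sqrt(best))
}

oracle_point_bundle <- function(b, p) {
  best <- Inf
  for (v in seq_len(nrow(b))) {
    dd <- (b[v, 1] - p[1])^2 + (b[v, 2] - p[2])^2
    if (dd < best) best <- dd
  }
  sqrt(best)
}
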