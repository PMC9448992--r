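test_that("axon bundle map satisfies its structural invariants", {
  map <- test_map()
  eye <- map$eye
  expect_length(map$bundles, 400)

  # no polyline crosses the raphe parabola
  crossing <- vapply(map$bundles, function(b) {
    s <- raphe_side(map$raphe, b)
    any(s == 1L) && any(s == -1L)
  }, logical(1))
  expect_false(any(crossing))

  # every polyline runs from the periphery and ends within the disc circle
  od <- eye$optic_disc_um
  end_r <- vapply(map$bundles, function(b) {
    sqrt(sum((b[nrow(b), ] - od)^2))
  }, numeric(1))
  start_r <- vapply(map$bundles, function(b) sqrt(sum((b[1, ] - od)^2)),
                    numeric(1))
  expect_true(all(end_r <= eye$optic_disc_radius_um + 1e-6))
  expect_true(all(start_r >= end_r))

  # uniform resampling: consecutive vertices never farther than the step
  max_seg <- vapply(map$bundles, function(b) {
    if (nrow(b) < 2) return(0)
    max(sqrt(diff(b[, 1])^2 + diff(b[, 2])^2))
  }, numeric(1))
  expect_true(all(max_seg <= map$sampling_step_um + 1e-6))
})

test_that("bundle density covers the array footprint", {
  map <- test_map()
  # probe a grid over a macular array footprint; every probe should be
  # within roughly one inter-bundle spacing of some bundle
  probes <- as.matrix(expand.grid(seq(-3200, 2600, by = 400),
                                  seq(-2000, 2400, by = 400)))
  d <- apply(probes, 1, function(p) nearest_bundle(map, p)$distance_um)
  expect_lt(max(d), 150)
})

test_that("trajectory configuration errors are caught", {
  eye <- eye_geometry()
  expect_error(build_axon_map(eye, n_bundles = 0), "n_bundles")
  expect_error(build_axon_map(eye, trajectory_params = list(beta_sup = NaN)),
               "configuration error")
  expect_error(build_axon_map(eye, trajectory_params = list(beta_sup = 99)),
               "published range")
  expect_error(build_axon_map(eye, trajectory_params = list(r_max_deg = 2)),
               "configuration error")
})

test_that("raphe parabola has the documented orientation and symmetry", {
  eye0 <- eye_geometry(raphe_angle_deg = 0)
  rp0 <- fit_raphe(eye0)
  # raphe angle 0: axis parallel to the horizontal through the disc
  expect_equal(abs(sin(rp0$axis_angle_deg * pi / 180)), 0, tolerance = 1e-12)

  # raphe angle 15: the extended raphe lies inferior to the fovea latitude
  eye15 <- eye_geometry(raphe_angle_deg = 15)
  rp15 <- fit_raphe(eye15)
  fr <- tpdiscrim:::disc_frame(eye15)
  far <- eye15$optic_disc_um + fr$xhat * (sqrt(sum(eye15$optic_disc_um^2)) + 2000)
  expect_lt(far[2], 0)

  # reflecting the eye geometry across the horizontal reflects the parabola
  eye_refl <- eye_geometry(optic_disc_deg = c(15, -2), raphe_angle_deg = -15)
  rp_refl <- fit_raphe(eye_refl)
  expect_equal(rp_refl$vertex_um[2], -rp15$vertex_um[2])
  expect_equal(rp_refl$axis_angle_deg %% 360, (-rp15$axis_angle_deg) %% 360,
               tolerance = 1e-9)

  expect_error(fit_raphe(eye_geometry(optic_disc_deg = c(1e-9, 0))))
})

test_that("electrode array placement is a rigid transform of the 6x10 grid", {
  arr <- electrode_array()
  expect_length(arr$labels, 60)
  # horizontal neighbors exactly one pitch apart
  expect_equal(sqrt(sum((electrode_position(arr, "A1") -
                           electrode_position(arr, "A2"))^2)), 575)
  # diagonal neighbors at pitch * sqrt(2)
  expect_equal(sqrt(sum((electrode_position(arr, "A1") -
                           electrode_position(arr, "B2"))^2)), 575 * sqrt(2),
               tolerance = 1e-9)
  # nearest-neighbor distance equals the pitch after any rigid placement
  placed <- electrode_array(center_offset = c(-437, 212), rotation_deg = -38)
  D <- as.matrix(dist(placed$positions))
  diag(D) <- Inf
  expect_equal(min(D), 575, tolerance = 1e-9)
  # rotation by 90 degrees leaves all pairwise distances unchanged
  rot <- electrode_array(rotation_deg = 90)
  expect_equal(as.matrix(dist(rot$positions)), as.matrix(dist(arr$positions)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("pair distances agree with a brute-force polyline oracle", {
  map <- test_map()
  arr <- test_array()
  set.seed(71)
  pick <- matrix(sample(arr$labels, 8), ncol = 2)
  for (i in seq_len(nrow(pick))) {
    e1 <- pick[i, 1]; e2 <- pick[i, 2]
    got <- pair_distances(e1, e2, arr, map)
    p1 <- electrode_position(arr, e1); p2 <- electrode_position(arr, e2)
    expect_equal(got$physical_um, sqrt(sum((p1 - p2)^2)))
    nb1 <- oracle_nearest_bundle(map, p1)
    nb2 <- oracle_nearest_bundle(map, p2)
    a1 <- map$bundles[[nb1$index]]; a2 <- map$bundles[[nb2$index]]
    d12 <- oracle_point_bundle(a2, p1)
    d21 <- oracle_point_bundle(a1, p2)
    expect_equal(got$to_axon_um, min(d12, d21))
    # along-axon: arc length on the fellow bundle between the to-axon foot
    # and the vertex beneath the fellow electrode
    fellow <- if (d12 <= d21) a2 else a1
    pn <- if (d12 <= d21) p1 else p2
    pf <- if (d12 <= d21) p2 else p1
    di <- sqrt((fellow[, 1] - pn[1])^2 + (fellow[, 2] - pn[2])^2)
    dj <- sqrt((fellow[, 1] - pf[1])^2 + (fellow[, 2] - pf[2])^2)
    seg <- sqrt(diff(fellow[, 1])^2 + diff(fellow[, 2])^2)
    s <- c(0, cumsum(seg))
    expect_equal(got$along_axon_um, abs(s[which.min(dj)] - s[which.min(di)]))
  }
})

test_that("nearest-bundle queries match a brute-force vertex scan", {
  map <- test_map()
  set.seed(5)
  probes <- cbind(runif(40, -3000, 3000), runif(40, -2500, 2500))
  for (i in seq_len(nrow(probes))) {
    got <- nearest_bundle(map, probes[i, ])
    ora <- oracle_nearest_bundle(map, probes[i, ])
    expect_equal(got$distance_um, ora$distance_um)
    expect_equal(got$index, ora$index)
  }
})

test_that("distance measures respect their geometric invariants", {
  map <- test_map()
  arr <- test_array()
  d <- all_pair_distances(arr, map, electrodes = test_electrodes)
  expect_equal(nrow(d), choose(10, 2))
  expect_true(all(d$physical_um >= 0 & d$to_axon_um >= 0 & d$along_axon_um >= 0))
  # the fellow bundle passes beneath the fellow electrode
  expect_true(all(d$to_axon_um <= d$physical_um + map$sampling_step_um))

  # degenerate same-electrode pair
  expect_equal(unlist(pair_distances("C5", "C5", arr, map)[, 3:5]),
               c(physical_um = 0, to_axon_um = 0, along_axon_um = 0))

  # a point on a bundle vertex is within one sampling step of that bundle
  b <- map$bundles[[200]]
  v <- b[round(nrow(b) / 2), ]
  expect_lte(nearest_bundle(map, v)$distance_um, map$sampling_step_um)
})

test_that("distances are invariant under joint rigid transforms", {
  map <- test_map()
  arr <- test_array()
  ref <- pair_distances("B3", "E7", arr, map)
  th <- 33 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(812, -387)
  map2 <- map
  map2$bundles <- lapply(map$bundles, function(b) {
    sweep(b %*% t(R), 2, -shift)
  })
  arr2 <- electrode_array(
    center_offset = drop(R %*% arr$center_offset) + shift,
    rotation_deg = arr$rotation_deg + 33)
  got <- pair_distances("B3", "E7", arr2, map2)
  expect_equal(got$physical_um, ref$physical_um, tolerance = 1e-9)
  expect_equal(got$to_axon_um, ref$to_axon_um, tolerance = 1e-6)
  expect_equal(got$along_axon_um, ref$along_axon_um, tolerance = 1e-6)
})

test_that("doubling polyline sampling density barely moves the distances", {
  eye <- eye_geometry()
  coarse <- build_axon_map(eye, n_bundles = 150, sampling_step_um = 40)
  fine <- build_axon_map(eye, n_bundles = 150, sampling_step_um = 20)
  arr <- test_array()
  pairs <- rbind(c("A2", "D7"), c("B9", "F3"), c("C4", "E8"))
  for (i in seq_len(nrow(pairs))) {
    dc <- pair_distances(pairs[i, 1], pairs[i, 2], arr, coarse)
    df <- pair_distances(pairs[i, 1], pairs[i, 2], arr, fine)
    expect_lt(abs(dc$to_axon_um - df$to_axon_um), 40)
    expect_lt(abs(dc$along_axon_um - df$along_axon_um), 40 + 40)
  }
})

test_that("distance correlation report reproduces the expected structure", {
  d <- data.frame(physical_um = c(1, 2, 3), to_axon_um = c(1, 2, 3),
                  along_axon_um = c(1, 2, 3))
  expect_equal(unname(distance_correlation_report(d)), matrix(1, 3, 3))
  expect_error(distance_correlation_report(d[1:2, ]), "at least 3")
  dc <- d; dc$to_axon_um <- 1
  expect_warning(r <- distance_correlation_report(dc), "constant")
  expect_true(anyNA(r))

  # plausible placements: along-axon tracks the physical distance much more
  # strongly than it tracks the to-axon distance
  map <- test_map()
  arr <- test_array()
  full <- all_pair_distances(arr, map, electrodes = test_electrodes)
  r <- distance_correlation_report(full)
  expect_gt(r["physical_um", "along_axon_um"], r["to_axon_um", "along_axon_um"])
})
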