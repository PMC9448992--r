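test_that("trial preprocessing applies the discard and collapse rules", {
  # category counts 0:2, 1:29, 2:20, 3:3 -> 52 retained, 23 positive
  tr <- data.frame(reported_count = rep(c(0, 1, 2, 3), c(2, 29, 20, 3)))
  out <- preprocess_trials(tr)
  expect_equal(nrow(out), 52)
  expect_equal(sum(out$outcome), 23)
  lg <- attr(out, "log")
  expect_equal(unname(lg["n_zero_discarded"]), 2)
  expect_equal(unname(lg["n_collapsed_3plus"]), 3)

  # all zero reports -> empty analysis set
  expect_equal(nrow(preprocess_trials(data.frame(reported_count = rep(0, 5)))), 0)

  # counts only in {1, 2}: nothing removed, nothing collapsed
  tr12 <- data.frame(reported_count = c(1, 2, 1, 2, 2))
  out12 <- preprocess_trials(tr12)
  expect_equal(nrow(out12), 5)
  expect_equal(out12$outcome, c(0, 1, 0, 1, 1))

  # counts above 3 are binned to 3 and collapse to outcome 1
  expect_equal(preprocess_trials(data.frame(reported_count = 7))$outcome, 1L)

  # catch trials are removed before anything else
  trc <- data.frame(reported_count = c(2, 0), is_catch = c(FALSE, TRUE))
  expect_equal(nrow(preprocess_trials(trc)), 1)
})

test_that("response probabilities are frequency-derived and sum to one", {
  expect_equal(round(response_probabilities(c(2, 29, 20, 3)), 2),
               c(`0` = 0.04, `1` = 0.54, `2` = 0.37, `3` = 0.06))
  expect_equal(round(response_probabilities(c(0, 38, 67, 0)), 2),
               c(`0` = 0, `1` = 0.36, `2` = 0.64, `3` = 0))
  expect_equal(unname(response_probabilities(c(0, 0, 10, 0))), c(0, 0, 1, 0))
  expect_equal(sum(response_probabilities(c(7, 3, 11, 2))), 1)
  expect_error(response_probabilities(c(0, 0, 0, 0)))
})

test_that("logistic fitting recovers known coefficients and matches glm", {
  # intercept-only with half the outcomes positive: logit(0.5) = 0
  half <- data.frame(outcome = rep(c(0, 1), 50))
  m0 <- fit_logistic(half, factors = character(0))
  expect_equal(unname(coef(m0)["intercept"]), 0, tolerance = 1e-8)

  # 5,000 seeded trials from the published two-factor weights: every
  # coefficient recovered within 3 standard errors
  truth <- tpd_coefficients("two_factor")
  tr <- make_trials(truth, 5000, seed = 301)
  fit <- fit_logistic(tr)
  expect_true(fit$convergence)
  expect_true(all(abs(coef(fit) - truth) < 3 * fit$se[names(truth)]))

  # independent cross-check: agrees with stats::glm on the same data
  gfit <- stats::glm(outcome ~ mean_amplitude_uA + physical_um,
                     family = binomial(), data = tr)
  expect_equal(unname(coef(fit)),
               unname(coef(gfit)[c("(Intercept)", "mean_amplitude_uA",
                                   "physical_um")]),
               tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(logLik(gfit)), tolerance = 1e-8)

  # perfectly separable data is flagged as non-convergence
  sep <- data.frame(outcome = rep(c(0, 1), each = 20),
                    mean_amplitude_uA = c(seq(500, 600, length.out = 20),
                                          seq(200, 300, length.out = 20)),
                    physical_um = 1000)
  msep <- fit_logistic(sep, factors = "mean_amplitude_uA")
  expect_false(msep$convergence)

  # singular design names the collinear factor
  bad <- tr
  bad$copy <- bad$physical_um
  expect_error(fit_logistic(bad, factors = c("physical_um", "copy")),
               "singular design")

  # one-class outcomes cannot identify free coefficients
  ones <- data.frame(outcome = rep(1, 10), mean_amplitude_uA = 1:10,
                     physical_um = 1:10)
  expect_error(fit_logistic(ones), "outcome class")
})

test_that("likelihood-ratio machinery is internally consistent", {
  truth <- tpd_coefficients("two_factor")
  tr <- make_trials(truth, 1500, seed = 17)
  m2 <- fit_logistic(tr)
  m3 <- fit_logistic(tr, factors = c("mean_amplitude_uA", "physical_um",
                                     "to_axon_um"))
  same <- lr_test(m2, m2)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  lt <- lr_test(m2, m3)
  expect_equal(lt$chi2, 2 * (m3$log_likelihood - m2$log_likelihood))
  expect_equal(lt$df, 1)
  expect_gte(lt$chi2, 0)
  expect_equal(lt$p, pchisq(lt$chi2, 1, lower.tail = FALSE))

  tab <- anova(m2, m3)
  expect_equal(tab$chi2[2], lt$chi2)

  other <- make_trials(truth, 1500, seed = 18)
  expect_error(lr_test(fit_logistic(other), m3), "different trials")

  # a pure-noise factor yields approximately uniform p values
  set.seed(99)
  ps <- replicate(150, {
    d <- make_trials(truth, 400, seed = sample.int(1e6, 1))
    d$noise <- rnorm(nrow(d))
    nested <- fit_logistic(d)
    full <- fit_logistic(d, factors = c("mean_amplitude_uA", "physical_um",
                                        "noise"))
    lr_test(nested, full)$p
  })
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_lt(abs(mean(ps < 0.25) - 0.25), 0.12)
})

test_that("predicted probabilities and iso-distance inversion agree", {
  zero <- as_tpd_logit(c(intercept = 0, mean_amplitude_uA = 0,
                         physical_um = 0))
  expect_equal(predict_p2(zero, 500, 3000), 0.5)

  # direct hand evaluation of the three-factor equation
  m3f <- as_tpd_logit(tpd_coefficients("three_factor"))
  expect_equal(predict_p2(m3f, 274, 1000, to_axon_um = 0),
               1 / (1 + exp(0.1839 + 0.0030 * 274 - 0.000602 * 1000)),
               tolerance = 1e-12)
  expect_equal(round(predict_p2(m3f, 274, 1000, to_axon_um = 0), 3), 0.400)
  expect_error(predict_p2(m3f, 274, 1000), "to_axon_um")

  # inversion consistency: the published two-factor weights put 75%
  # performance at 2393.66 um for a 274 uA amplitude
  t6 <- as_tpd_logit(tpd_coefficients("two_factor"))
  expect_equal(predict_p2(t6, 274, 2393.66), 0.75, tolerance = 1e-4)
  d75 <- iso_distance(t6, 274, 0.75)
  expect_equal(round(d75), 2394)
  expect_equal(round(iso_distance(t6, 210, 0.75)), 2161)

  # zero-distance root: target probability attained at distance 0
  p0 <- 1 / (1 + exp(0.0599 + 0.003014 * 300))
  expect_equal(iso_distance(t6, 300, p_target = p0), 0, tolerance = 1e-9)

  # round-trip property across random converged models
  set.seed(42)
  for (i in 1:25) {
    cf <- c(intercept = rnorm(1), mean_amplitude_uA = -abs(rnorm(1, 0.003, 0.001)),
            physical_um = abs(rnorm(1, 8e-4, 3e-4)))
    m <- as_tpd_logit(cf)
    a <- runif(1, 100, 700); p <- runif(1, 0.05, 0.95)
    d <- iso_distance(m, a, p)
    expect_equal(predict_p2(m, a, d), p, tolerance = 1e-9)
  }

  # with the published signs, probability falls with amplitude and rises
  # with distance
  amps <- seq(177, 660, by = 10)
  expect_true(all(diff(predict_p2(t6, amps, 2000)) < 0))
  dists <- seq(575, 5750, by = 25)
  expect_true(all(diff(predict_p2(t6, 300, dists)) > 0))

  degen <- as_tpd_logit(c(intercept = 0, mean_amplitude_uA = -0.003,
                          physical_um = 0))
  expect_error(iso_distance(degen, 274), "zero distance coefficient")
})

test_that("fixed-weight augmentation freezes the base and fits the new factor", {
  truth <- c(tpd_coefficients("two_factor"), to_axon_um = 3e-4)
  tr <- make_trials(truth, 6000, seed = 88)
  base <- as_tpd_logit(tpd_coefficients("two_factor"))

  aug <- fixed_weight_augment(base, tr)
  # frozen coefficients carried to machine precision
  expect_identical(unname(coef(aug)[c("mean_amplitude_uA", "physical_um")]),
                   unname(coef(base)[c("mean_amplitude_uA", "physical_um")]))
  expect_setequal(aug$frozen, c("mean_amplitude_uA", "physical_um"))
  # known axon coefficient recovered within 3 SE
  expect_lt(abs(coef(aug)["to_axon_um"] - 3e-4), 3 * aug$se["to_axon_um"])

  # strict mode freezes the intercept as well
  strict <- fixed_weight_augment(base, tr, refit_intercept = FALSE)
  expect_identical(unname(coef(strict)["intercept"]),
                   unname(coef(base)["intercept"]))

  # constant new factor: base model reproduced, flagged unidentifiable
  tr0 <- tr
  tr0$to_axon_um <- 0
  expect_warning(flat <- fixed_weight_augment(base, tr0), "unidentifiable")
  expect_true(isTRUE(attr(flat, "unidentifiable")))
  expect_equal(coef(flat)[names(coef(base))], coef(base))
})

test_that("Wald intervals from the information matrix have nominal coverage", {
  truth <- tpd_coefficients("two_factor")
  set.seed(1234)
  seeds <- sample.int(1e6, 500)
  hits <- matrix(FALSE, length(seeds), 3)
  for (i in seq_along(seeds)) {
    tr <- make_trials(truth, 1000, seed = seeds[i])
    f <- fit_logistic(tr)
    lo <- coef(f) - 1.96 * f$se[names(coef(f))]
    hi <- coef(f) + 1.96 * f$se[names(coef(f))]
    hits[i, ] <- truth >= lo & truth <= hi
  }
  cov <- colMeans(hits)
  expect_true(all(cov >= 0.93 & cov <= 0.97))
})

test_that("Wilson intervals bracket the proportion and hit known values", {
  expect_equal(round(wilson_interval(11, 15, 0.95), 2),
               c(lower = 0.48, upper = 0.89))
  expect_equal(unname(wilson_interval(0, 12)[1]), 0)
  expect_equal(unname(wilson_interval(12, 12)[2]), 1)
  for (k in c(0, 3, 9, 15)) {
    ci <- wilson_interval(k, 15)
    expect_true(ci[1] <= k / 15 && k / 15 <= ci[2])
  }
  expect_error(wilson_interval(5, 0))
  expect_error(wilson_interval(-1, 10))
})

test_that("psychometric threshold fitting recovers and flags degeneracies", {
  cfg <- generator_config(seed = 9)
  stair <- gen_yesno_staircase(cfg, true_threshold_uA = 274, slope = 0.03,
                               n_trials = 300)
  fit <- fit_psychometric_threshold(stair$amplitude_uA, stair$detected)
  expect_equal(fit$flag, "ok")
  expect_lt(abs(fit$threshold_uA - 274) / 274, 0.10)

  # step data: threshold within the response gap, separation flagged
  amp <- c(seq(100, 190, by = 10), seq(210, 300, by = 10))
  det <- amp > 200
  sf <- fit_psychometric_threshold(amp, det)
  expect_false(sf$converged)
  expect_equal(sf$flag, "separation")
  expect_true(sf$threshold_uA > 190 && sf$threshold_uA < 210)

  # constant responses: no threshold
  cf <- fit_psychometric_threshold(c(100, 200, 300), c(TRUE, TRUE, TRUE))
  expect_true(is.na(cf$threshold_uA))
  expect_equal(cf$flag, "constant_response")

  # 50% yes at every amplitude: flat, no usable threshold
  ff <- fit_psychometric_threshold(rep(c(100, 300), each = 40),
                                   rep(c(TRUE, FALSE), 40))
  expect_true(ff$flag %in% c("flat", "separation") || is.na(ff$threshold_uA) ||
                abs(ff$slope) < 1e-3)
})

test_that("micron-degree conversion uses the retinal scale factor", {
  expect_equal(um_to_deg(288), 1)
  expect_equal(um_to_deg(0), 0)
  expect_equal(round(um_to_deg(2393.66), 2), 8.31)
  expect_equal(deg_to_um(um_to_deg(1234.5)), 1234.5)
  expect_error(um_to_deg(100, um_per_degree = 0))
})
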