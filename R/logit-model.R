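#' Published coefficient sets for the two-point discrimination model
#'
#' Returns the coefficient vectors of the logistic model
#' `P("2"|2) = logistic(b0 + b_amp * MeanAmplitude + b_dist * PhysicalDistance
#' [+ b_axon * DistanceToAxon])` as reported for the two- and three-factor
#' fits. `"two_factor"` carries the two-factor weights at full printed precision
#' (amplitude -0.003014); `"two_factor_rounded"` is the same model with the amplitude weight
#' rounded to -0.00314 as printed in the equation form; `"two_factor"` is the
#' default because it reproduces the published 75% iso-performance thresholds.
#' `"three_factor"` is the freely-fit three-factor model.
#'
#' @param source one of `"two_factor"`, `"two_factor_rounded"`, `"three_factor"`.
#' @return Named numeric vector with elements `intercept`,
#'   `mean_amplitude_uA`, `physical_um` and (for `"three_factor"`) `to_axon_um`.
#' @export
tpd_coefficients <- function(source = c("two_factor", "two_factor_rounded", "three_factor")) {
  source <- match.arg(source)
  switch(source,
    two_factor = c(intercept = -0.0599, mean_amplitude_uA = -0.003014,
               physical_um = 0.000829),
    two_factor_rounded = c(intercept = -0.0599, mean_amplitude_uA = -0.00314,
            physical_um = 0.000829),
    three_factor = c(intercept = -0.1839, mean_amplitude_uA = -0.0030,
            physical_um = 0.000602, to_axon_um = 0.000502581))
}

logistic <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

# Iteratively reweighted least squares for a Bernoulli logit model with an
# offset. Returns free-coefficient estimates, their covariance, the
# log-likelihood and a convergence flag; separation is detected as a
# diverging coefficient norm (|beta_j| * sd(x_j) beyond any plausible logit
# scale).
irls_logit <- function(X, y, offset = 0, tol = 1e-10, maxit = 100) {
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("singular design: collinear factor(s) ", paste(bad, collapse = ", "))
  }
  beta <- rep(0, p)
  ll_old <- -Inf
  converged <- FALSE
  scale <- pmax(apply(X, 2, stats::sd), 1)
  if (!is.null(colnames(X)) && "intercept" %in% colnames(X)) {
    scale[colnames(X) == "intercept"] <- 1
  }
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- logistic(eta)
    ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
    if (is.finite(ll) && abs(ll - ll_old) < tol && it > 1) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- (eta - offset) + (y - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
    if (any(abs(beta) * scale > 50)) {  # separation: diverging coefficients
      converged <- FALSE
      break
    }
  }
  eta <- drop(X %*% beta) + offset
  mu <- logistic(eta)
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(beta = stats::setNames(beta, colnames(X)), vcov = vc,
       log_likelihood = ll, converged = converged, fitted = mu,
       iterations = it)
}

#' Fit the logistic two-point discrimination model
#'
#' Maximum-likelihood logistic regression of the binary outcome "two or more
#' percepts reported" on trial-level factors, with optional frozen
#' coefficients that are carried at supplied values (entering the linear
#' predictor as an offset) while the remaining coefficients are fit. Fitting
#' uses iteratively reweighted least squares (convergence when the
#' log-likelihood improves by less than 1e-10, at most 100 iterations);
#' complete separation is flagged as non-convergence.
#'
#' @param trials data.frame of analysis trials (see [preprocess_trials()]).
#' @param factors character vector of regressor column names (use
#'   `character(0)` for an intercept-only model).
#' @param frozen optional named numeric vector of coefficients to hold fixed
#'   (may include `"intercept"`).
#' @param outcome name of the 0/1 outcome column.
#' @return Object of class `"tpd_logit"`: coefficients (fit and frozen),
#'   `frozen` names, `log_likelihood`, `n_obs`, `convergence`, `vcov` and
#'   standard errors for the free coefficients.
#' @seealso [predict_p2()], [iso_distance()], [lr_test()],
#'   [fixed_weight_augment()]
#' @export
fit_logistic <- function(trials, factors = c("mean_amplitude_uA", "physical_um"),
                         frozen = NULL, outcome = "outcome") {
  stopifnot(is.data.frame(trials), outcome %in% names(trials))
  miss <- setdiff(factors, names(trials))
  if (length(miss)) stop("missing factor column(s): ", paste(miss, collapse = ", "))
  y <- trials[[outcome]]
  # fractional outcomes in [0, 1] are accepted as expected response
  # frequencies (population-level fits)
  if (any(!is.finite(y)) || any(y < 0 | y > 1)) {
    stop("outcome must lie in [0, 1]")
  }
  terms <- c("intercept", factors)
  frozen_names <- intersect(names(frozen), terms)
  free_names <- setdiff(terms, frozen_names)
  if (length(free_names) > 0 && length(unique(y)) < 2) {
    stop("need at least one trial per outcome class to fit free coefficients")
  }
  mm <- cbind(intercept = rep(1, nrow(trials)))
  for (f in factors) mm <- cbind(mm, trials[[f]])
  colnames(mm) <- terms
  offset <- if (length(frozen_names)) {
    drop(mm[, frozen_names, drop = FALSE] %*% frozen[frozen_names])
  } else rep(0, nrow(mm))

  if (length(free_names) == 0) {
    mu <- logistic(offset)
    ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
    fit <- list(beta = numeric(0), vcov = matrix(numeric(0), 0, 0),
                log_likelihood = ll, converged = TRUE, iterations = 0L)
  } else {
    fit <- irls_logit(mm[, free_names, drop = FALSE], y, offset)
  }
  coefs <- stats::setNames(rep(NA_real_, length(terms)), terms)
  coefs[frozen_names] <- frozen[frozen_names]
  coefs[free_names] <- fit$beta
  structure(list(
    coefficients = coefs,
    frozen = frozen_names,
    log_likelihood = fit$log_likelihood,
    n_obs = length(y),
    convergence = fit$converged,
    vcov = fit$vcov,
    se = if (length(free_names)) sqrt(diag(fit$vcov)) else numeric(0),
    n_free = length(free_names),
    iterations = fit$iterations,
    y = y,
    factors = factors
  ), class = "tpd_logit")
}

#' Build a model object from supplied coefficients
#'
#' Wraps published or externally chosen coefficients (e.g.
#' [tpd_coefficients()]) in a `"tpd_logit"` object so that prediction and
#' inversion methods apply. All coefficients are marked frozen.
#'
#' @param coefficients named numeric vector including `intercept`.
#' @return A `"tpd_logit"` object.
#' @examples
#' m <- as_tpd_logit(tpd_coefficients("two_factor"))
#' iso_distance(m, amplitude_uA = 274, p_target = 0.75)
#' @export
as_tpd_logit <- function(coefficients) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            "intercept" %in% names(coefficients))
  structure(list(
    coefficients = coefficients,
    frozen = names(coefficients),
    log_likelihood = NA_real_,
    n_obs = 0L,
    convergence = TRUE,
    vcov = NULL, se = numeric(0), n_free = 0L, iterations = 0L,
    y = NULL,
    factors = setdiff(names(coefficients), "intercept")
  ), class = "tpd_logit")
}

#' @export
print.tpd_logit <- function(x, ...) {
  cat("Two-point discrimination logistic model\n")
  cat("  coefficients:\n")
  for (nm in names(x$coefficients)) {
    tag <- if (nm %in% x$frozen) " (frozen)" else ""
    cat(sprintf("    %-18s % .6g%s\n", nm, x$coefficients[nm], tag))
  }
  if (is.finite(x$log_likelihood)) {
    cat(sprintf("  logLik %.3f on %d trials; converged: %s\n",
                x$log_likelihood, x$n_obs, x$convergence))
  }
  invisible(x)
}

#' @export
coef.tpd_logit <- function(object, ...) object$coefficients

#' @export
logLik.tpd_logit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_free, class = "logLik")
}

#' @export
vcov.tpd_logit <- function(object, ...) object$vcov

#' @export
summary.tpd_logit <- function(object, ...) {
  free <- setdiff(names(object$coefficients), object$frozen)
  est <- object$coefficients[free]
  se <- object$se[free]
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, frozen = object$coefficients[object$frozen],
              log_likelihood = object$log_likelihood, n_obs = object$n_obs,
              convergence = object$convergence)
  class(out) <- "summary.tpd_logit"
  out
}

#' @export
print.summary.tpd_logit <- function(x, ...) {
  cat("Two-point discrimination logistic model\n\nFree coefficients:\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  if (length(x$frozen)) {
    cat("\nFrozen coefficients:\n")
    print(x$frozen)
  }
  cat(sprintf("\nlogLik %.3f on %d trials; converged: %s\n",
              x$log_likelihood, x$n_obs, x$convergence))
  invisible(x)
}

#' @export
predict.tpd_logit <- function(object, newdata, type = "response", ...) {
  cf <- object$coefficients
  eta <- rep(cf[["intercept"]], nrow(newdata))
  for (nm in setdiff(names(cf), "intercept")) {
    if (!nm %in% names(newdata)) stop("missing factor value: ", nm)
    eta <- eta + cf[[nm]] * newdata[[nm]]
  }
  if (type == "link") eta else logistic(eta)
}

#' @export
simulate.tpd_logit <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, newdata)
  as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
}

#' Predicted probability of reporting two percepts
#'
#' Evaluates `P("2"|2)` from a fitted or supplied logistic model at the given
#' mean detection-threshold amplitude and inter-electrode distances.
#'
#' @param model a `"tpd_logit"` object (must have converged, or carry
#'   supplied coefficients).
#' @param amplitude_uA mean detection-threshold amplitude of the pair (uA).
#' @param distance_um physical center-to-center distance (um).
#' @param to_axon_um distance to axon (um); required when the model carries a
#'   to-axon coefficient.
#' @return Probability in (0, 1); vectorized over the inputs.
#' @examples
#' m <- as_tpd_logit(tpd_coefficients("three_factor"))
#' predict_p2(m, 274, 1000, to_axon_um = 0)  # about 0.400
#' @export
predict_p2 <- function(model, amplitude_uA, distance_um, to_axon_um = NULL) {
  stopifnot(inherits(model, "tpd_logit"))
  if (!model$convergence) stop("model did not converge; coefficients unreliable")
  cf <- model$coefficients
  eta <- cf[["intercept"]] +
    cf[["mean_amplitude_uA"]] * amplitude_uA +
    cf[["physical_um"]] * distance_um
  if ("to_axon_um" %in% names(cf)) {
    if (is.null(to_axon_um)) stop("missing factor value: to_axon_um")
    eta <- eta + cf[["to_axon_um"]] * to_axon_um
  }
  unname(logistic(eta))
}

#' Invert the model into an iso-performance distance
#'
#' Closed-form inversion of the logistic model: the inter-electrode physical
#' distance at which the model predicts probability `p_target` of reporting
#' two percepts at the given amplitude,
#' `distance = (logit(p) - b0 - b_amp * A - b_axon * x) / b_dist`.
#' With `axon_equals_distance = TRUE` the to-axon regressor is tied to the
#' physical distance (minimal axonal stimulation), so the inversion divides by
#' `b_dist + b_axon` instead.
#'
#' @param model a `"tpd_logit"` object.
#' @param amplitude_uA amplitude at which to invert (uA).
#' @param p_target target probability (default 0.75).
#' @param to_axon_um fixed to-axon distance for three-factor models (um).
#' @param axon_equals_distance set the to-axon regressor equal to the
#'   physical distance.
#' @return Distance in um (vectorized over `amplitude_uA`).
#' @examples
#' m <- as_tpd_logit(tpd_coefficients("two_factor"))
#' iso_distance(m, 274)  # about 2394 um
#' @export
iso_distance <- function(model, amplitude_uA, p_target = 0.75,
                         to_axon_um = 0, axon_equals_distance = FALSE) {
  stopifnot(inherits(model, "tpd_logit"))
  cf <- model$coefficients
  bx <- if ("to_axon_um" %in% names(cf)) cf[["to_axon_um"]] else 0
  num <- logit(p_target) - cf[["intercept"]] - cf[["mean_amplitude_uA"]] * amplitude_uA
  if (axon_equals_distance) {
    den <- cf[["physical_um"]] + bx
  } else {
    num <- num - bx * to_axon_um
    den <- cf[["physical_um"]]
  }
  if (abs(den) < .Machine$double.eps) stop("zero distance coefficient: cannot invert")
  unname(num / den)
}

#' Likelihood-ratio test between nested logistic models
#'
#' @param nested,full `"tpd_logit"` models fit to the same trials; the nested
#'   model's free factors must be a subset of the full model's.
#' @return List with `chi2 = 2 * (LL_full - LL_nested)`, `df` (difference in
#'   free coefficients) and the chi-squared `p` value.
#' @export
lr_test <- function(nested, full) {
  stopifnot(inherits(nested, "tpd_logit"), inherits(full, "tpd_logit"))
  if (nested$n_obs != full$n_obs ||
      (!is.null(nested$y) && !is.null(full$y) && !identical(nested$y, full$y))) {
    stop("models were fit to different trials")
  }
  if (!all(nested$factors %in% full$factors)) {
    stop("'nested' factors must be a subset of 'full' factors")
  }
  chi2 <- 2 * (full$log_likelihood - nested$log_likelihood)
  df <- full$n_free - nested$n_free
  p <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else
    as.numeric(chi2 <= 0)
  list(chi2 = chi2, df = df, p = p)
}

#' @export
anova.tpd_logit <- function(object, ...) {
  others <- list(...)
  others <- others[vapply(others, inherits, logical(1), "tpd_logit")]
  if (!length(others)) stop("supply a second tpd_logit model to compare")
  full <- others[[1]]
  lt <- lr_test(object, full)
  tab <- data.frame(
    model = c("nested", "full"),
    n_free = c(object$n_free, full$n_free),
    logLik = c(object$log_likelihood, full$log_likelihood),
    chi2 = c(NA, lt$chi2), df = c(NA, lt$df), p = c(NA, lt$p))
  class(tab) <- c("anova", "data.frame")
  tab
}

#' Fixed-weight augmentation with an additional factor
#'
#' Freezes the fitted (or supplied) weights of a base model -- its amplitude
#' and distance coefficients -- and fits only the new factor's coefficient by
#' maximum likelihood (plus, by default, a refit intercept). This isolates
#' the additional factor's effect without letting it redistribute weight
#' across the correlated base factors.
#'
#' @param base a converged `"tpd_logit"` model.
#' @param trials analysis trials containing the base factors and the new
#'   factor.
#' @param new_factor column name of the added factor (default
#'   `"to_axon_um"`).
#' @param refit_intercept refit the intercept together with the new factor
#'   (default); `FALSE` freezes the intercept at the base value as well.
#' @return A `"tpd_logit"` with the base coefficients frozen. If the new
#'   factor is constant its coefficient is unidentifiable: the base model is
#'   reproduced and the result carries attribute `unidentifiable = TRUE`.
#' @export
fixed_weight_augment <- function(base, trials, new_factor = "to_axon_um",
                                 refit_intercept = TRUE) {
  stopifnot(inherits(base, "tpd_logit"))
  if (!base$convergence) stop("base model did not converge")
  if (!new_factor %in% names(trials)) stop("missing factor column: ", new_factor)
  base_terms <- setdiff(names(base$coefficients), "intercept")
  frozen <- base$coefficients[base_terms]
  if (stats::sd(trials[[new_factor]]) == 0) {
    out <- base
    out$coefficients <- c(base$coefficients,
                          stats::setNames(0, new_factor))
    out$factors <- c(base$factors, new_factor)
    out$frozen <- names(out$coefficients)
    attr(out, "unidentifiable") <- TRUE
    warning("new factor is constant; coefficient unidentifiable, base model reproduced")
    return(out)
  }
  if (!refit_intercept) {
    frozen <- c(stats::setNames(base$coefficients["intercept"], "intercept"), frozen)
  }
  fit_logistic(trials, factors = c(base_terms, new_factor), frozen = frozen)
}

#' Iso-performance contour of a logistic model
#'
#' Samples the locus of (amplitude, distance) combinations at which the model
#' predicts probability `p_target` of reporting two percepts.
#'
#' @param model a `"tpd_logit"`.
#' @param amplitudes_uA amplitudes at which to evaluate (uA).
#' @param p_target target probability.
#' @param axon one of `"absent"` (two-factor model), `"zero"` (to-axon fixed
#'   at 0) or `"equal_physical"` (to-axon tied to the physical distance:
#'   minimal axonal stimulation).
#' @return Object of classes `"iso_contour"` and `"data.frame"` with columns
#'   `amplitude_uA`, `distance_um`; attribute `p_target`.
#' @export
iso_performance_contour <- function(model, amplitudes_uA = seq(177, 660, by = 1),
                                    p_target = 0.75,
                                    axon = c("absent", "zero", "equal_physical")) {
  axon <- match.arg(axon)
  d <- switch(axon,
    absent = iso_distance(model, amplitudes_uA, p_target),
    zero = iso_distance(model, amplitudes_uA, p_target, to_axon_um = 0),
    equal_physical = iso_distance(model, amplitudes_uA, p_target,
                                  axon_equals_distance = TRUE))
  out <- data.frame(amplitude_uA = amplitudes_uA, distance_um = d)
  attr(out, "p_target") <- p_target
  class(out) <- c("iso_contour", "data.frame")
  out
}
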