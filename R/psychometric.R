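#' Fit a psychometric detection threshold from yes/no data
#'
#' Pools yes/no detection responses across amplitudes and fits a
#' two-parameter sigmoid (logistic in amplitude) by maximum likelihood. The
#' detection threshold is the amplitude at which the fitted function predicts
#' a percept report on 50% of trials.
#'
#' @param amplitude_uA stimulus amplitudes (uA).
#' @param detected logical or 0/1 vector of percept reports.
#' @return Object of class `"psychometric_fit"`: `threshold_uA` (NA when no
#'   threshold is defined), `slope` (per uA), `coefficients`, `converged`,
#'   and `flag` (`"ok"`, `"separation"`, `"constant_response"`,
#'   `"flat"`).
#' @export
fit_psychometric_threshold <- function(amplitude_uA, detected) {
  stopifnot(length(amplitude_uA) == length(detected))
  y <- as.integer(detected)
  if (length(unique(y)) < 2) {
    return(structure(list(threshold_uA = NA_real_, slope = NA_real_,
                          coefficients = c(intercept = NA_real_, slope = NA_real_),
                          converged = FALSE, flag = "constant_response",
                          n_obs = length(y)),
                     class = "psychometric_fit"))
  }
  X <- cbind(intercept = 1, amplitude = amplitude_uA)
  fit <- irls_logit(X, y)
  b0 <- fit$beta[["intercept"]]; b1 <- fit$beta[["amplitude"]]
  flag <- if (!fit$converged) "separation" else "ok"
  thr <- if (abs(b1) < 1e-8) NA_real_ else -b0 / b1
  if (is.na(thr) || b1 <= 0) {
    flag <- if (flag == "ok") "flat" else flag
    if (is.na(thr)) thr <- NA_real_
  }
  structure(list(threshold_uA = unname(thr), slope = unname(b1),
                 coefficients = fit$beta, converged = fit$converged,
                 flag = flag, n_obs = length(y)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Psychometric detection fit (yes/no)\n")
  if (is.na(x$threshold_uA)) {
    cat("  no 50% threshold defined; flag:", x$flag, "\n")
  } else {
    cat(sprintf("  50%% threshold: %.1f uA (slope %.4g /uA, flag: %s)\n",
                x$threshold_uA, x$slope, x$flag))
  }
  invisible(x)
}
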