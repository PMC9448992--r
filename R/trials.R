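#' Preprocess two-point discrimination trials
#'
#' Applies the analysis rules for verbal percept-count reports: catch trials
#' are removed, trials where no percept was reported (count 0) are discarded,
#' counts above 3 are first binned to 3, and reports of 2 or more percepts are
#' collapsed into the binary outcome "two percepts seen".
#'
#' @param trials data.frame with at least `reported_count`; `is_catch` is
#'   honored if present. Other columns (pair identifiers, amplitudes,
#'   distances) are carried through.
#' @return A data.frame of retained trials with an added integer `outcome`
#'   column (1 if two or more percepts were reported), carrying a `"log"`
#'   attribute with the counts of removed catch trials, discarded
#'   zero-response trials and collapsed 3+ reports.
#' @examples
#' tr <- data.frame(reported_count = c(0, 1, 2, 3, 1),
#'                  is_catch = c(FALSE, FALSE, FALSE, FALSE, TRUE))
#' out <- preprocess_trials(tr)
#' attr(out, "log")
#' @export
preprocess_trials <- function(trials) {
  stopifnot(is.data.frame(trials), "reported_count" %in% names(trials))
  n0 <- nrow(trials)
  catch <- if ("is_catch" %in% names(trials)) as.logical(trials$is_catch) else
    rep(FALSE, n0)
  catch[is.na(catch)] <- FALSE
  x <- trials[!catch, , drop = FALSE]
  n_catch <- n0 - nrow(x)
  cnt <- pmin(x$reported_count, 3L)  # 3+ binned as 3
  keep <- cnt > 0
  n_zero <- sum(!keep)
  x <- x[keep, , drop = FALSE]
  cnt <- cnt[keep]
  x$outcome <- as.integer(cnt >= 2)
  n_collapsed <- sum(cnt == 3)
  attr(x, "log") <- c(n_input = n0, n_catch_removed = n_catch,
                      n_zero_discarded = n_zero, n_collapsed_3plus = n_collapsed,
                      n_retained = nrow(x))
  rownames(x) <- NULL
  x
}

#' Per-category response probabilities
#'
#' @param counts numeric vector of response frequencies per reported-percept
#'   category (0, 1, 2, 3).
#' @return Probabilities `counts / sum(counts)`, named after the categories.
#' @examples
#' response_probabilities(c(2, 29, 20, 3))
#' @export
response_probabilities <- function(counts) {
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("'counts' must be non-negative with a positive total")
  }
  p <- counts / sum(counts)
  if (is.null(names(p))) names(p) <- as.character(seq_along(p) - 1)
  p
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes number of successes.
#' @param n number of trials.
#' @param confidence confidence level (default 0.95).
#' @return `c(lower, upper)`; always contains `successes / n`.
#' @examples
#' wilson_interval(11, 15)  # about (0.48, 0.89)
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  if (n <= 0 || successes < 0 || successes > n) {
    stop("need 0 <= successes <= n with n > 0")
  }
  if (confidence <= 0 || confidence >= 1) stop("'confidence' must be in (0,1)")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  lo <- if (successes == 0) 0 else max(0, ctr - hw)
  hi <- if (successes == n) 1 else min(1, ctr + hw)
  c(lower = lo, upper = hi)
}
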