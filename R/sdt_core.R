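# Signal detection kernel shared by all observer models: class-conditional
# densities, log likelihood ratios, criteria, sensitivity, confidence binning.

#' Signal detection parameters for one task
#'
#' Defines the generative evidence model for a single task. For detection the
#' two stimulus classes are noise, \eqn{N(\mu_n, \sigma_n)}, and signal,
#' \eqn{N(\mu_s, \sigma_s)} with \eqn{\sigma_s \ge \sigma_n} (unequal-variance
#' SDT: evidence for presence widens the signal distribution). For
#' discrimination the two classes are anticlockwise and clockwise gratings at
#' \eqn{\mp \mu_s} with a shared standard deviation \eqn{\sigma_n}
#' (equal-variance SDT).
#'
#' The decision criterion defaults to the balanced criterion: the evidence
#' value at which the overall probability of an above-criterion response is
#' 0.5 under equal class base rates, matching the near-unbiased responding the
#' task design aims for. Pass `criterion` explicitly to model biased observers.
#'
#' @param task `"detection"` or `"discrimination"`.
#' @param mu_signal Mean of the signal distribution (detection) or
#'   half-separation of the two classes (discrimination), in evidence units.
#' @param sigma_signal Standard deviation of the signal distribution. Ignored
#'   for discrimination (forced equal to `sigma_noise`). Must be
#'   `>= sigma_noise` for detection.
#' @param mu_noise,sigma_noise Mean and standard deviation of the noise
#'   distribution (detection); for discrimination `sigma_noise` is the shared
#'   class standard deviation and `mu_noise` is ignored.
#' @param criterion Decision criterion on the evidence axis, or `NULL` for the
#'   balanced criterion.
#' @return An object of class `"sdt_params"`: a list with elements `task`,
#'   `mu1`, `sigma1` (lower class: noise / anticlockwise), `mu2`, `sigma2`
#'   (upper class: signal / clockwise) and `criterion`.
#' @examples
#' sdt_params("detection", mu_signal = 1.5, sigma_signal = 1.5)
#' sdt_params("discrimination", mu_signal = 0.75)
#' @export
sdt_params <- function(task = c("detection", "discrimination"),
                       mu_signal = 1.5,
                       sigma_signal = 1.5,
                       mu_noise = 0,
                       sigma_noise = 1,
                       criterion = NULL) {
  task <- match.arg(task)
  stopifnot(is.finite(mu_signal), is.finite(mu_noise),
            sigma_noise > 0, sigma_signal > 0)
  if (task == "detection") {
    if (sigma_signal < sigma_noise)
      stop("detection requires sigma_signal >= sigma_noise (unequal-variance SDT)")
    p <- list(task = task,
              mu1 = mu_noise, sigma1 = sigma_noise,
              mu2 = mu_signal, sigma2 = sigma_signal)
  } else {
    p <- list(task = task,
              mu1 = -mu_signal, sigma1 = sigma_noise,
              mu2 = +mu_signal, sigma2 = sigma_noise)
  }
  class(p) <- "sdt_params"
  p$criterion <- if (is.null(criterion)) balanced_criterion(p) else criterion
  stopifnot(is.finite(p$criterion))
  p
}

#' @export
print.sdt_params <- function(x, ...) {
  cat(sprintf("SDT parameters [%s]\n", x$task))
  cat(sprintf("  class 1 (%s): N(%.3f, %.3f)\n",
              if (x$task == "detection") "noise" else "anticlockwise",
              x$mu1, x$sigma1))
  cat(sprintf("  class 2 (%s): N(%.3f, %.3f)\n",
              if (x$task == "detection") "signal" else "clockwise",
              x$mu2, x$sigma2))
  cat(sprintf("  criterion: %.4f\n", x$criterion))
  invisible(x)
}

#' Class labels for a task
#' @param task `"detection"` or `"discrimination"`.
#' @return Character vector of the two class labels, lower class first.
#' @export
task_classes <- function(task) {
  switch(task,
         detection = c("absent", "present"),
         discrimination = c("anticlockwise", "clockwise"),
         stop("unknown task: ", task))
}

#' Response labels for a task
#' @inheritParams task_classes
#' @return Character vector of the two response labels, below-criterion first.
#' @export
task_responses <- function(task) {
  switch(task,
         detection = c("no", "yes"),
         discrimination = c("anticlockwise", "clockwise"),
         stop("unknown task: ", task))
}

# Criterion at which P(above-criterion response) = 0.5 under equal base rates.
balanced_criterion <- function(p) {
  f <- function(c) {
    0.5 * stats::pnorm(c, p$mu1, p$sigma1, lower.tail = FALSE) +
      0.5 * stats::pnorm(c, p$mu2, p$sigma2, lower.tail = FALSE) - 0.5
  }
  lo <- min(p$mu1, p$mu2) - 10 * max(p$sigma1, p$sigma2)
  hi <- max(p$mu1, p$mu2) + 10 * max(p$sigma1, p$sigma2)
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Log likelihood ratio of the two stimulus classes
#'
#' Computes \eqn{\log p(x | \text{class 2}) / p(x | \text{class 1})} at
#' evidence values `x`: signal over noise for detection, clockwise over
#' anticlockwise for discrimination. The mapping is affine in `x` for
#' equal class variances and quadratic (opening upwards when
#' \eqn{\sigma_2 > \sigma_1}) for unequal variances.
#'
#' @param x Numeric vector of evidence values (finite).
#' @param params An [sdt_params()] object.
#' @return Numeric vector of log likelihood ratios.
#' @export
log_likelihood_ratio <- function(x, params) {
  stopifnot(inherits(params, "sdt_params"))
  if (!all(is.finite(x))) stop("evidence values must be finite")
  stats::dnorm(x, params$mu2, params$sigma2, log = TRUE) -
    stats::dnorm(x, params$mu1, params$sigma1, log = TRUE)
}

#' Sensitivity and criterion from hit and false-alarm rates
#'
#' Standard equal-variance summary statistics:
#' \eqn{d' = z(\mathrm{HR}) - z(\mathrm{FA})} and
#' \eqn{c = -(z(\mathrm{HR}) + z(\mathrm{FA}))/2}, with \eqn{z} the standard
#' normal quantile function. Rates of exactly 0 or 1 are rejected; apply a
#' count correction first (see [sensitivity_from_counts()]).
#'
#' @param hit_rate,fa_rate Proportions strictly inside (0, 1).
#' @return List with elements `dprime` and `criterion_c`.
#' @examples
#' sensitivity_from_rates(0.8413, 0.1587) # dprime ~ 2, c ~ 0
#' @export
sensitivity_from_rates <- function(hit_rate, fa_rate) {
  if (any(hit_rate <= 0 | hit_rate >= 1 | fa_rate <= 0 | fa_rate >= 1))
    stop("rates must lie strictly inside (0, 1); use sensitivity_from_counts() ",
         "with correction for degenerate rates")
  zh <- stats::qnorm(hit_rate)
  zf <- stats::qnorm(fa_rate)
  list(dprime = zh - zf, criterion_c = -(zh + zf) / 2)
}

#' Sensitivity from raw outcome counts with log-linear correction
#'
#' Converts hit/false-alarm counts to rates, optionally applying the
#' log-linear correction (add 0.5 to each cell, 1 to each total) that keeps
#' rates off the 0/1 boundary on small runs, then calls
#' [sensitivity_from_rates()].
#'
#' @param n_hit,n_signal Hits and signal-trial total.
#' @param n_fa,n_noise False alarms and noise-trial total.
#' @param correction Apply the log-linear correction (default `TRUE`).
#' @return As [sensitivity_from_rates()].
#' @export
sensitivity_from_counts <- function(n_hit, n_signal, n_fa, n_noise,
                                    correction = TRUE) {
  stopifnot(n_hit <= n_signal, n_fa <= n_noise, n_signal > 0, n_noise > 0)
  if (correction) {
    hr <- (n_hit + 0.5) / (n_signal + 1)
    fa <- (n_fa + 0.5) / (n_noise + 1)
  } else {
    hr <- n_hit / n_signal
    fa <- n_fa / n_noise
  }
  sensitivity_from_rates(hr, fa)
}

#' Hit and false-alarm rates implied by d-prime and criterion c
#'
#' Inverse of [sensitivity_from_rates()] under the equal-variance model;
#' useful for closed-form checks of simulated accuracies.
#'
#' @param dprime Sensitivity.
#' @param criterion_c Criterion in z units (0 = unbiased).
#' @return List with elements `hit_rate` and `fa_rate`.
#' @export
rates_from_sensitivity <- function(dprime, criterion_c = 0) {
  list(hit_rate = stats::pnorm(dprime / 2 - criterion_c),
       fa_rate = stats::pnorm(-dprime / 2 - criterion_c))
}

#' Confidence binning rule
#'
#' A six-point confidence scale realised as five strictly increasing
#' thresholds on a nonnegative magnitude (distance of the evidence sample
#' from the criterion for the static observer; |log likelihood ratio| for the
#' dynamic and attention observers). By default the thresholds are equally
#' spaced between 0 and the 99th percentile of the magnitude's distribution,
#' so that simulated observers use the full range of the scale.
#'
#' @param thresholds Strictly increasing positive numeric vector of length
#'   `n_levels - 1`.
#' @param n_levels Number of confidence levels (default 6).
#' @return Object of class `"confidence_rule"`.
#' @seealso [confidence_rule_for()], [bin_confidence()]
#' @export
confidence_rule <- function(thresholds, n_levels = 6L) {
  thresholds <- as.numeric(thresholds)
  stopifnot(length(thresholds) == n_levels - 1L,
            all(thresholds > 0), !is.unsorted(thresholds, strictly = TRUE))
  structure(list(thresholds = thresholds, n_levels = as.integer(n_levels)),
            class = "confidence_rule")
}

#' Default confidence rule for an SDT observer
#'
#' Places the five thresholds equally spaced between 0 and the `p_max`
#' quantile (default 0.99) of \eqn{|x - c|} under the generative mixture of
#' the two classes at equal base rates, computed from the mixture CDF by root
#' finding (no simulation involved).
#'
#' @param params An [sdt_params()] object.
#' @param n_levels Number of confidence levels.
#' @param p_max Quantile of the magnitude distribution mapped to the top of
#'   the scale.
#' @return A [confidence_rule()].
#' @export
confidence_rule_for <- function(params, n_levels = 6L, p_max = 0.99) {
  stopifnot(inherits(params, "sdt_params"), p_max > 0, p_max < 1)
  cc <- params$criterion
  cdf_absdist <- function(q) {
    0.5 * (stats::pnorm(cc + q, params$mu1, params$sigma1) -
             stats::pnorm(cc - q, params$mu1, params$sigma1)) +
      0.5 * (stats::pnorm(cc + q, params$mu2, params$sigma2) -
               stats::pnorm(cc - q, params$mu2, params$sigma2))
  }
  hi <- 20 * max(params$sigma1, params$sigma2) +
    abs(params$mu1 - cc) + abs(params$mu2 - cc)
  q99 <- stats::uniroot(function(q) cdf_absdist(q) - p_max,
                        c(1e-12, hi), tol = 1e-10)$root
  confidence_rule(seq(0, q99, length.out = n_levels + 1L)[2:n_levels],
                  n_levels = n_levels)
}

#' Confidence rule from realised magnitudes
#'
#' Equally spaced thresholds between 0 and the empirical `p_max` quantile of
#' a sample of magnitudes; used to bin |LLR|-based confidence in the dynamic
#' and attention observers.
#'
#' @param magnitudes Nonnegative numeric vector.
#' @inheritParams confidence_rule_for
#' @return A [confidence_rule()].
#' @export
confidence_rule_from_magnitudes <- function(magnitudes, n_levels = 6L,
                                            p_max = 0.99) {
  stopifnot(all(magnitudes >= 0), length(magnitudes) >= n_levels)
  q99 <- as.numeric(stats::quantile(magnitudes, p_max, names = FALSE))
  if (q99 <= 0) stop("magnitude distribution is degenerate at 0")
  confidence_rule(seq(0, q99, length.out = n_levels + 1L)[2:n_levels],
                  n_levels = n_levels)
}

#' Map magnitudes to confidence levels
#'
#' Deterministic, exhaustive and exclusive binning: every magnitude maps to
#' exactly one level in `1..n_levels`; magnitudes above the top threshold
#' saturate at the highest level.
#'
#' @param magnitude Nonnegative numeric vector.
#' @param rule A [confidence_rule()].
#' @return Integer vector of confidence levels.
#' @export
bin_confidence <- function(magnitude, rule) {
  stopifnot(inherits(rule, "confidence_rule"), all(magnitude >= 0))
  findInterval(magnitude, rule$thresholds) + 1L
}

#' Simulate trials from a static SDT observer
#'
#' Draws stimuli at the given prevalence, samples evidence from the stimulus
#' class density, responds by side of the criterion, and rates confidence by
#' binning the distance of the sample from the criterion.
#'
#' @param n_trials Number of trials.
#' @param params An [sdt_params()] object.
#' @param rule A [confidence_rule()]; default [confidence_rule_for()]`(params)`.
#' @param prevalence Probability of the upper class (signal / clockwise).
#' @param seed Optional integer seed.
#' @return Data frame with columns `stimulus`, `x`, `response`, `correct`,
#'   `confidence`.
#' @export
simulate_sdt_trials <- function(n_trials, params,
                                rule = confidence_rule_for(params),
                                prevalence = 0.5, seed = NULL) {
  stopifnot(inherits(params, "sdt_params"), n_trials >= 1,
            prevalence >= 0, prevalence <= 1)
  if (!is.null(seed)) set.seed(seed)
  classes <- task_classes(params$task)
  responses <- task_responses(params$task)
  is_upper <- stats::runif(n_trials) < prevalence
  x <- ifelse(is_upper,
              stats::rnorm(n_trials, params$mu2, params$sigma2),
              stats::rnorm(n_trials, params$mu1, params$sigma1))
  resp_upper <- x > params$criterion
  data.frame(
    stimulus = classes[is_upper + 1L],
    x = x,
    response = responses[resp_upper + 1L],
    correct = is_upper == resp_upper,
    confidence = bin_confidence(abs(x - params$criterion), rule),
    stringsAsFactors = FALSE
  )
}

#' Simulate a single trial for a given stimulus
#'
#' Single-trial version of [simulate_sdt_trials()] with the stimulus class
#' fixed by the caller (used by the session generator, where stimulus order
#' is balanced by design rather than Bernoulli).
#'
#' @param stimulus One of the task's class labels (see [task_classes()]).
#' @inheritParams simulate_sdt_trials
#' @return List with elements `response`, `confidence`, `x`, `correct`.
#' @export
sdt_trial <- function(stimulus, params, rule = confidence_rule_for(params),
                      seed = NULL) {
  stopifnot(inherits(params, "sdt_params"))
  classes <- task_classes(params$task)
  if (!stimulus %in% classes)
    stop("stimulus must be one of: ", paste(classes, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  upper <- stimulus == classes[2L]
  x <- if (upper) stats::rnorm(1, params$mu2, params$sigma2)
       else stats::rnorm(1, params$mu1, params$sigma1)
  resp_upper <- x > params$criterion
  list(response = task_responses(params$task)[resp_upper + 1L],
       confidence = bin_confidence(abs(x - params$criterion), rule),
       x = x,
       correct = upper == resp_upper)
}
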