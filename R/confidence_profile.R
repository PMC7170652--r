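# Two-step confidence-profile analysis: per-subject polynomial fits of
# six-level confidence profiles per response, OLS group-level inference on
# the coefficients, the standard contrast battery, and JZS Bayes factors.

#' Fit a second-order polynomial to one confidence profile
#'
#' Ordinary least squares of a six-level signal profile on an intercept,
#' linear and quadratic confidence predictors. Confidence codes are centred
#' (`confidence - 3.5`) by default, which decorrelates the linear and
#' quadratic terms on the full scale; set `centered = FALSE` for raw codes.
#' Masked levels (`NA` values: confidence levels the subject never used) are
#' dropped; at least three available levels are required for the
#' three-parameter fit, otherwise the profile is skipped with a warning and
#' `NA` coefficients (so group counts can still see it).
#'
#' @param values Numeric vector over confidence levels `1..length(values)`
#'   (signal units; `NA` = masked level).
#' @param confidence Confidence levels the values belong to (default
#'   `seq_along(values)`).
#' @param centered Centre the confidence codes (default `TRUE`).
#' @param weights Optional nonnegative per-level weights (e.g. trial
#'   counts); default unweighted.
#' @return List with elements `intercept`, `linear`, `quadratic`, `n_levels`
#'   (levels used) and `ok`.
#' @examples
#' fit_confidence_polynomial((1:6 - 3.5)^2) # pure quadratic: (0, 0, 1)
#' @export
fit_confidence_polynomial <- function(values, confidence = seq_along(values),
                                      centered = TRUE, weights = NULL) {
  stopifnot(length(values) == length(confidence))
  ok <- is.finite(values)
  if (sum(ok) < 3) {
    warning("fewer than 3 available confidence levels; profile skipped")
    return(list(intercept = NA_real_, linear = NA_real_,
                quadratic = NA_real_, n_levels = sum(ok), ok = FALSE))
  }
  code <- confidence[ok] - if (centered) 3.5 else 0
  X <- cbind(1, code, code^2)
  y <- values[ok]
  if (is.null(weights)) {
    cf <- stats::lm.fit(X, y)$coefficients
  } else {
    w <- weights[ok]
    stopifnot(all(w >= 0))
    cf <- stats::lm.wfit(X, y, w)$coefficients
  }
  list(intercept = unname(cf[1]), linear = unname(cf[2]),
       quadratic = unname(cf[3]), n_levels = sum(ok), ok = TRUE)
}

#' Per-subject polynomial coefficients for a profile table
#'
#' Applies [fit_confidence_polynomial()] to every (subject, task, response)
#' profile in a long table and returns the coefficient table that feeds
#' group inference.
#'
#' @param profiles Data frame with columns `subject`, `task`, `response`,
#'   `confidence`, `value`.
#' @param ... Passed to [fit_confidence_polynomial()].
#' @return Data frame with columns `subject`, `task`, `response`,
#'   `intercept`, `linear`, `quadratic`, `n_levels`.
#' @export
fit_profile_table <- function(profiles, ...) {
  stopifnot(all(c("subject", "task", "response", "confidence", "value")
                %in% names(profiles)))
  pieces <- split(profiles,
                  list(profiles$subject, profiles$task, profiles$response),
                  drop = TRUE)
  rows <- lapply(pieces, function(p) {
    f <- fit_confidence_polynomial(p$value, p$confidence, ...)
    data.frame(subject = p$subject[1], task = p$task[1],
               response = p$response[1],
               intercept = f$intercept, linear = f$linear,
               quadratic = f$quadratic, n_levels = f$n_levels,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject, out$task, out$response), ]
}

#' Group-level inference on a coefficient contrast
#'
#' Second step of the two-step analysis: each subject's contrast value is a
#' weighted sum of their per-response polynomial coefficients, and the
#' group-level test is a one-sample t-test of those values against zero
#' (ordinary least squares on an intercept), with Cohen's
#' \eqn{d = \bar{x}/s = t/\sqrt{n}} and an optional JZS Bayes factor in
#' favour of the null.
#'
#' @param coefs Coefficient table from [fit_profile_table()].
#' @param weights Data frame with columns `task`, `response`, `weight`
#'   naming the cells entering the contrast.
#' @param term Which coefficient the contrast is over: `"intercept"`,
#'   `"linear"` or `"quadratic"`.
#' @param contrast Name for the contrast (reporting only).
#' @param bayes Also compute `bf01` via [jzs_bayes_factor()] (default
#'   `TRUE`).
#' @return One-row data frame of class `"group_result"`: `contrast`, `term`,
#'   `n`, `t`, `df`, `p`, `cohens_d`, `bf01`.
#' @export
group_inference <- function(coefs, weights,
                            term = c("quadratic", "linear", "intercept"),
                            contrast = "contrast", bayes = TRUE) {
  term <- match.arg(term)
  stopifnot(all(c("task", "response", "weight") %in% names(weights)))
  subjects <- unique(coefs$subject)
  vals <- vapply(subjects, function(s) {
    sc <- coefs[coefs$subject == s, ]
    v <- 0
    for (i in seq_len(nrow(weights))) {
      row <- sc[sc$task == weights$task[i] & sc$response == weights$response[i], ]
      if (nrow(row) != 1 || !is.finite(row[[term]])) return(NA_real_)
      v <- v + weights$weight[i] * row[[term]]
    }
    v
  }, numeric(1))
  vals <- vals[is.finite(vals)]
  n <- length(vals)
  if (n < 2)
    stop("contrast '", contrast, "': fewer than 2 subjects contribute to ",
         "every weighted cell")
  s <- stats::sd(vals)
  if (s == 0)
    stop("contrast '", contrast, "': degenerate variance ",
         "(all subject values identical)")
  tt <- mean(vals) / (s / sqrt(n))
  out <- data.frame(
    contrast = contrast, term = term, n = n, t = tt, df = n - 1,
    p = 2 * stats::pt(-abs(tt), n - 1),
    cohens_d = mean(vals) / s,
    bf01 = if (bayes) jzs_bayes_factor(tt, n) else NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("group_result", "data.frame")
  out
}

#' JZS Bayes factor for a one-sample t-test
#'
#' Evidence in favour of the null (`BF01`) for a one-sample t-test under the
#' Jeffreys-Zellner-Siow prior: a Cauchy prior with scale `r` on the
#' standardised effect size, i.e. a normal effect prior whose variance `g`
#' follows an inverse-gamma(1/2, r^2/2) mixing distribution. The marginal
#' likelihood under the alternative is computed by adaptive numerical
#' integration over `g`:
#' \deqn{BF_{01}^{-1} = \frac{\int_0^\infty (1+Ng)^{-1/2}
#'   \left(1 + \frac{t^2}{(1+Ng)\nu}\right)^{-(\nu+1)/2} \pi(g)\, dg}
#'   {\left(1 + t^2/\nu\right)^{-(\nu+1)/2}}, \qquad \nu = N - 1.}
#'
#' @param t Observed t statistic (finite).
#' @param n Sample size (>= 2).
#' @param scale Cauchy prior scale `r` (default 1, the unit-information
#'   prior).
#' @return `BF01` (values > 1 favour the null).
#' @examples
#' jzs_bayes_factor(0, 35) # > 1: a null result favours the null
#' @export
jzs_bayes_factor <- function(t, n, scale = 1) {
  stopifnot(is.finite(t), n >= 2, scale > 0)
  nu <- n - 1
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    exp(-0.5 * log1p(n * g) -
          (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) - log_null) *
      scale / sqrt(2 * pi) * g^(-1.5) * exp(-scale^2 / (2 * g))
  }
  alt <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-9,
                     subdivisions = 500L),
    error = function(e) stop("JZS integration failed: ",
                             conditionMessage(e)))
  1 / alt$value
}

#' The study's standard contrast battery
#'
#' Runs the family of group-level contrasts the analysis reports: the
#' overall quadratic effect of confidence; the quadratic and linear task
#' differences (detection minus discrimination); the within-detection linear
#' yes-vs-no difference; and the per-task simple effects of each term.
#' Contrasts whose cells are missing from the coefficient table are returned
#' as named skipped rows rather than dropped silently. P-values are
#' two-sided and uncorrected.
#'
#' @param coefs Coefficient table from [fit_profile_table()] covering the
#'   four responses.
#' @param bayes Compute `bf01` per contrast (default `TRUE`).
#' @return Data frame with one row per contrast (columns as
#'   [group_inference()], plus `skipped`).
#' @export
standard_contrast_battery <- function(coefs, bayes = TRUE) {
  w <- function(task, response, weight) data.frame(
    task = task, response = response, weight = weight,
    stringsAsFactors = FALSE)
  det <- "detection"; dis <- "discrimination"
  all4 <- rbind(w(det, "yes", 0.25), w(det, "no", 0.25),
                w(dis, "clockwise", 0.25), w(dis, "anticlockwise", 0.25))
  task_diff <- rbind(w(det, "yes", 0.5), w(det, "no", 0.5),
                     w(dis, "clockwise", -0.5), w(dis, "anticlockwise", -0.5))
  det_only <- rbind(w(det, "yes", 0.5), w(det, "no", 0.5))
  dis_only <- rbind(w(dis, "clockwise", 0.5), w(dis, "anticlockwise", 0.5))
  yes_no <- rbind(w(det, "yes", 1), w(det, "no", -1))
  spec <- list(
    list(name = "quadratic_overall", weights = all4, term = "quadratic"),
    list(name = "quadratic_task_diff", weights = task_diff, term = "quadratic"),
    list(name = "linear_task_diff", weights = task_diff, term = "linear"),
    list(name = "linear_yes_vs_no", weights = yes_no, term = "linear"),
    list(name = "quadratic_detection", weights = det_only, term = "quadratic"),
    list(name = "quadratic_discrimination", weights = dis_only,
         term = "quadratic"),
    list(name = "linear_detection", weights = det_only, term = "linear"),
    list(name = "linear_discrimination", weights = dis_only, term = "linear"))
  rows <- lapply(spec, function(s) {
    res <- tryCatch(
      group_inference(coefs, s$weights, term = s$term, contrast = s$name,
                      bayes = bayes),
      error = function(e) data.frame(
        contrast = s$name, term = s$term, n = NA_integer_, t = NA_real_,
        df = NA_integer_, p = NA_real_, cohens_d = NA_real_,
        bf01 = NA_real_, stringsAsFactors = FALSE))
    res$skipped <- !is.finite(res$t)
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
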