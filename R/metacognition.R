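# Behavioural metacognition metrics and data-quality filters:
# response-conditional type-2 ROC / AUROC2, meta-d' and metacognitive
# efficiency, and the study's subject- and run-level exclusion rules.

#' Tally type-2 outcomes per response and confidence level
#'
#' Counts correct and incorrect trials at each confidence level, separately
#' for each response type. Missed trials (missing response or confidence)
#' are removed before tallying.
#'
#' @param response Character vector of responses.
#' @param correct Logical vector.
#' @param confidence Integer confidence ratings 1..`n_levels`.
#' @param n_levels Number of confidence levels (default 6).
#' @return Data frame of class `"type2_counts"` with columns `response`,
#'   `confidence`, `n_correct`, `n_incorrect`.
#' @export
type2_counts <- function(response, correct, confidence, n_levels = 6L) {
  stopifnot(length(response) == length(correct),
            length(correct) == length(confidence))
  keep <- !is.na(response) & !is.na(correct) & !is.na(confidence)
  response <- response[keep]; correct <- correct[keep]
  confidence <- confidence[keep]
  if (any(confidence < 1 | confidence > n_levels))
    stop("confidence out of range 1..", n_levels)
  out <- expand.grid(response = sort(unique(response)),
                     confidence = seq_len(n_levels),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(r, k) paste(r, k)
  lev <- key(out$response, out$confidence)
  out$n_correct <- as.integer(table(factor(key(response, confidence)[correct],
                                           levels = lev)))
  out$n_incorrect <- as.integer(table(factor(key(response, confidence)[!correct],
                                             levels = lev)))
  class(out) <- c("type2_counts", "data.frame")
  out
}

# Extract the (correct, incorrect) count vectors for one response.
type2_vectors <- function(counts, response) {
  stopifnot(inherits(counts, "type2_counts") || is.data.frame(counts))
  cc <- counts[counts$response == response, ]
  if (nrow(cc) == 0) stop("no counts for response '", response, "'")
  cc <- cc[order(cc$confidence), ]
  list(correct = cc$n_correct, incorrect = cc$n_incorrect)
}

#' Response-conditional type-2 ROC curve
#'
#' Plots the cumulative distribution of confidence levels in correct
#' responses against that in incorrect responses, sweeping the confidence
#' threshold from the highest level down. The returned points run from
#' (0, 0) to (1, 1) and are monotone non-decreasing in both coordinates;
#' the x coordinate is the cumulative proportion of incorrect trials at or
#' above the threshold, the y coordinate the same for correct trials.
#'
#' @param counts A [type2_counts()] table.
#' @param response Which response's curve to extract.
#' @return Data frame with columns `fpr` (incorrect cumulative proportion)
#'   and `tpr` (correct cumulative proportion), one row per threshold plus
#'   the two endpoints.
#' @export
type2_roc <- function(counts, response) {
  v <- type2_vectors(counts, response)
  if (sum(v$correct) == 0)
    stop("degenerate type-2 data for response '", response,
         "': no correct trials")
  if (sum(v$incorrect) == 0)
    stop("degenerate type-2 data for response '", response,
         "': no incorrect trials")
  # cumulative from the highest confidence level down
  tpr <- c(0, cumsum(rev(v$correct)) / sum(v$correct))
  fpr <- c(0, cumsum(rev(v$incorrect)) / sum(v$incorrect))
  data.frame(fpr = fpr, tpr = tpr)
}

#' Area under the type-2 ROC curve (AUROC2)
#'
#' Trapezoidal area under the response-conditional type-2 ROC. Identical
#' confidence distributions for correct and incorrect trials give 0.5 (no
#' metacognitive insight); perfect separation gives 1.
#'
#' @inheritParams type2_roc
#' @return Area in `[0, 1]`.
#' @export
auroc2 <- function(counts, response) {
  roc <- type2_roc(counts, response)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' AUROC2 per response from a trial table
#'
#' Convenience wrapper: tallies type-2 counts from a trial table and returns
#' the AUROC2 of every response with at least one correct and one incorrect
#' trial (others are `NA`).
#'
#' @param trials Trial table with columns `response`, `correct`,
#'   `confidence` (and optionally `task`).
#' @return Data frame with columns `response` and `auroc2`.
#' @export
auroc2_from_trials <- function(trials) {
  counts <- type2_counts(trials$response, trials$correct, trials$confidence)
  responses <- unique(counts$response)
  data.frame(
    response = responses,
    auroc2 = vapply(responses, function(r) {
      tryCatch(auroc2(counts, r), error = function(e) NA_real_)
    }, numeric(1)),
    stringsAsFactors = FALSE)
}

# ---- meta-d' -------------------------------------------------------------

# Response-conditional confidence probabilities predicted by an
# equal-variance SDT observer with sensitivity meta_d, type-1 criterion at
# the empirical relative position, and response-specific type-2 criteria.
# Returns a list of four probability vectors (stim x response).
meta_d_predicted <- function(meta_d, t2_lo, t2_hi, meta_c, n_levels) {
  mus <- c(-meta_d / 2, meta_d / 2)          # S1, S2
  # criteria for "S1" responses: meta_c down to -Inf (confidence 1..K maps
  # to bands approaching the criterion); for "S2": meta_c up to +Inf
  lo_cuts <- c(-Inf, t2_lo, meta_c)          # increasing, length K+1
  hi_cuts <- c(meta_c, t2_hi, Inf)
  out <- list()
  for (s in 1:2) {
    p_lo <- diff(stats::pnorm(lo_cuts, mus[s]))   # mass per band, low side
    p_hi <- diff(stats::pnorm(hi_cuts, mus[s]))
    out[[paste0("s", s, "_r1")]] <- rev(p_lo)     # confidence 1..K
    out[[paste0("s", s, "_r2")]] <- p_hi
  }
  out
}

#' Maximum-likelihood meta-d' and metacognitive efficiency
#'
#' Fits the standard meta-d' model: the type-1 sensitivity an equal-variance
#' SDT observer would need in order to produce the observed
#' response-conditional confidence counts, given the empirical type-1
#' criterion (held at its relative position \eqn{c' = c/d'}). The fit
#' maximises the multinomial likelihood of the confidence counts conditional
#' on each (stimulus, response) cell over meta-d' and the 2(K-1)
#' response-specific type-2 criteria. Metacognitive efficiency is
#' `meta_d / dprime`.
#'
#' @param counts Integer array `2 x 2 x K`: stimulus (S1, S2) x response
#'   (r1 = "S1", r2 = "S2") x confidence level 1..K. For detection S1 is
#'   target-absent and r1 the no response.
#' @param pad Add `1/(2K)` to every count cell before fitting (default
#'   `TRUE`), the standard guard against zero cells.
#' @return List with `meta_d`, `dprime`, `criterion_c`, `m_ratio`,
#'   `logLik`, `convergence` (0 = converged) and the fitted type-2 criteria.
#' @export
meta_dprime <- function(counts, pad = TRUE) {
  d <- dim(counts)
  if (length(d) != 3 || d[1] != 2 || d[2] != 2)
    stop("counts must be a 2 x 2 x K array (stimulus x response x confidence)")
  K <- d[3]
  if (K < 2) stop("need at least 2 confidence levels")
  if (any(counts < 0)) stop("negative counts")
  if (any(apply(counts, 1, sum) == 0)) stop("a stimulus row has no trials")
  cts <- counts + if (pad) 1 / (2 * K) else 0

  # type-1 summary from the (padded) response marginals
  n_s1 <- sum(cts[1, , ]); n_s2 <- sum(cts[2, , ])
  hr <- sum(cts[2, 2, ]) / n_s2
  fa <- sum(cts[1, 2, ]) / n_s1
  t1 <- sensitivity_from_rates(min(max(hr, 1e-8), 1 - 1e-8),
                               min(max(fa, 1e-8), 1 - 1e-8))
  dprime <- t1$dprime
  c_rel <- if (abs(dprime) > 1e-8) t1$criterion_c / dprime else 0

  nll <- function(par) {
    meta_d <- par[1]
    meta_c <- c_rel * meta_d
    t2_lo <- meta_c - cumsum(exp(par[2:K]))          # K-1 below, decreasing
    t2_hi <- meta_c + cumsum(exp(par[(K + 1):(2 * K - 1)]))
    pr <- meta_d_predicted(meta_d, rev(t2_lo), t2_hi, meta_c, K)
    # rev(): meta_d_predicted expects t2_lo increasing toward meta_c
    ll <- 0
    obs <- list(cts[1, 1, ], cts[1, 2, ], cts[2, 1, ], cts[2, 2, ])
    prd <- list(pr$s1_r1, pr$s1_r2, pr$s2_r1, pr$s2_r2)
    for (i in 1:4) {
      p <- prd[[i]] / sum(prd[[i]])
      ll <- ll + sum(obs[[i]] * log(pmax(p, 1e-300))) *
        (sum(prd[[i]]) > 0)
    }
    -ll
  }
  init <- c(dprime, rep(log(0.4), 2 * (K - 1)))
  fit <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  if (fit$convergence != 0)
    warning("meta-d' fit did not converge (code ", fit$convergence, ")")
  meta_d <- fit$par[1]
  list(meta_d = meta_d,
       dprime = dprime,
       criterion_c = t1$criterion_c,
       m_ratio = meta_d / dprime,
       t2_criteria_low = c_rel * meta_d - cumsum(exp(fit$par[2:K])),
       t2_criteria_high = c_rel * meta_d +
         cumsum(exp(fit$par[(K + 1):(2 * K - 1)])),
       logLik = -fit$value,
       convergence = fit$convergence)
}

#' Meta-d' likelihood of a candidate solution
#'
#' Log likelihood of the response-conditional confidence counts under a
#' given meta-d' and explicit type-2 criteria, with the type-1 criterion at
#' the empirical relative position. Exposed so independent search procedures
#' can score candidate solutions against the same objective.
#'
#' @inheritParams meta_dprime
#' @param meta_d Candidate meta-d'.
#' @param t2_low Type-2 criteria below the type-1 criterion, increasing
#'   (length K-1).
#' @param t2_high Type-2 criteria above, increasing (length K-1).
#' @return Log likelihood (response-conditional multinomial).
#' @export
meta_d_loglik <- function(counts, meta_d, t2_low, t2_high, pad = TRUE) {
  K <- dim(counts)[3]
  cts <- counts + if (pad) 1 / (2 * K) else 0
  hr <- sum(cts[2, 2, ]) / sum(cts[2, , ])
  fa <- sum(cts[1, 2, ]) / sum(cts[1, , ])
  t1 <- sensitivity_from_rates(min(max(hr, 1e-8), 1 - 1e-8),
                               min(max(fa, 1e-8), 1 - 1e-8))
  c_rel <- if (abs(t1$dprime) > 1e-8) t1$criterion_c / t1$dprime else 0
  meta_c <- c_rel * meta_d
  if (any(t2_low >= meta_c) || any(t2_high <= meta_c)) return(-Inf)
  pr <- meta_d_predicted(meta_d, t2_low, t2_high, meta_c, K)
  obs <- list(cts[1, 1, ], cts[1, 2, ], cts[2, 1, ], cts[2, 2, ])
  prd <- list(pr$s1_r1, pr$s1_r2, pr$s2_r1, pr$s2_r2)
  ll <- 0
  for (i in 1:4) {
    p <- prd[[i]] / sum(prd[[i]])
    ll <- ll + sum(obs[[i]] * log(pmax(p, 1e-300)))
  }
  ll
}

#' Tally a 2 x 2 x K count array from a trial table
#'
#' @param trials Trial table for one task with columns `stimulus`,
#'   `response`, `confidence`; missed trials are dropped.
#' @param task Task name, fixing the class/response order (lower class
#'   first: absent/no or anticlockwise).
#' @param n_levels Number of confidence levels.
#' @return Integer array `2 x 2 x n_levels`.
#' @export
response_confidence_counts <- function(trials, task, n_levels = 6L) {
  classes <- task_classes(task)
  responses <- task_responses(task)
  keep <- !is.na(trials$response) & !is.na(trials$confidence)
  tr <- trials[keep, ]
  arr <- array(0L, dim = c(2, 2, n_levels),
               dimnames = list(classes, responses, seq_len(n_levels)))
  tab <- table(factor(tr$stimulus, classes), factor(tr$response, responses),
               factor(tr$confidence, seq_len(n_levels)))
  arr[] <- as.integer(tab)
  arr
}

# ---- exclusion rules -----------------------------------------------------

# Proportion of trials sharing the modal value (0 when empty).
modal_share <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(0)
  max(table(x)) / length(x)
}

#' Apply the study's subject- and run-level exclusion rules
#'
#' Evaluates the pre-specified data-quality rules on one subject's trial
#' table. Subject-level rules: missing more than 20% of trials; accuracy
#' below 60% on either task; using the same response in more than 75% of a
#' task's trials; using the same confidence level in more than 80% of all
#' trials globally or of a particular response's trials; a motion flag in
#' more than `motion_max_runs` runs. Run-level rules: missing more than 20%
#' of the run's trials; run accuracy below 60%; response bias above 80% for
#' one of the tasks; the same confidence level in more than 95% of the run's
#' trials globally or for a particular response; the run's motion flag. An
#' excluded subject makes all of their runs unusable. Boundary values are
#' honoured exactly as stated (strict inequalities throughout except the
#' accuracy rule, which excludes only accuracy strictly below 60%).
#'
#' Motion cannot be computed from behaviour; it enters as precomputed
#' per-run flags.
#'
#' @param trials One subject's trial table (columns `subject`, `run`,
#'   `task`, `response`, `correct`, `confidence`).
#' @param motion_flags Optional data frame with columns `run` and `flag`
#'   (logical, `TRUE` = exceeded the motion cutoff).
#' @param motion_max_runs Subject excluded when more than this many runs are
#'   motion-flagged (default 2).
#' @return List of class `"exclusion_report"` with elements `subject` (one
#'   row: `subject`, `included`, `rules` as a semicolon-joined string) and
#'   `runs` (per run: `run`, `usable`, `rules`).
#' @export
apply_exclusion <- function(trials, motion_flags = NULL, motion_max_runs = 2L) {
  if (nrow(trials) == 0) stop("empty trial table")
  stopifnot(all(c("run", "task", "response", "correct", "confidence")
                %in% names(trials)))
  subject_id <- if ("subject" %in% names(trials)) trials$subject[1] else NA
  runs <- sort(unique(trials$run))
  motion <- setNames(rep(FALSE, length(runs)), runs)
  if (!is.null(motion_flags))
    motion[as.character(motion_flags$run)] <- motion_flags$flag

  subj_rules <- character(0)
  if (mean(is.na(trials$response)) > 0.20)
    subj_rules <- c(subj_rules, "missing_gt_20pct")
  for (task in unique(trials$task)) {
    tt <- trials[trials$task == task, ]
    if (mean(tt$correct, na.rm = TRUE) < 0.60)
      subj_rules <- c(subj_rules, paste0("accuracy_lt_60pct_", task))
    if (modal_share(tt$response) > 0.75)
      subj_rules <- c(subj_rules, paste0("response_bias_gt_75pct_", task))
  }
  conf_bias <- modal_share(trials$confidence) > 0.80 ||
    any(vapply(split(trials$confidence, trials$response),
               function(v) modal_share(v) > 0.80, logical(1)))
  if (conf_bias) subj_rules <- c(subj_rules, "confidence_gt_80pct")
  if (sum(motion) > motion_max_runs)
    subj_rules <- c(subj_rules, "motion_gt_2_runs")
  included <- length(subj_rules) == 0

  run_rows <- lapply(runs, function(r) {
    rt <- trials[trials$run == r, ]
    rules <- character(0)
    if (mean(is.na(rt$response)) > 0.20) rules <- c(rules, "missing_gt_20pct")
    if (mean(rt$correct, na.rm = TRUE) < 0.60)
      rules <- c(rules, "accuracy_lt_60pct")
    for (task in unique(rt$task)) {
      if (modal_share(rt$response[rt$task == task]) > 0.80) {
        rules <- c(rules, paste0("response_bias_gt_80pct_", task))
      }
    }
    rconf <- modal_share(rt$confidence) > 0.95 ||
      any(vapply(split(rt$confidence, rt$response),
                 function(v) modal_share(v) > 0.95, logical(1)))
    if (rconf) rules <- c(rules, "confidence_gt_95pct")
    if (motion[as.character(r)]) rules <- c(rules, "motion")
    if (!included) rules <- c(rules, "subject_excluded")
    data.frame(run = r, usable = length(rules) == 0,
               rules = paste(rules, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  structure(list(
    subject = data.frame(subject = subject_id, included = included,
                         rules = paste(subj_rules, collapse = ";"),
                         stringsAsFactors = FALSE),
    runs = do.call(rbind, run_rows)),
    class = "exclusion_report")
}
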