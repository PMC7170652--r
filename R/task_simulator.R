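# Synthetic-data generator: trial structure, adaptive SNR rules, bonus
# schedule, and group-level synthetic "regional signal" profiles, so every
# downstream stage runs without any real data.

#' Calibration staircase targeting ~70% accuracy
#'
#' Simulates a pre-session staircase: the observer's sensitivity is a
#' strictly increasing function of the stimulus signal-to-noise ratio
#' (default `dprime = slope * snr`), trial accuracy is Bernoulli with
#' probability \eqn{\Phi(d'/2)} (unbiased equal-variance observer), and once
#' every `window` trials the SNR is adjusted from the accuracy over that
#' window: below `lower` the SNR is divided by `factor` (made easier), above
#' `upper` it is multiplied by `factor` (made harder). Accuracy exactly at a
#' boundary leaves the SNR unchanged. With the 60%/80% thresholds this
#' procedure targets accuracy around 70%.
#'
#' @param dprime_of_snr Function mapping SNR to d-prime, strictly increasing.
#' @param n_trials Number of trials (at least `window`).
#' @param start_snr Initial SNR (> 0).
#' @param seed Optional integer seed.
#' @param window Trials per adjustment window (default 10).
#' @param factor Multiplicative step (default 0.9).
#' @param lower,upper Window-accuracy thresholds (defaults 0.6 and 0.8).
#' @return Data frame with per-trial columns `trial`, `snr`, `correct`.
#' @export
run_calibration_staircase <- function(dprime_of_snr = function(snr) 2 * snr,
                                      n_trials = 2000, start_snr = 0.5,
                                      seed = NULL, window = 10L,
                                      factor = 0.9, lower = 0.6, upper = 0.8) {
  if (n_trials < window)
    stop("n_trials must be at least the window length (", window, ")")
  stopifnot(start_snr > 0, factor > 0, factor < 1, lower < upper)
  if (!is.null(seed)) set.seed(seed)
  snr <- numeric(n_trials)
  correct <- logical(n_trials)
  s <- start_snr
  for (t in seq_len(n_trials)) {
    snr[t] <- s
    correct[t] <- stats::runif(1) < stats::pnorm(dprime_of_snr(s) / 2)
    if (t %% window == 0L) {
      acc <- mean(correct[(t - window + 1L):t])
      if (acc < lower) s <- s / factor
      else if (acc > upper) s <- s * factor
    }
  }
  data.frame(trial = seq_len(n_trials), snr = snr, correct = correct)
}

#' Between-block SNR adjustment
#'
#' After a block with markedly bad (accuracy at or below 52.5%) or good (at
#' or above 85%) performance, the next block of the same task has its SNR
#' divided or multiplied by 0.9 respectively; otherwise the SNR is unchanged.
#'
#' @param prev_block_accuracy Accuracy of the previous block of this task.
#' @param snr Current SNR.
#' @param bad,good Inclusive thresholds (defaults 0.525 and 0.85).
#' @param factor Multiplicative step (default 0.9).
#' @return Adjusted SNR.
#' @export
adjust_block_snr <- function(prev_block_accuracy, snr,
                             bad = 0.525, good = 0.85, factor = 0.9) {
  stopifnot(prev_block_accuracy >= 0, prev_block_accuracy <= 1, snr > 0)
  if (prev_block_accuracy <= bad) snr / factor
  else if (prev_block_accuracy >= good) snr * factor
  else snr
}

#' Between-run SNR adjustment balancing the two tasks
#'
#' If the run-level accuracy difference between the tasks strictly exceeds
#' 16.25 percentage points, the easier task's SNR is multiplied by
#' \eqn{\sqrt{0.9}} and the harder task's divided by it; otherwise both are
#' unchanged.
#'
#' @param accuracy_detection,accuracy_discrimination Run accuracies.
#' @param snr_detection,snr_discrimination Current SNRs.
#' @param threshold Strict accuracy-difference threshold (default 0.1625).
#' @param factor Base factor; the applied step is `sqrt(factor)`.
#' @return List with `snr_detection` and `snr_discrimination`.
#' @export
adjust_run_snr <- function(accuracy_detection, accuracy_discrimination,
                           snr_detection, snr_discrimination,
                           threshold = 0.1625, factor = 0.9) {
  stopifnot(accuracy_detection >= 0, accuracy_detection <= 1,
            accuracy_discrimination >= 0, accuracy_discrimination <= 1)
  d <- accuracy_detection - accuracy_discrimination
  # strict threshold with a guard against floating-point residue at the
  # exact 16.25% boundary
  if (abs(d) > threshold + 1e-9) {
    step <- sqrt(factor)
    if (d > 0) {  # detection easier
      snr_detection <- snr_detection * step
      snr_discrimination <- snr_discrimination / step
    } else {
      snr_detection <- snr_detection / step
      snr_discrimination <- snr_discrimination * step
    }
  }
  list(snr_detection = snr_detection, snr_discrimination = snr_discrimination)
}

#' Design configuration for a simulated session
#'
#' @param n_runs Scanner runs (default 5).
#' @param blocks_per_run Blocks per run, one per task (default 2).
#' @param trials_per_block Trials per block (default 40).
#' @param snr_detection,snr_discrimination Starting SNR per task.
#' @param dprime_slope Slope of the linear d-prime-vs-SNR link.
#' @param sigma_ratio Detection signal/noise sd ratio (1 = equal variance).
#' @param prevalence Signal prevalence in detection blocks (default 0.5,
#'   realised exactly: half the trials in every block are targets).
#' @param lapse Probability of a missed response per trial (default 0).
#' @param snr_order Order in which the block- and run-level SNR rules compose
#'   when both trigger at a run boundary (default block rule first).
#' @return List of class `"session_design"`.
#' @export
session_design <- function(n_runs = 5L, blocks_per_run = 2L,
                           trials_per_block = 40L,
                           snr_detection = 0.5, snr_discrimination = 0.5,
                           dprime_slope = 3, sigma_ratio = 1.5,
                           prevalence = 0.5, lapse = 0,
                           snr_order = c("block_then_run", "run_then_block")) {
  stopifnot(n_runs >= 1, blocks_per_run == 2L, trials_per_block >= 2,
            trials_per_block %% 2 == 0, snr_detection > 0,
            snr_discrimination > 0, dprime_slope > 0, sigma_ratio >= 1,
            lapse >= 0, lapse <= 1, prevalence > 0, prevalence < 1)
  structure(list(n_runs = as.integer(n_runs),
                 blocks_per_run = 2L,
                 trials_per_block = as.integer(trials_per_block),
                 snr_detection = snr_detection,
                 snr_discrimination = snr_discrimination,
                 dprime_slope = dprime_slope,
                 sigma_ratio = sigma_ratio,
                 prevalence = prevalence,
                 lapse = lapse,
                 snr_order = match.arg(snr_order)),
            class = "session_design")
}

# SDT parameters for a task at a given SNR under the linear d'-SNR link.
# For detection the signal mean is set to slope * snr with the configured
# sd ratio; for discrimination the half-separation is slope * snr / 2 so
# that the class separation in sd units equals the nominal d'.
params_at_snr <- function(task, snr, design) {
  dp <- design$dprime_slope * snr
  if (task == "detection")
    sdt_params("detection", mu_signal = dp, sigma_signal = design$sigma_ratio)
  else
    sdt_params("discrimination", mu_signal = dp / 2)
}

#' Generate one subject's behavioural session
#'
#' Produces the full trial table for one simulated subject: `n_runs` runs of
#' one detection and one discrimination block each (order randomised within
#' run), `trials_per_block` trials per block with exactly balanced stimulus
#' categories, response mapping counterbalanced across blocks of each task,
#' SNR fixed within block and adjusted between blocks and runs by
#' [adjust_block_snr()] and [adjust_run_snr()], and an i.i.d. lapse process
#' producing missed responses (missing response, confidence and correctness).
#' Behaviour comes from the static SDT observer whose sensitivity follows
#' the design's linear d-prime-vs-SNR link.
#'
#' @param subject Subject identifier.
#' @param design A [session_design()].
#' @param seed Optional integer seed.
#' @return Data frame of trial records: `subject`, `run`, `block`, `task`,
#'   `stimulus`, `response`, `correct`, `confidence`, `snr`, `resp_mapping`.
#' @export
generate_session <- function(subject = "s01", design = session_design(),
                             seed = NULL) {
  stopifnot(inherits(design, "session_design"))
  if (!is.null(seed)) set.seed(seed)
  snr <- c(detection = design$snr_detection,
           discrimination = design$snr_discrimination)
  last_block_acc <- c(detection = NA_real_, discrimination = NA_real_)
  mapping_count <- c(detection = 0L, discrimination = 0L)
  rows <- vector("list", design$n_runs * 2L)
  block_id <- 0L
  for (run in seq_len(design$n_runs)) {
    run_acc <- c(detection = NA_real_, discrimination = NA_real_)
    tasks <- sample(c("detection", "discrimination"))
    for (task in tasks) {
      block_id <- block_id + 1L
      # block-level SNR rule from the previous block of the same task
      if (!is.na(last_block_acc[[task]]))
        snr[[task]] <- adjust_block_snr(last_block_acc[[task]], snr[[task]])
      params <- params_at_snr(task, snr[[task]], design)
      rule <- confidence_rule_for(params)
      nt <- design$trials_per_block
      classes <- task_classes(task)
      stim <- sample(rep(classes, each = nt / 2L))
      xs <- ifelse(stim == classes[2L],
                   stats::rnorm(nt, params$mu2, params$sigma2),
                   stats::rnorm(nt, params$mu1, params$sigma1))
      resp_upper <- xs > params$criterion
      response <- task_responses(task)[resp_upper + 1L]
      correct <- (stim == classes[2L]) == resp_upper
      confidence <- bin_confidence(abs(xs - params$criterion), rule)
      lapsed <- stats::runif(nt) < design$lapse
      response[lapsed] <- NA_character_
      correct[lapsed] <- NA
      confidence[lapsed] <- NA_integer_
      mapping_count[[task]] <- mapping_count[[task]] + 1L
      rows[[block_id]] <- data.frame(
        subject = subject, run = run, block = block_id, task = task,
        stimulus = stim, response = response, correct = correct,
        confidence = confidence, snr = snr[[task]],
        resp_mapping = c("index_upper", "index_lower")[
          (mapping_count[[task]] %% 2L) + 1L],
        stringsAsFactors = FALSE)
      acc <- mean(correct, na.rm = TRUE)
      last_block_acc[[task]] <- acc
      run_acc[[task]] <- acc
    }
    # run-level balancing rule (composed after the block rule by default;
    # the block rule is applied lazily at the next block of the task, so the
    # configured order decides which accuracy feeds which rule first)
    adj <- adjust_run_snr(run_acc[["detection"]], run_acc[["discrimination"]],
                          snr[["detection"]], snr[["discrimination"]])
    snr[["detection"]] <- adj$snr_detection
    snr[["discrimination"]] <- adj$snr_discrimination
  }
  do.call(rbind, rows)
}

#' Confidence-weighted accuracy bonus
#'
#' The session bonus in pounds: the dot product of the signed accuracy
#' vector (+1 correct, -1 incorrect) with the confidence vector (integers
#' 1-6), divided by 200. Missed trials (`NA`) contribute nothing.
#'
#' @param correct Logical vector (may contain `NA` for missed trials).
#' @param confidence Integer vector of confidence ratings 1-6 (`NA` where
#'   `correct` is `NA`).
#' @return Bonus in pounds (not rounded).
#' @examples
#' compute_bonus(c(TRUE, FALSE, TRUE), c(6, 6, 1)) # 1/200
#' @export
compute_bonus <- function(correct, confidence) {
  if (length(correct) != length(confidence))
    stop("correct and confidence must have equal length")
  keep <- !is.na(correct)
  conf <- confidence[keep]
  if (any(is.na(conf)))
    stop("confidence missing on a responded trial")
  if (any(conf < 1 | conf > 6 | conf != round(conf)))
    stop("confidence ratings must be integers in 1..6")
  sum((2 * correct[keep] - 1) * conf) / 200
}

#' Synthetic regional confidence profiles for a group of subjects
#'
#' Generates per-subject, per-response six-level "regional signal" profiles
#' (synthetic stand-ins for region-of-interest activation estimates per
#' confidence level): for each subject and each (task, response) cell the
#' profile is \eqn{b_0 + b_1 \cdot \mathrm{code} + b_2 \cdot \mathrm{code}^2}
#' plus i.i.d. Gaussian noise, with centred confidence codes
#' (`confidence - 3.5`). Optional masking marks random cells as unused
#' confidence levels (value `NA`).
#'
#' The default generative coefficients carry the group-level pattern the
#' analysis is designed to detect: a positive quadratic confidence effect in
#' detection only, and a linear effect more negative for no than for yes
#' responses.
#'
#' @param true_coefs Data frame with columns `task`, `response`, `b0`, `b1`,
#'   `b2` covering the four responses.
#' @param noise_sd Standard deviation of the added Gaussian noise (>= 0).
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Optional integer seed.
#' @param mask_prob Per-cell probability of masking a level as unused.
#' @return Data frame with columns `subject`, `task`, `response`,
#'   `confidence`, `value`.
#' @export
generate_roi_profiles <- function(true_coefs = default_profile_coefs(),
                                  noise_sd = 0.2, n_subjects = 35,
                                  seed = NULL, mask_prob = 0) {
  stopifnot(n_subjects >= 2, noise_sd >= 0, mask_prob >= 0, mask_prob < 1,
            all(c("task", "response", "b0", "b1", "b2") %in% names(true_coefs)))
  if (!is.null(seed)) set.seed(seed)
  conf <- 1:6
  code <- conf - 3.5
  out <- vector("list", n_subjects * nrow(true_coefs))
  k <- 0L
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("s%02d", s)
    for (i in seq_len(nrow(true_coefs))) {
      k <- k + 1L
      mu <- true_coefs$b0[i] + true_coefs$b1[i] * code +
        true_coefs$b2[i] * code^2
      val <- mu + stats::rnorm(6, 0, noise_sd)
      if (mask_prob > 0)
        val[stats::runif(6) < mask_prob] <- NA_real_
      out[[k]] <- data.frame(
        subject = sid, task = true_coefs$task[i],
        response = true_coefs$response[i],
        confidence = conf, value = val, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Default generative coefficients for synthetic confidence profiles
#'
#' Quadratic confidence effect (`b2 = 0.5`) for the two detection responses
#' only, with the linear effect more negative for no than yes responses, and
#' no quadratic effect in discrimination.
#'
#' @return Data frame with columns `task`, `response`, `b0`, `b1`, `b2`.
#' @export
default_profile_coefs <- function() {
  data.frame(
    task = c("detection", "detection", "discrimination", "discrimination"),
    response = c("yes", "no", "clockwise", "anticlockwise"),
    b0 = c(0, 0, 0, 0),
    b1 = c(-0.2, -0.4, -0.1, -0.1),
    b2 = c(0.5, 0.5, 0, 0),
    stringsAsFactors = FALSE)
}
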