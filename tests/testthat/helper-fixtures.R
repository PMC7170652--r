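# Shared fixtures and independent mini-oracles used across the test files.

# A minimal hand-built trial table: `n` trials of one task spread over runs,
# with explicit response/correct/confidence vectors.
make_trials <- function(n, task = "detection", runs = 1L,
                        response = NULL, correct = NULL, confidence = NULL,
                        missing = 0L) {
  classes <- task_classes(task)
  responses <- task_responses(task)
  if (is.null(response)) response <- rep(responses, length.out = n)
  if (is.null(correct)) correct <- rep(c(TRUE, TRUE, TRUE, FALSE),
                                       length.out = n)
  if (is.null(confidence)) confidence <- rep(1:6, length.out = n)
  if (missing > 0) {
    idx <- seq_len(missing)
    response[idx] <- NA
    correct[idx] <- NA
    confidence[idx] <- NA
  }
  data.frame(
    subject = "s01",
    run = rep(seq_len(runs), each = ceiling(n / runs))[seq_len(n)],
    block = rep(1L, n),
    task = task,
    stimulus = rep(classes, length.out = n),
    response = response, correct = correct, confidence = confidence,
    snr = 0.5, resp_mapping = "index_upper",
    stringsAsFactors = FALSE)
}

# Confidence vector for run-level boundary tests: `share` of each run's
# trials (and of each response's trials, responses alternating by position)
# at level 6, the rest at lower levels.
conf_at_run_share <- function(n = 400, runs = 2, share = 0.95) {
  conf <- rep(6L, n)
  per_run <- n / runs
  n_low <- round((1 - share) * per_run)      # low-confidence trials per run
  for (r in seq_len(runs)) {
    offset <- (r - 1) * per_run
    odd <- offset + seq(1, by = 2, length.out = ceiling(n_low / 2))
    even <- offset + seq(2, by = 2, length.out = floor(n_low / 2))
    conf[c(odd, even)] <- rep(1:5, length.out = n_low)
  }
  conf
}

# Independent cumulative-sum type-2 ROC (oracle for type2_roc/auroc2):
# sweeps confidence from high to low, trapezoidal area.
oracle_auroc2 <- function(correct_counts, incorrect_counts) {
  tpr <- c(0, cumsum(rev(correct_counts)) / sum(correct_counts))
  fpr <- c(0, cumsum(rev(incorrect_counts)) / sum(incorrect_counts))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Closed-form OLS of a 6-point profile on centred linear + quadratic codes
# via the normal equations (oracle for fit_confidence_polynomial).
oracle_poly_fit <- function(values, confidence = seq_along(values)) {
  code <- confidence - 3.5
  X <- cbind(1, code, code^2)
  solve(t(X) %*% X, t(X) %*% values)[, 1]
}

# Fast generator + fitter for group-level null simulations: returns the
# coefficient table of n_subjects x 4 responses profiles with pure-noise
# values. Uses the same normal-equation projection as the package fit
# (equality asserted separately in the confidence-profile tests).
fast_null_coefs <- function(n_subjects, noise_sd, responses = NULL) {
  if (is.null(responses))
    responses <- data.frame(
      task = c("detection", "detection", "discrimination", "discrimination"),
      response = c("yes", "no", "clockwise", "anticlockwise"),
      stringsAsFactors = FALSE)
  code <- 1:6 - 3.5
  X <- cbind(1, code, code^2)
  W <- solve(crossprod(X)) %*% t(X)          # 3 x 6 projection
  m <- n_subjects * nrow(responses)
  noise <- matrix(rnorm(m * 6, 0, noise_sd), m, 6)
  cf <- noise %*% t(W)
  data.frame(
    subject = rep(sprintf("s%02d", seq_len(n_subjects)),
                  each = nrow(responses)),
    task = rep(responses$task, n_subjects),
    response = rep(responses$response, n_subjects),
    intercept = cf[, 1], linear = cf[, 2], quadratic = cf[, 3],
    n_levels = 6L, stringsAsFactors = FALSE)
}

# Independent JZS marginal-likelihood quadrature on the substitution
# u = g / (1 + g) with the midpoint rule at n_grid points; doubling n_grid
# is used to confirm convergence.
oracle_jzs_bf01 <- function(t, n, scale = 1, n_grid = 20000) {
  nu <- n - 1
  u <- (seq_len(n_grid) - 0.5) / n_grid
  g <- u / (1 - u)
  jac <- 1 / (1 - u)^2
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  f <- exp(-0.5 * log1p(n * g) -
             (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) - log_null) *
    scale / sqrt(2 * pi) * g^(-1.5) * exp(-scale^2 / (2 * g)) * jac
  1 / (mean(f[is.finite(f)]) * 1)
}
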