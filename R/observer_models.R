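# Three candidate accounts of detection/discrimination confidence, each
# exposed as a simulator emitting response-by-confidence prediction curves:
#   static_sdt          - |LLR| under fixed unequal-variance SDT
#   dynamic_criterion   - |criterion shift| under trial-to-trial belief updating
#   attention_monitoring- posterior P(onTask) under a latent attention state

# ---- prediction curves --------------------------------------------------

# Build a tidy prediction curve from per-trial values. Every response x level
# cell is present; cells with no trials are flagged (n = 0, mean/se = NA).
curve_from_trials <- function(model, quantity, task, response, confidence,
                              value, n_levels = 6L) {
  responses <- task_responses(task)
  grid <- expand.grid(response = responses, confidence = seq_len(n_levels),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(response, confidence)
  gkey <- paste(grid$response, grid$confidence)
  grid$n <- as.integer(table(factor(key, levels = gkey)))
  agg_m <- tapply(value, factor(key, levels = gkey), mean)
  agg_s <- tapply(value, factor(key, levels = gkey),
                  function(v) stats::sd(v) / sqrt(length(v)))
  out <- data.frame(model = model, quantity = quantity, task = task,
                    response = grid$response, confidence = grid$confidence,
                    mean = as.numeric(agg_m), se = as.numeric(agg_s),
                    n = grid$n, stringsAsFactors = FALSE)
  class(out) <- c("prediction_curve", "data.frame")
  out
}

#' Quadratic fit of a prediction curve, with Monte-Carlo standard errors
#'
#' For each (task, response) of a prediction curve, fits
#' `mean ~ 1 + code + code^2` by ordinary least squares over the non-empty
#' cells, with the confidence codes centred (`confidence - 3.5`). Standard
#' errors of the coefficients are propagated from the per-cell Monte-Carlo
#' standard errors (the coefficients are linear in the cell means), so they
#' measure simulation noise, not lack of fit. Responses with fewer than three
#' non-empty cells are returned with `NA` coefficients.
#'
#' @param curve A prediction curve as returned by [static_prediction()],
#'   [dynamic_criterion_simulate()] or [attention_monitoring_simulate()].
#' @param center Centre of the confidence codes (default 3.5 for a 6-point
#'   scale, decorrelating the linear and quadratic terms).
#' @return Data frame with columns `model`, `quantity`, `task`, `response`,
#'   `term` (`intercept`, `linear`, `quadratic`), `estimate`, `mc_se`,
#'   `n_cells`.
#' @export
curve_poly_fit <- function(curve, center = 3.5) {
  stopifnot(inherits(curve, "prediction_curve") || is.data.frame(curve))
  groups <- unique(curve[, c("model", "quantity", "task", "response")])
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    cc <- curve[curve$model == g$model & curve$task == g$task &
                  curve$response == g$response & curve$n > 0, ]
    terms <- c("intercept", "linear", "quadratic")
    if (nrow(cc) < 3) {
      est <- mse <- rep(NA_real_, 3)
    } else {
      code <- cc$confidence - center
      X <- cbind(1, code, code^2)
      W <- solve(crossprod(X)) %*% t(X)            # coef = W %*% mean
      est <- drop(W %*% cc$mean)
      se2 <- ifelse(is.finite(cc$se), cc$se^2, 0)
      mse <- sqrt(drop(W^2 %*% se2))
    }
    out[[i]] <- data.frame(
      model = g$model, quantity = g$quantity, task = g$task,
      response = g$response, term = terms,
      estimate = est, mc_se = mse, n_cells = nrow(cc),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Response-conditional |LLR| binning: thresholds equally spaced between 0 and
# the response-specific 99th percentile, so both responses use the full scale
# (as participants do) even though their |LLR| ranges differ.
bin_confidence_by_response <- function(magnitude, response, n_levels = 6L,
                                       p_max = 0.99) {
  conf <- integer(length(magnitude))
  for (rr in unique(response)) {
    i <- response == rr
    rule <- confidence_rule_from_magnitudes(magnitude[i], n_levels, p_max)
    conf[i] <- bin_confidence(magnitude[i], rule)
  }
  conf
}

# ---- static SDT model ---------------------------------------------------

#' Prediction curve of the static signal detection model
#'
#' Simulates both tasks under fixed SDT parameters (unequal-variance for
#' detection, equal-variance for discrimination), with confidence given by
#' the binned distance of the evidence sample from the criterion, and returns
#' the mean absolute log likelihood ratio per (task, response, confidence)
#' cell. Under unequal variances the evidence-to-LLR mapping is quadratic, so
#' the yes-response curve carries a pronounced positive quadratic confidence
#' effect, while both discrimination curves are affine.
#'
#' @param det_params,disc_params [sdt_params()] for the two tasks; detection
#'   must be unequal- (or equal-) variance, discrimination equal-variance.
#' @param n_trials Trials simulated per task.
#' @param seed Optional integer seed.
#' @param rule_det,rule_disc Confidence rules; default the analytic
#'   [confidence_rule_for()] of each task.
#' @return A prediction curve data frame (see [curve_poly_fit()] for the
#'   polynomial summary).
#' @export
static_prediction <- function(det_params = sdt_params("detection"),
                              disc_params = sdt_params("discrimination",
                                                       mu_signal = 0.75),
                              n_trials = 1e5, seed = NULL,
                              rule_det = confidence_rule_for(det_params),
                              rule_disc = confidence_rule_for(disc_params)) {
  stopifnot(det_params$task == "detection",
            disc_params$task == "discrimination")
  if (det_params$sigma2 < det_params$sigma1)
    stop("detection parameters must be unequal-variance (sigma_signal >= sigma_noise)")
  if (!is.null(seed)) set.seed(seed)
  pieces <- lapply(list(det_params, disc_params), function(p) {
    rule <- if (p$task == "detection") rule_det else rule_disc
    tr <- simulate_sdt_trials(n_trials, p, rule = rule)
    curve_from_trials("static_sdt", "abs_llr", p$task, tr$response,
                      tr$confidence, abs(log_likelihood_ratio(tr$x, p)),
                      n_levels = rule$n_levels)
  })
  out <- rbind(pieces[[1]], pieces[[2]])
  class(out) <- c("prediction_curve", "data.frame")
  out
}

# ---- dynamic criterion model --------------------------------------------

#' Prior beliefs for the dynamic criterion observer
#'
#' Normal-gamma beliefs about the generative distributions. For detection the
#' observer learns the signal mean `m` (conditional normal with pseudo-count
#' `kappa`) and the shared sensory precision `tau` (gamma with shape `alpha`,
#' rate `beta`); the noise mean is known to be 0 and the signal/noise
#' standard-deviation ratio is known. For discrimination the same structure
#' describes the half-separation of the two symmetric classes. `forgetting`
#' (in (0, 1]) exponentially discounts the pseudo-counts before each update,
#' keeping learning - and hence criterion movement - alive in a stationary
#' environment; 1 means no forgetting.
#'
#' @param m,kappa Prior mean and pseudo-count for the (signal) mean.
#' @param alpha,beta Gamma prior shape and rate for the precision.
#' @param forgetting Exponential discount applied to `kappa`, `alpha`, `beta`
#'   before each trial's update.
#' @return Object of class `"dynamic_belief"`.
#' @export
dynamic_belief <- function(m = 1.5, kappa = 1.5, alpha = 1.2, beta = 1.2,
                           forgetting = 0.8) {
  stopifnot(kappa > 0, alpha > 0, beta > 0,
            forgetting > 0, forgetting <= 1)
  structure(list(m = m, kappa = kappa, alpha = alpha, beta = beta,
                 forgetting = forgetting),
            class = "dynamic_belief")
}

#' One conjugate belief update of the dynamic criterion observer (detection)
#'
#' Responsibility-weighted normal-gamma update. With responsibility
#' \eqn{r = P(\text{signal} \mid x)} under the current plug-in beliefs, the
#' observed sample updates the signal-mean belief with fractional weight
#' \eqn{r} and the precision belief with the responsibility-weighted squared
#' residuals of the two hypotheses:
#' \deqn{\kappa' = \lambda\kappa + r, \quad
#'       m' = (\lambda\kappa\, m + r x) / \kappa'}
#' \deqn{\alpha' = \lambda\alpha + 1/2, \quad
#'       \beta' = \lambda\beta + \tfrac12\left[
#'         r \frac{\lambda\kappa}{\lambda\kappa + r}
#'           \frac{(x - m)^2}{\rho^2} + (1 - r)\, x^2 \right]}
#' where \eqn{\rho} is the known signal/noise standard-deviation ratio and
#' \eqn{\lambda} the forgetting factor.
#'
#' @param belief A [dynamic_belief()].
#' @param x Observed evidence sample.
#' @param r Responsibility of the signal hypothesis for `x` (in `[0, 1]`).
#' @param rho Known signal/noise standard-deviation ratio.
#' @return Updated `"dynamic_belief"`.
#' @export
dynamic_belief_update <- function(belief, x, r, rho = 1.5) {
  stopifnot(inherits(belief, "dynamic_belief"), r >= 0, r <= 1, rho >= 1)
  lam <- belief$forgetting
  kap <- lam * belief$kappa
  alpha <- lam * belief$alpha
  beta <- lam * belief$beta
  m_new <- (kap * belief$m + r * x) / (kap + r)
  beta_new <- beta + 0.5 * (r * (kap / (kap + r)) * (x - belief$m)^2 / rho^2 +
                              (1 - r) * x^2)
  dynamic_belief(m = m_new, kappa = kap + r, alpha = alpha + 0.5,
                 beta = beta_new, forgetting = lam)
}

# Decision criterion implied by plug-in beliefs (m, tau) for detection with
# known sd ratio rho: the upper root of LLR(x) = 0. For rho = 1 the LLR is
# affine and the criterion is m / 2.
dynamic_criterion_from_belief <- function(m, tau, rho) {
  if (!is.finite(tau) || tau <= 0) return(NA_real_)
  if (rho == 1) return(m / 2)
  a <- tau * (1 - 1 / rho^2) / 2
  b <- tau * m / rho^2
  d <- -tau * m^2 / (2 * rho^2) - log(rho)
  disc <- b^2 - 4 * a * d
  if (disc < 0) return(NA_real_)
  (-b + sqrt(disc)) / (2 * a)
}

#' Simulate the dynamic criterion observer
#'
#' Runs the trial-to-trial belief-updating observer with no feedback: on each
#' trial the evidence sample updates normal-gamma beliefs about the
#' generative distributions (responsibility-weighted, see
#' [dynamic_belief_update()]), the decision criterion is re-placed where the
#' posterior-predictive log likelihood ratio crosses zero, and the absolute
#' criterion shift caused by the trial is recorded against the trial's
#' confidence (proportional to |LLR|, binned response-conditionally into six
#' levels). In detection the criterion depends on both the learned signal
#' mean and the learned precision, producing a positive quadratic confidence
#' effect; in discrimination the problem is symmetric, the criterion stays at
#' the class midpoint, and the shift is identically zero.
#'
#' @param task `"detection"` or `"discrimination"`.
#' @param belief Prior beliefs, a [dynamic_belief()]; its `m` is the prior
#'   signal mean (detection) or half-separation (discrimination).
#' @param gen_params Generative [sdt_params()] for the environment; defaults
#'   match the static model's defaults for the task.
#' @param n_trials Number of trials.
#' @param seed Optional integer seed.
#' @return List with elements `trace` (one row per trial: `trial`,
#'   `stimulus`, `x`, `response`, `confidence`, `llr`, `criterion`,
#'   `abs_delta_c`, belief columns) and `curve` (prediction curve of the mean
#'   |criterion shift| per cell).
#' @export
dynamic_criterion_simulate <- function(task = c("detection", "discrimination"),
                                       belief = NULL,
                                       gen_params = NULL,
                                       n_trials = 1e4, seed = NULL) {
  task <- match.arg(task)
  if (is.null(gen_params))
    gen_params <- if (task == "detection") sdt_params("detection")
                  else sdt_params("discrimination", mu_signal = 0.75)
  stopifnot(gen_params$task == task)
  if (is.null(belief))
    belief <- dynamic_belief(m = if (task == "detection") gen_params$mu2
                                 else gen_params$mu2)
  if (!is.null(seed)) set.seed(seed)

  classes <- task_classes(task)
  responses <- task_responses(task)
  upper <- stats::runif(n_trials) < 0.5
  x <- ifelse(upper,
              stats::rnorm(n_trials, gen_params$mu2, gen_params$sigma2),
              stats::rnorm(n_trials, gen_params$mu1, gen_params$sigma1))

  llr <- crit <- dc <- m_tr <- tau_tr <- numeric(n_trials)
  resp <- logical(n_trials)

  if (task == "detection") {
    rho <- gen_params$sigma2 / gen_params$sigma1
    c_prev <- dynamic_criterion_from_belief(belief$m, belief$alpha / belief$beta, rho)
    for (t in seq_len(n_trials)) {
      tau <- belief$alpha / belief$beta
      if (!is.finite(tau) || tau <= 1e-10)
        stop("dynamic criterion observer diverged at trial ", t,
             ": precision belief collapsed (tau = ", signif(tau, 3), ")")
      s <- 1 / sqrt(tau)
      l <- stats::dnorm(x[t], belief$m, rho * s, log = TRUE) -
           stats::dnorm(x[t], 0, s, log = TRUE)
      llr[t] <- l
      resp[t] <- l > 0
      m_tr[t] <- belief$m; tau_tr[t] <- tau
      belief <- dynamic_belief_update(belief, x[t], stats::plogis(l), rho)
      c_new <- dynamic_criterion_from_belief(belief$m,
                                             belief$alpha / belief$beta, rho)
      if (!is.finite(c_new))
        stop("dynamic criterion observer diverged at trial ", t,
             ": no criterion solves posterior-predictive LLR = 0")
      crit[t] <- c_new
      dc[t] <- abs(c_new - c_prev)
      c_prev <- c_new
    }
  } else {
    # symmetric problem: the zero-LLR criterion is the class midpoint
    # whatever the beliefs, so the criterion never moves. Beliefs about the
    # half-separation and precision are still tracked.
    lam <- belief$forgetting
    for (t in seq_len(n_trials)) {
      tau <- belief$alpha / belief$beta
      if (!is.finite(tau) || tau <= 1e-10)
        stop("dynamic criterion observer diverged at trial ", t,
             ": precision belief collapsed (tau = ", signif(tau, 3), ")")
      s <- 1 / sqrt(tau)
      l <- stats::dnorm(x[t], belief$m, s, log = TRUE) -
           stats::dnorm(x[t], -belief$m, s, log = TRUE)
      llr[t] <- l
      resp[t] <- l > 0
      m_tr[t] <- belief$m; tau_tr[t] <- tau
      r <- stats::plogis(l)
      kap <- lam * belief$kappa
      beta_new <- lam * belief$beta +
        0.5 * (r * (x[t] - belief$m)^2 + (1 - r) * (x[t] + belief$m)^2)
      belief <- dynamic_belief(
        m = (kap * belief$m + (2 * r - 1) * x[t]) / (kap + 1),
        kappa = kap + 1,
        alpha = lam * belief$alpha + 0.5,
        beta = beta_new,
        forgetting = lam)
      crit[t] <- 0
      dc[t] <- 0
    }
  }

  resp_lab <- responses[resp + 1L]
  conf <- bin_confidence_by_response(abs(llr), resp_lab)
  trace <- data.frame(
    trial = seq_len(n_trials),
    stimulus = classes[upper + 1L],
    x = x, response = resp_lab, confidence = conf, llr = llr,
    criterion = crit, abs_delta_c = dc,
    belief_m = m_tr, belief_tau = tau_tr,
    stringsAsFactors = FALSE)
  curve <- curve_from_trials("dynamic_criterion", "abs_criterion_shift",
                             task, resp_lab, conf, dc)
  list(trace = trace, curve = curve)
}

#' Switch/stay contrast on a dynamic criterion trace
#'
#' Restricts to consecutive pairs of trials of the same stimulus category and
#' contrasts the absolute criterion shift on trials whose response differs
#' from the previous response (switch) against trials that repeat it (stay).
#' The shift attributed to a trial is the one produced by that trial's own
#' belief update (`abs_delta_c`): a switched response to an unchanged
#' stimulus category means the consecutive samples disagreed, which is
#' surprising under the current beliefs and drives a larger update. The
#' dynamic criterion model therefore predicts larger shifts on switch trials.
#'
#' @param trace Trace data frame from [dynamic_criterion_simulate()] (needs
#'   columns `stimulus`, `response`, `abs_delta_c`).
#' @return List with `switch_mean`, `stay_mean`, `difference`, and the pair
#'   counts `n_switch`, `n_stay`.
#' @export
dynamic_switch_stay_contrast <- function(trace) {
  stopifnot(all(c("stimulus", "response", "abs_delta_c") %in% names(trace)))
  n <- nrow(trace)
  if (n < 2) stop("need at least 2 trials")
  same_stim <- trace$stimulus[-1] == trace$stimulus[-n]
  idx <- which(same_stim) + 1L        # second trial of each qualifying pair
  if (length(idx) < 2)
    stop("fewer than 2 consecutive same-stimulus pairs in trace")
  is_switch <- trace$response[idx] != trace$response[idx - 1L]
  if (!any(is_switch))
    stop("no switch trials among same-stimulus pairs; contrast undefined")
  if (all(is_switch))
    stop("no stay trials among same-stimulus pairs; contrast undefined")
  sw <- mean(trace$abs_delta_c[idx[is_switch]])
  st <- mean(trace$abs_delta_c[idx[!is_switch]])
  list(switch_mean = sw, stay_mean = st, difference = sw - st,
       n_switch = sum(is_switch), n_stay = sum(!is_switch))
}

# ---- attention monitoring model -----------------------------------------

#' Parameters of the attention monitoring observer
#'
#' A latent binary attention state, resampled independently on every trial
#' with prior probability `p_on`, scales the precision of both stimulus-class
#' distributions: on-task evidence has precision `tau_on`, off-task evidence
#' `tau_off < tau_on` (wider distributions). Detection additionally widens
#' the signal distribution by the factor `sigma_ratio` in both states.
#'
#' @param mu Signal mean (detection) or half-separation (discrimination).
#' @param sigma_ratio Signal/noise standard-deviation ratio (detection only).
#' @param tau_on,tau_off Sensory precision in the on-/off-task states.
#' @param p_on Prior probability of being on task.
#' @return Object of class `"attention_params"`.
#' @export
attention_params <- function(mu = 1.5, sigma_ratio = 1.25,
                             tau_on = 1, tau_off = 0.4, p_on = 0.75) {
  stopifnot(tau_on > 0, tau_off > 0, p_on >= 0, p_on <= 1, sigma_ratio >= 1)
  if (tau_off > tau_on)
    stop("on-task precision must be at least off-task precision")
  if (tau_off == tau_on)
    warning("equal on/off-task precisions: attention state is unidentifiable")
  structure(list(mu = mu, sigma_ratio = sigma_ratio, tau_on = tau_on,
                 tau_off = tau_off, p_on = p_on),
            class = "attention_params")
}

# Class means and state-dependent sds for the attention observer.
attention_components <- function(params, task) {
  s_on <- 1 / sqrt(params$tau_on)
  s_off <- 1 / sqrt(params$tau_off)
  if (task == "detection") {
    list(mus = c(0, params$mu),
         sds = rbind(on = c(s_on, params$sigma_ratio * s_on),
                     off = c(s_off, params$sigma_ratio * s_off)))
  } else {
    list(mus = c(-params$mu, params$mu),
         sds = rbind(on = c(s_on, s_on), off = c(s_off, s_off)))
  }
}

#' Joint posterior over stimulus class and attention state
#'
#' For evidence value(s) `x`, returns the normalised four-cell posterior over
#' (class 1/2) x (on/off task) by Bayes' rule with equal class base rates and
#' prior `p_on` on the attentive state.
#'
#' @param x Numeric vector of evidence values.
#' @param params An [attention_params()].
#' @param task Task name.
#' @return Matrix with `length(x)` rows and columns `c1_on`, `c2_on`,
#'   `c1_off`, `c2_off`, rows summing to 1.
#' @export
attention_posterior <- function(x, params, task = "detection") {
  stopifnot(inherits(params, "attention_params"))
  comp <- attention_components(params, task)
  j <- cbind(
    c1_on = params$p_on * 0.5 * stats::dnorm(x, comp$mus[1], comp$sds["on", 1]),
    c2_on = params$p_on * 0.5 * stats::dnorm(x, comp$mus[2], comp$sds["on", 2]),
    c1_off = (1 - params$p_on) * 0.5 * stats::dnorm(x, comp$mus[1], comp$sds["off", 1]),
    c2_off = (1 - params$p_on) * 0.5 * stats::dnorm(x, comp$mus[2], comp$sds["off", 2]))
  j / rowSums(j)
}

#' Simulate the attention monitoring observer
#'
#' On each trial the attention state is drawn from its prior, the stimulus
#' class at equal base rates, and evidence from the corresponding component.
#' The observer computes the joint posterior over (class, attention state),
#' responds with the maximum-posterior class, and rates confidence in
#' proportion to the class log likelihood ratio - by default marginalising
#' over the attention state; `confidence = "conditional"` instead conditions
#' on the maximum-posterior attention state. The curve records the mean
#' posterior probability of being on task per (response, confidence) cell.
#'
#' @param task `"detection"` or `"discrimination"`.
#' @param params An [attention_params()]; the default discrimination
#'   half-separation is `mu / 2`.
#' @param n_trials Number of trials.
#' @param seed Optional integer seed.
#' @param confidence `"marginal"` (default) or `"conditional"`.
#' @return List with `trace` (per trial: `attention`, `stimulus`, `x`,
#'   `response`, `confidence`, `llr`, `p_on`) and `curve` (prediction curve
#'   of mean P(onTask)).
#' @export
attention_monitoring_simulate <- function(task = c("detection", "discrimination"),
                                          params = NULL,
                                          n_trials = 1e4, seed = NULL,
                                          confidence = c("marginal", "conditional")) {
  task <- match.arg(task)
  confidence <- match.arg(confidence)
  if (is.null(params))
    params <- if (task == "detection") attention_params()
              else attention_params(mu = 0.75)
  stopifnot(inherits(params, "attention_params"))
  if (!is.null(seed)) set.seed(seed)

  comp <- attention_components(params, task)
  on <- stats::runif(n_trials) < params$p_on
  upper <- stats::runif(n_trials) < 0.5
  sd_trial <- comp$sds[ifelse(on, "on", "off"), ][cbind(seq_len(n_trials),
                                                        upper + 1L)]
  x <- stats::rnorm(n_trials, comp$mus[upper + 1L], sd_trial)

  post <- attention_posterior(x, params, task)
  p2 <- post[, "c2_on"] + post[, "c2_off"]
  p_on_post <- post[, "c1_on"] + post[, "c2_on"]
  eps <- 1e-15
  if (confidence == "marginal") {
    llr <- stats::qlogis(pmin(pmax(p2, eps), 1 - eps))
  } else {
    a_map <- ifelse(p_on_post >= 0.5, "on", "off")
    sds <- comp$sds[a_map, , drop = FALSE]
    llr <- stats::dnorm(x, comp$mus[2], sds[, 2], log = TRUE) -
           stats::dnorm(x, comp$mus[1], sds[, 1], log = TRUE)
  }
  resp_upper <- llr > 0
  resp_lab <- task_responses(task)[resp_upper + 1L]
  conf <- bin_confidence_by_response(abs(llr), resp_lab)

  trace <- data.frame(
    trial = seq_len(n_trials),
    attention = ifelse(on, "on", "off"),
    stimulus = task_classes(task)[upper + 1L],
    x = x, response = resp_lab, confidence = conf, llr = llr,
    p_on = p_on_post, correct = upper == resp_upper,
    stringsAsFactors = FALSE)
  curve <- curve_from_trials("attention_monitoring", "p_on_task",
                             task, resp_lab, conf, p_on_post)
  list(trace = trace, curve = curve)
}
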