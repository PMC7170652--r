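# The three observer models and their response-by-confidence curves.

test_that("static curve: discrimination cell means match a quadrature oracle", {
  p <- sdt_params("discrimination", mu_signal = 0.75)
  rule <- confidence_rule_for(p)
  cur <- static_prediction(disc_params = p, n_trials = 1e5, seed = 42,
                           rule_disc = rule)
  cw <- cur[cur$task == "discrimination" & cur$response == "clockwise", ]
  cuts <- c(0, rule$thresholds, Inf)
  f_mix <- function(x) 0.5 * dnorm(x, p$mu1, p$sigma1) +
    0.5 * dnorm(x, p$mu2, p$sigma2)
  zs <- vapply(1:6, function(k) {
    lo <- p$criterion + cuts[k]; hi <- p$criterion + cuts[k + 1]
    num <- integrate(function(x) abs(log_likelihood_ratio(x, p)) * f_mix(x),
                     lo, hi, rel.tol = 1e-9)$value
    den <- integrate(f_mix, lo, hi, rel.tol = 1e-9)$value
    (cw$mean[cw$confidence == k] - num / den) / cw$se[cw$confidence == k]
  }, numeric(1))
  expect_lt(max(abs(zs)), 3.5)     # per-cell agreement over 6 joint cells
  expect_lt(mean(abs(zs)), 1.5)
})

test_that("static curve: symmetric discrimination responses are exchangeable", {
  cur <- static_prediction(n_trials = 5e4, seed = 7)
  cw <- cur[cur$task == "discrimination" & cur$response == "clockwise", ]
  acw <- cur[cur$task == "discrimination" & cur$response == "anticlockwise", ]
  z <- (cw$mean - acw$mean) / sqrt(cw$se^2 + acw$se^2)
  expect_lt(max(abs(z)), 3.5)
})

test_that("static detection quadratic vanishes under equal variances and grows with the sd ratio", {
  # equal variance removes the unequal-variance signature: the detection-yes
  # quadratic falls to the discretisation level of the linear discrimination
  # curve (a few percent of the linear term), far below its uv value
  quad_of <- function(sigma_s, seed) {
    dp <- sdt_params("detection", mu_signal = 1.5, sigma_signal = sigma_s)
    cur <- static_prediction(det_params = dp, n_trials = 4e4, seed = seed)
    cf <- curve_poly_fit(cur)
    yes <- cf[cf$task == "detection" & cf$response == "yes", ]
    c(quad = yes$estimate[yes$term == "quadratic"],
      lin = yes$estimate[yes$term == "linear"])
  }
  ev <- quad_of(1.0, 5)
  uv <- quad_of(1.5, 5)
  expect_lt(abs(ev["quad"]), 0.12 * abs(ev["lin"]))
  expect_gt(uv["quad"], 4 * abs(ev["quad"]))
  # monotone in the sd ratio on a 3-point grid
  qs <- vapply(c(1.2, 1.5, 1.8), function(s) quad_of(s, 5)["quad"],
               numeric(1))
  expect_true(all(diff(qs) > 0))
})

test_that("Monte-Carlo cell SEs shrink like 1/sqrt(n)", {
  a <- static_prediction(n_trials = 5e3, seed = 3)
  b <- static_prediction(n_trials = 2e4, seed = 3)
  keep <- a$n > 30 & b$n > 30
  ratio <- b$se[keep] / a$se[keep]          # expect 1/2 at 4x trials
  expect_equal(mean(ratio), 0.5, tolerance = 0.2)
})

test_that("dynamic belief update matches the conjugate closed form", {
  b <- dynamic_belief(m = 1.2, kappa = 4, alpha = 3, beta = 2.5,
                      forgetting = 0.9)
  x <- 0.8; r <- 0.3; rho <- 1.5
  u <- dynamic_belief_update(b, x, r, rho)
  # hand-computed one-step normal-gamma update with discounting
  kap <- 0.9 * 4
  expect_equal(u$kappa, kap + r)
  expect_equal(u$m, (kap * 1.2 + r * x) / (kap + r))
  expect_equal(u$alpha, 0.9 * 3 + 0.5)
  expect_equal(u$beta, 0.9 * 2.5 +
                 0.5 * (r * (kap / (kap + r)) * (x - 1.2)^2 / rho^2 +
                          (1 - r) * x^2))
})

test_that("a dogmatic prior freezes the criterion", {
  b <- dynamic_belief(m = 1.5, kappa = 1e12, alpha = 1e12, beta = 1e12,
                      forgetting = 1)
  sim <- dynamic_criterion_simulate("detection", belief = b, n_trials = 300,
                                    seed = 8)
  expect_lt(max(sim$trace$abs_delta_c), 1e-6)
})

test_that("dynamic criterion: discrimination shifts are exactly zero by symmetry", {
  sim <- dynamic_criterion_simulate("discrimination", n_trials = 3000,
                                    seed = 9)
  expect_true(all(sim$trace$abs_delta_c == 0))
  cf <- curve_poly_fit(sim$curve)
  expect_equal(cf$estimate[cf$term == "quadratic"], c(0, 0))
})

test_that("dynamic criterion: detection curves carry a positive quadratic", {
  sim <- dynamic_criterion_simulate("detection", n_trials = 3e4, seed = 10)
  cf <- curve_poly_fit(sim$curve)
  quad <- cf[cf$term == "quadratic", ]
  expect_true(all(quad$estimate > 0))
  pooled <- mean(quad$estimate)
  pooled_se <- sqrt(sum(quad$mc_se^2)) / 2
  expect_gt(pooled, 3 * pooled_se)
})

test_that("switch/stay contrast: hand-built trace and degenerate inputs", {
  tr <- data.frame(
    stimulus = c("present", "present", "present", "absent", "absent", "absent"),
    response = c("yes", "no", "no", "no", "yes", "yes"),
    abs_delta_c = c(0.1, 0.4, 0.2, 0.3, 0.5, 0.1),
    stringsAsFactors = FALSE)
  # qualifying pairs (same stimulus): trials 2, 3, 5, 6
  # switch at 2 (yes->no) and 5 (no->yes); stay at 3 and 6
  res <- dynamic_switch_stay_contrast(tr)
  expect_equal(res$switch_mean, mean(c(0.4, 0.5)))
  expect_equal(res$stay_mean, mean(c(0.2, 0.1)))
  expect_equal(res$difference, 0.45 - 0.15)
  expect_equal(res$n_switch, 2L)
  # all-identical responses: no switch trials -> error naming the problem
  tr2 <- tr; tr2$response <- "yes"
  expect_error(dynamic_switch_stay_contrast(tr2), "no switch trials")
  expect_error(dynamic_switch_stay_contrast(tr[1:2, ]), "fewer than 2")
})

test_that("dynamic criterion: switch trials shift the criterion more than stay trials", {
  sim <- dynamic_criterion_simulate("detection", n_trials = 1e4, seed = 12)
  res <- dynamic_switch_stay_contrast(sim$trace)
  expect_gt(res$difference, 0)
})

test_that("attention posterior is a normalised four-cell Bayes table", {
  ap <- attention_params(mu = 1.5, sigma_ratio = 1.25, tau_on = 1,
                         tau_off = 0.4, p_on = 0.75)
  x <- 0.9
  post <- attention_posterior(x, ap, "detection")
  # hand enumeration of the four joint states
  s_on <- 1; s_off <- 1 / sqrt(0.4)
  j <- c(0.75 * 0.5 * dnorm(x, 0, s_on),
         0.75 * 0.5 * dnorm(x, 1.5, 1.25 * s_on),
         0.25 * 0.5 * dnorm(x, 0, s_off),
         0.25 * 0.5 * dnorm(x, 1.5, 1.25 * s_off))
  expect_equal(as.numeric(post), j / sum(j), tolerance = 1e-12)
  # law of total probability on a grid
  g <- attention_posterior(seq(-4, 6, by = 0.5), ap, "detection")
  expect_true(all(abs(rowSums(g) - 1) < 1e-12))
  expect_true(all(g >= 0 & g <= 1))
})

test_that("attention model degenerate cases: certain prior and equal precisions", {
  expect_warning(attention_params(tau_on = 1, tau_off = 1), "unidentifiable")
  expect_error(attention_params(tau_on = 0.3, tau_off = 0.4), "at least")
  ap <- attention_params(p_on = 1)
  sim <- attention_monitoring_simulate("detection", params = ap,
                                       n_trials = 2000, seed = 13)
  expect_true(all(abs(sim$trace$p_on - 1) < 1e-12))
  expect_true(all(abs(sim$curve$mean[sim$curve$n > 0] - 1) < 1e-12))
})

test_that("attention model: quadratic confidence profile and yes/no interaction", {
  sim <- attention_monitoring_simulate("detection", n_trials = 5e4, seed = 14)
  cf <- curve_poly_fit(sim$curve)
  quad <- cf[cf$term == "quadratic", ]
  expect_true(all(abs(quad$estimate) > 3 * quad$mc_se))
  lin <- cf[cf$term == "linear", ]
  z_int <- diff(lin$estimate) / sqrt(sum(lin$mc_se^2))
  expect_gt(abs(z_int), 3)
  # the model predicts a quadratic effect in discrimination too
  simd <- attention_monitoring_simulate("discrimination", n_trials = 5e4,
                                        seed = 15)
  cfd <- curve_poly_fit(simd$curve)
  quadd <- cfd[cfd$term == "quadratic", ]
  expect_true(all(abs(quadd$estimate) > 3 * quadd$mc_se))
})

test_that("attention model: symmetric discrimination responses are exchangeable", {
  sim <- attention_monitoring_simulate("discrimination", n_trials = 4e4,
                                       seed = 16)
  cur <- sim$curve
  cw <- cur[cur$response == "clockwise" & cur$n > 0, ]
  acw <- cur[cur$response == "anticlockwise" & cur$n > 0, ]
  z <- (cw$mean - acw$mean) / sqrt(cw$se^2 + acw$se^2)
  expect_lt(max(abs(z)), 3.5)
})

test_that("conditional-confidence variant runs and differs from marginal", {
  a <- attention_monitoring_simulate("detection", n_trials = 2000, seed = 17,
                                     confidence = "marginal")
  b <- attention_monitoring_simulate("detection", n_trials = 2000, seed = 17,
                                     confidence = "conditional")
  expect_false(identical(a$trace$confidence, b$trace$confidence))
  expect_true(all(b$trace$confidence %in% 1:6))
})
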