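# Polynomial profile fits, group inference, contrast battery, JZS Bayes
# factors.

test_that("polynomial fit recovers exact profiles and matches the normal-equation oracle", {
  f <- fit_confidence_polynomial((1:6 - 3.5)^2)
  expect_equal(c(f$intercept, f$linear, f$quadratic), c(0, 0, 1),
               tolerance = 1e-12)
  f <- fit_confidence_polynomial(rep(4.2, 6))
  expect_equal(c(f$intercept, f$linear, f$quadratic), c(4.2, 0, 0),
               tolerance = 1e-12)
  v <- c(3.0, 1.4, 0.6, 0.6, 1.4, 3.0)
  f <- fit_confidence_polynomial(v)
  o <- oracle_poly_fit(v)
  expect_equal(c(f$intercept, f$linear, f$quadratic), unname(o),
               tolerance = 1e-12)
  # symmetric profile has no linear component
  expect_equal(f$linear, 0, tolerance = 1e-12)
})

test_that("polynomial fit: equivariance and masked levels", {
  set.seed(1)
  v <- rnorm(6)
  f0 <- fit_confidence_polynomial(v)
  f_shift <- fit_confidence_polynomial(v + 7)
  expect_equal(f_shift$intercept, f0$intercept + 7)
  expect_equal(f_shift$linear, f0$linear)
  expect_equal(f_shift$quadratic, f0$quadratic)
  f_scale <- fit_confidence_polynomial(3 * v)
  expect_equal(c(f_scale$intercept, f_scale$linear, f_scale$quadratic),
               3 * c(f0$intercept, f0$linear, f0$quadratic))
  # masked levels are dropped; under 3 levels the profile is skipped
  v2 <- v; v2[c(1, 6)] <- NA
  expect_equal(fit_confidence_polynomial(v2)$n_levels, 4)
  v3 <- v; v3[1:4] <- NA
  expect_warning(f3 <- fit_confidence_polynomial(v3), "fewer than 3")
  expect_false(f3$ok)
  expect_true(is.na(f3$quadratic))
})

test_that("package fit agrees with the fast matrix fitter used in simulations", {
  set.seed(2)
  v <- rnorm(6, sd = 0.7)
  f <- fit_confidence_polynomial(v)
  code <- 1:6 - 3.5
  W <- solve(crossprod(cbind(1, code, code^2))) %*% t(cbind(1, code, code^2))
  expect_equal(c(f$intercept, f$linear, f$quadratic),
               unname(drop(W %*% v)), tolerance = 1e-12)
})

test_that("group inference implements the one-sample t identity", {
  # n subjects with contrast mean/sd ratio 0.515 give t = 0.515 * sqrt(35)
  set.seed(3)
  vals <- rnorm(35)
  vals <- (vals - mean(vals)) / sd(vals)      # mean 0, sd 1
  vals <- vals * 1 + 0.515                    # mean 0.515, sd 1
  coefs <- data.frame(subject = sprintf("s%02d", 1:35), task = "detection",
                      response = "yes", intercept = 0, linear = 0,
                      quadratic = vals, n_levels = 6L,
                      stringsAsFactors = FALSE)
  w <- data.frame(task = "detection", response = "yes", weight = 1)
  g <- group_inference(coefs, w, term = "quadratic", contrast = "t_identity")
  expect_equal(g$t, 0.515 * sqrt(35), tolerance = 1e-10)
  expect_equal(g$df, 34)
  expect_equal(g$cohens_d, g$t / sqrt(35), tolerance = 1e-10)
  expect_equal(g$p, 2 * pt(-abs(g$t), 34))
  # cross-check the whole t-test against stats::t.test
  tt <- t.test(vals)
  expect_equal(g$t, unname(tt$statistic))
  expect_equal(g$p, tt$p.value)
  # degenerate variance errors; permutation of subject labels is invariant
  coefs0 <- coefs; coefs0$quadratic <- 1
  expect_error(group_inference(coefs0, w), "degenerate variance")
  coefs_p <- coefs[sample(nrow(coefs)), ]
  gp <- group_inference(coefs_p, w, term = "quadratic")
  expect_equal(gp$t, g$t)
})

test_that("all-zero contrasts give t = 0 and bookkeeping is per contrast", {
  set.seed(4)
  coefs <- fast_null_coefs(12, 0.5)
  # identical generative coefficients everywhere: difference contrasts ~ 0
  bat <- standard_contrast_battery(coefs, bayes = FALSE)
  expect_equal(nrow(bat), 8)
  expect_true(all(bat$df[!bat$skipped] == 11))
  # missing cells propagate to named skipped contrasts
  coefs2 <- coefs[coefs$response != "no", ]
  bat2 <- standard_contrast_battery(coefs2, bayes = FALSE)
  expect_true(bat2$skipped[bat2$contrast == "quadratic_task_diff"])
  expect_false(bat2$skipped[bat2$contrast == "quadratic_discrimination"])
})

test_that("parameter recovery: mean fitted coefficients match generative values", {
  pr <- generate_roi_profiles(noise_sd = 1.0, n_subjects = 35, seed = 5)
  cf <- fit_profile_table(pr)
  truth <- default_profile_coefs()
  for (i in seq_len(nrow(truth))) {
    sub <- cf[cf$task == truth$task[i] & cf$response == truth$response[i], ]
    for (term in c("linear", "quadratic")) {
      b <- if (term == "linear") truth$b1[i] else truth$b2[i]
      se <- sd(sub[[term]]) / sqrt(nrow(sub))
      expect_lt(abs(mean(sub[[term]]) - b), 3 * se + 1e-8)
    }
  }
})

test_that("group-level power and sign for the designed effects", {
  # detection-vs-discrimination quadratic contrast: high power at the
  # designed effect, correct sign for the yes/no linear difference
  hits_quad <- hits_lin <- 0
  n_sims <- 60
  set.seed(6)
  for (s in seq_len(n_sims)) {
    pr <- generate_roi_profiles(noise_sd = 0.2, n_subjects = 35)
    cf <- fit_profile_table(pr)
    bat <- standard_contrast_battery(cf, bayes = FALSE)
    q <- bat[bat$contrast == "quadratic_task_diff", ]
    l <- bat[bat$contrast == "linear_yes_vs_no", ]
    hits_quad <- hits_quad + (q$p < 0.05 && q$t > 0)
    hits_lin <- hits_lin + (l$p < 0.05 && l$t > 0)  # yes less negative
  }
  expect_gte(hits_quad / n_sims, 0.9)
  expect_gte(hits_lin / n_sims, 0.9)
})

test_that("JZS Bayes factor: null evidence, monotonicity, and sample-size behaviour", {
  expect_gt(jzs_bayes_factor(0, 35), 1)
  bfs <- vapply(seq(0, 5, by = 0.5), jzs_bayes_factor, numeric(1), n = 35)
  expect_true(all(diff(bfs) < 0))
  # stronger null evidence with more data at t = 0
  bf_n <- vapply(c(5, 10, 20, 40, 80), jzs_bayes_factor, numeric(1), t = 0)
  expect_true(all(diff(bf_n) > 0))
})

test_that("JZS Bayes factor matches an independent quadrature oracle", {
  for (tt in c(0.3, 2.0, 3.5)) {
    o1 <- oracle_jzs_bf01(tt, 35, n_grid = 20000)
    o2 <- oracle_jzs_bf01(tt, 35, n_grid = 40000)
    expect_equal(o1, o2, tolerance = 1e-6)          # oracle converged
    expect_equal(jzs_bayes_factor(tt, 35), o2, tolerance = 1e-4)
  }
})

test_that("JZS Bayes factors reproduce published values for matched t statistics", {
  # one-sample JZS BF01 at n = 35, unit prior scale, as printed for the
  # behavioural null results (t, BF01) pairs
  published <- rbind(c(0.90, 5.15), c(0.30, 7.29), c(0.39, 7.07),
                     c(0.22, 7.43), c(0.06, 7.6))
  for (i in seq_len(nrow(published))) {
    expect_equal(jzs_bayes_factor(published[i, 1], 35), published[i, 2],
                 tolerance = 0.005)
  }
})
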