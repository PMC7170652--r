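# Type-2 ROC / AUROC2, meta-d', exclusion rules.

counts_from_vectors <- function(correct_counts, incorrect_counts,
                                response = "yes") {
  out <- data.frame(response = response, confidence = 1:6,
                    n_correct = correct_counts,
                    n_incorrect = incorrect_counts,
                    stringsAsFactors = FALSE)
  class(out) <- c("type2_counts", "data.frame")
  out
}

test_that("type-2 ROC endpoints, monotonicity and degenerate errors", {
  cc <- counts_from_vectors(rep(10, 6), rep(5, 6))
  roc <- type2_roc(cc, "yes")
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  # identical distributions: all points on the diagonal
  expect_equal(roc$fpr, roc$tpr)
  # perfect separation passes through (0, 1)
  cc <- counts_from_vectors(c(0, 0, 0, 0, 0, 6), c(4, 0, 0, 0, 0, 0))
  roc <- type2_roc(cc, "yes")
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_error(type2_roc(counts_from_vectors(rep(1, 6), rep(0, 6)), "yes"),
               "no incorrect")
  expect_error(type2_roc(counts_from_vectors(rep(0, 6), rep(1, 6)), "yes"),
               "no correct")
})

test_that("AUROC2 equals the cumulative-sum trapezoid oracle", {
  expect_identical(auroc2(counts_from_vectors(rep(10, 6), rep(5, 6)), "yes"),
                   0.5)
  expect_identical(
    auroc2(counts_from_vectors(c(0, 0, 0, 10, 10, 10),
                               c(10, 10, 10, 0, 0, 0)), "yes"), 1)
  corr <- c(0, 0, 1, 0, 2, 3); inc <- c(2, 1, 1, 0, 0, 0)
  expect_equal(auroc2(counts_from_vectors(corr, inc), "yes"),
               oracle_auroc2(corr, inc))
  # invariance to a strictly monotone relabelling of the confidence scale
  set.seed(4)
  n <- 400
  conf <- sample(1:6, n, replace = TRUE, prob = c(1, 2, 3, 3, 2, 1))
  correct <- runif(n) < plogis(conf - 3)
  a1 <- auroc2(type2_counts(rep("yes", n), correct, conf), "yes")
  a2 <- auroc2(type2_counts(rep("yes", n), correct,
                            c(1L, 3L, 4L, 7L, 8L, 12L)[conf],
                            n_levels = 12L), "yes")
  expect_equal(a2, a1)
})

test_that("yes-response metacognitive sensitivity exceeds no under unequal variance", {
  p <- sdt_params("detection", mu_signal = 1.5, sigma_signal = 1.5)
  tr <- simulate_sdt_trials(1e5, p, seed = 6)
  a <- auroc2_from_trials(tr)
  expect_gt(a$auroc2[a$response == "yes"], a$auroc2[a$response == "no"])
  # both sides remain above chance
  expect_true(all(a$auroc2 > 0.5))
})

test_that("meta-d' recovers the generative d' for an ideal observer and collapses when ratings are shuffled", {
  set.seed(7)
  p <- sdt_params("detection", mu_signal = 1.5, sigma_signal = 1,
                  criterion = 0.75)
  tr <- simulate_sdt_trials(5e4, p)
  fit <- meta_dprime(response_confidence_counts(tr, "detection"))
  expect_equal(fit$meta_d, fit$dprime, tolerance = 0.07)
  expect_equal(fit$m_ratio, 1, tolerance = 0.05)
  tr$confidence <- ave(tr$confidence, tr$response, FUN = sample)
  fit0 <- meta_dprime(response_confidence_counts(tr, "detection"))
  expect_lt(abs(fit0$m_ratio), 0.08)
})

test_that("meta-d' equals a two-stage grid-search oracle on a small fixture", {
  # 2 x 2 x 2 fixture: 3 free parameters, searchable by brute force
  # [stimulus, response, confidence]:
  # S1: r1 = (38, 12), r2 = (9, 5);  S2: r1 = (14, 6), r2 = (21, 33)
  counts <- array(c(38, 14, 9, 21, 12, 6, 5, 33), dim = c(2, 2, 2))
  fit <- meta_dprime(counts)
  # independent likelihood (plain pnorm arithmetic on padded counts)
  cts <- counts + 1 / 4
  hr <- sum(cts[2, 2, ]) / sum(cts[2, , ])
  fa <- sum(cts[1, 2, ]) / sum(cts[1, , ])
  c_rel <- (-(qnorm(hr) + qnorm(fa)) / 2) / (qnorm(hr) - qnorm(fa))
  loglik <- function(md, dlo, dhi) {
    mc <- c_rel * md
    mus <- c(-md / 2, md / 2)
    ll <- 0
    for (s in 1:2) {
      p_lo <- diff(pnorm(c(-Inf, mc - dlo, mc), mus[s]))
      p_hi <- diff(pnorm(c(mc, mc + dhi, Inf), mus[s]))
      pr1 <- rev(p_lo) / sum(p_lo)
      pr2 <- p_hi / sum(p_hi)
      ll <- ll + sum(cts[s, 1, ] * log(pr1)) + sum(cts[s, 2, ] * log(pr2))
    }
    ll
  }
  grid_best <- function(mds, dlos, dhis) {
    best <- c(-Inf, NA, NA, NA)
    for (md in mds) for (dlo in dlos) {
      lls <- vapply(dhis, function(dh) loglik(md, dlo, dh), numeric(1))
      k <- which.max(lls)
      if (lls[k] > best[1]) best <- c(lls[k], md, dlo, dhis[k])
    }
    best
  }
  b1 <- grid_best(seq(0.2, 2.5, by = 0.05), seq(0.05, 2, by = 0.05),
                  seq(0.05, 2, by = 0.05))
  b2 <- grid_best(seq(b1[2] - 0.06, b1[2] + 0.06, by = 0.002),
                  seq(max(b1[3] - 0.06, 0.001), b1[3] + 0.06, by = 0.002),
                  seq(max(b1[4] - 0.06, 0.001), b1[4] + 0.06, by = 0.002))
  b3 <- grid_best(seq(b2[2] - 0.003, b2[2] + 0.003, by = 2e-4),
                  seq(max(b2[3] - 0.003, 1e-4), b2[3] + 0.003, by = 2e-4),
                  seq(max(b2[4] - 0.003, 1e-4), b2[4] + 0.003, by = 2e-4))
  expect_equal(fit$meta_d, b3[2], tolerance = 1e-3)
})

test_that("exclusion rules are pinned at the quoted boundaries", {
  # 400 trials; exactly 20% missing -> included, 21% -> excluded
  t20 <- make_trials(400, missing = 80)
  expect_true(apply_exclusion(t20)$subject$included)
  t21 <- make_trials(400, missing = 84)
  rep21 <- apply_exclusion(t21)
  expect_false(rep21$subject$included)
  expect_match(rep21$subject$rules, "missing_gt_20pct")

  # accuracy: exactly 60% included, below excluded
  t60 <- make_trials(400, correct = rep(c(TRUE, TRUE, TRUE, FALSE, FALSE),
                                        80))
  expect_true(apply_exclusion(t60)$subject$included)
  t59 <- make_trials(400, correct = c(rep(TRUE, 236), rep(FALSE, 164)))
  rep59 <- apply_exclusion(t59)
  expect_false(rep59$subject$included)
  expect_match(rep59$subject$rules, "accuracy_lt_60pct")

  # response bias: exactly 75% same response included, more excluded
  t75 <- make_trials(400, response = rep(c("yes", "yes", "yes", "no"), 100))
  expect_true(apply_exclusion(t75)$subject$included)
  t76 <- make_trials(400, response = c(rep("yes", 304), rep("no", 96)))
  rep76 <- apply_exclusion(t76)
  expect_false(rep76$subject$included)
  expect_match(rep76$subject$rules, "response_bias_gt_75pct")

  # subject confidence rule: more than 80% at one level
  t80 <- make_trials(400, confidence = rep(c(6, 6, 6, 6, 1), 80))
  expect_true(apply_exclusion(t80)$subject$included)
  t81 <- make_trials(400, confidence = c(rep(6, 324), rep(1:5, length.out = 76)))
  rep81 <- apply_exclusion(t81)
  expect_false(rep81$subject$included)
  expect_match(rep81$subject$rules, "confidence_gt_80pct")

  # run confidence rule: 96% of a run's trials at one level -> run excluded,
  # exactly 95% -> usable
  t95 <- make_trials(400, runs = 2, confidence = conf_at_run_share(share = 0.95))
  r95 <- apply_exclusion(t95)
  expect_false(any(grepl("confidence_gt_95pct", r95$runs$rules)))
  t96 <- make_trials(400, runs = 2, confidence = conf_at_run_share(share = 0.96))
  r96 <- apply_exclusion(t96)
  expect_true(all(grepl("confidence_gt_95pct", r96$runs$rules)))

  # run response bias: exactly 80% usable, 81% excluded
  t80b <- make_trials(400, runs = 1,
                      response = rep(c("yes", "yes", "yes", "yes", "no"), 80))
  r <- apply_exclusion(t80b)
  expect_false(grepl("response_bias_gt_80pct", r$runs$rules[1]))
  t81b <- make_trials(400, runs = 1,
                      response = c(rep("yes", 324), rep("no", 76)))
  r <- apply_exclusion(t81b)
  expect_match(r$runs$rules[1], "response_bias_gt_80pct")

  # excluded subject makes all runs unusable
  expect_true(all(!apply_exclusion(t21)$runs$usable))
  expect_true(all(grepl("subject_excluded", apply_exclusion(t21)$runs$rules)))

  # motion flags enter externally
  tm <- make_trials(400, runs = 5)
  mf <- data.frame(run = 1:5, flag = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  rm_ <- apply_exclusion(tm, motion_flags = mf)
  expect_false(rm_$subject$included)
  expect_match(rm_$subject$rules, "motion")
  expect_error(apply_exclusion(make_trials(4)[0, ]), "empty")
})
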