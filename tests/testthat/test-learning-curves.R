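test_that("curve evaluation matches the analytic forms and their landmarks", {
  p <- c(13.25, -0.39, 10.28)
  # zero at the x-intercept, 63.2% of A one time constant later
  expect_equal(lc_predict("exponential", p, x = -0.39), 0)
  expect_equal(lc_predict("exponential", p, x = -0.39 + 10.28),
               13.25 * (1 - exp(-1)), tolerance = 1e-12)
  # saturation at A for large x
  expect_equal(lc_predict("exponential", p, x = 1e4), 13.25, tolerance = 1e-9)
  expect_lt(abs(lc_predict("exponential", p, x = -0.39 + 20 * 10.28) - 13.25),
            1e-6 * 13.25)
  # strictly increasing when A > 0, tau > 0
  y <- lc_predict("exponential", p, x = 1:36)
  expect_true(all(diff(y) > 0))
  expect_error(lc_predict("exponential", c(10, 0, -2), 1:5), "tau")
  expect_equal(lc_predict("power", c(3.2, -0.34, 0.41), 1),
               3.2 * (1.34)^0.41)
  expect_error(lc_predict("power", c(1, 5, 0.5), x = 1:10), "domain")
  expect_equal(lc_predict("linear", c(0.27, -0.5, 4.74), 2),
               0.27 * 2.5 + 4.74)
})

test_that("the Gaussian likelihood matches closed forms and is monotone in residuals", {
  x <- 1:10
  y <- lc_predict("exponential", c(8, 0, 3), x)
  s <- 1.7
  expect_equal(neg_log_likelihood(c(8, 0, 3, s), x, y),
               10 * log(s * sqrt(2 * pi)), tolerance = 1e-12)
  # 3-point case against explicit density arithmetic
  x3 <- c(1, 2, 3); y3 <- c(0.5, 2.1, 2.0); p3 <- c(3, 0, 2); s3 <- 0.8
  mu3 <- 3 * (1 - exp(-x3 / 2))
  manual <- 3 * (0.5 * log(2 * pi * s3^2)) + sum((y3 - mu3)^2) / (2 * s3^2)
  expect_equal(neg_log_likelihood(c(p3, s3), x3, y3), manual,
               tolerance = 1e-10)
  # doubled residuals at fixed sigma increase the NLL
  y_far <- mu3 + 2 * (y3 - mu3)
  expect_gt(neg_log_likelihood(c(p3, s3), x3, y_far),
            neg_log_likelihood(c(p3, s3), x3, y3))
  # missing points are skipped
  expect_equal(neg_log_likelihood(c(8, 0, 3, s), x, c(y[1:9], NA)),
               9 * log(s * sqrt(2 * pi)), tolerance = 1e-12)
  # domain violations return a large finite penalty, with a warning
  expect_warning(v <- neg_log_likelihood(c(1, 5, 0.5, 1), 1:10,
                                         rep(1, 10), form = "power"),
                 "penalty")
  expect_true(is.finite(v) && v >= 1e9)
})

test_that("information criteria implement their defining formulas", {
  expect_equal(aicc(4, 36, -100), 2 * 4 * 36 / (36 - 4 - 1) + 200,
               tolerance = 1e-12)
  expect_equal(aicc(4, 36, -100), 209.2903226, tolerance = 1e-7)
  expect_equal(bic(4, 36, -100), 4 * log(36) + 200, tolerance = 1e-12)
  expect_equal(bic(4, 36, -100), 214.3340758, tolerance = 1e-7)
  # random (k, n, logL) triples against independently typed arithmetic
  cases <- withr::with_seed(10, data.frame(
    k = sample(2:6, 25, TRUE), n = sample(10:500, 25), logL = rnorm(25, 0, 50)
  ))
  for (i in seq_len(nrow(cases))) {
    k <- cases$k[i]; n <- cases$n[i]; L <- cases$logL[i]
    expect_equal(aicc(k, n, L), 2 * k * n / (n - k - 1) - 2 * L,
                 tolerance = 1e-12)
    expect_equal(bic(k, n, L), k * log(n) - 2 * L, tolerance = 1e-12)
  }
  # AICc penalty tends to the plain AIC penalty 2k as n grows
  expect_equal(2 * 4 * 1e9 / (1e9 - 5), 8, tolerance = 1e-6)
  expect_error(aicc(4, 5, -10), "n > k \\+ 1")
})

test_that("Bayes factors reproduce published comparisons and are antisymmetric", {
  # published group BIC values: exponential 12508, power 12511, linear 12516
  expect_equal(bayes_factor(12508, 12516), exp(4), tolerance = 1e-12)
  expect_equal(round(bayes_factor(12508, 12516), 1), 54.6)
  expect_equal(round(bayes_factor(12511, 12516), 1), 12.2)
  expect_equal(round(bayes_factor(12508, 12511), 1), 4.5)
  expect_equal(bayes_factor(100, 100), 1)
  for (pair in list(c(12508, 12516), c(3.2, -1.5))) {
    expect_equal(bayes_factor(pair[1], pair[2]) * bayes_factor(pair[2], pair[1]),
                 1, tolerance = 1e-12)
  }
  expect_equal(interpret_bayes_factor(c(54.6, 4.5, 12.2, 1, 0.3, 200, 2)),
               c("Strongly supports the M1", "Positively supports the M1",
                 "Positively supports the M1", "Substantially supports the M0",
                 "Substantially supports the M0", "Very strongly supports the M1",
                 "Not worth more than a bare mention"))
  expect_equal(interpret_delta_aicc(c(7, 4, 1, 11)),
               c("Strongly supports the M1", "Positively supports the M1",
                 "Substantially supports the M0", "Very strongly supports the M1"))
})

test_that("bounded MLE recovers exact parameters from noiseless data", {
  y <- lc_predict("exponential", c(10, 0, 5), 1:36)
  f <- fit_mle(1:36, y, "exponential", scope = "group")
  expect_true(f$converged)
  expect_equal(f$w1, 10, tolerance = 1e-4)
  expect_equal(f$w2, 0, tolerance = 1e-4)
  expect_equal(f$w3, 5, tolerance = 1e-4)
  expect_equal(f$AICc, aicc(4, 36, f$logL), tolerance = 1e-12)
  expect_equal(f$BIC, bic(4, 36, f$logL), tolerance = 1e-12)

  # linear data: slope w1 is identified (offset is split across w2/w3)
  ylin <- 0.27 * (1:36) + 4.0
  flin <- fit_mle(1:36, ylin, "linear")
  expect_equal(flin$w1, 0.27, tolerance = 1e-3)
  expect_equal(0.27 * (-flin$w2) + flin$w3, 4.0, tolerance = 1e-3)
  expect_error(fit_mle(1:4, rep(1, 4), "exponential"), "at least 5")
})

test_that("stochastic recovery of the group curve is accurate at study-scale noise", {
  # 200 simulated group series; median |A_hat - A| below 10% of A
  err <- sapply(1:200, function(i) {
    g <- simulate_group_series(13.25, -0.39, 10.28, noise_sd = 2,
                               seed = 5000 + i)
    abs(fit_mle(g$block, g$score, "exponential", seed = i)$w1 - 13.25)
  })
  expect_lt(median(err), 0.1 * 13.25)
})

test_that("a larger sigma bound never decreases the maximized likelihood", {
  g <- simulate_group_series(13.25, -0.39, 10.28, noise_sd = 2, seed = 99)
  b_small <- default_bounds("exponential", "group")
  b_small$upper[4] <- 1 # sigma capped well below the true noise
  b_wide <- default_bounds("exponential", "group")
  f_small <- fit_mle(g$block, g$score, "exponential", bounds = b_small)
  f_wide <- fit_mle(g$block, g$score, "exponential", bounds = b_wide)
  expect_gte(f_wide$logL, f_small$logL - 1e-8)
})

test_that("model comparison orders pairs, flags mismatched data, and self-compares to unity", {
  g <- simulate_group_series(13.25, -0.39, 10.28, noise_sd = 2, seed = 7)
  fits <- fit_group_curve(g, seed = 2)
  cmp <- suppressWarnings(compare_models(fits))
  expect_equal(nrow(cmp), 6)
  # delta AICc additivity over the model chain and BF antisymmetry hold exactly
  d_el <- cmp$delta_aicc[cmp$m1 == "exponential" & cmp$m0 == "linear"]
  d_ep <- cmp$delta_aicc[cmp$m1 == "exponential" & cmp$m0 == "power"]
  d_pl <- cmp$delta_aicc[cmp$m1 == "power" & cmp$m0 == "linear"]
  expect_equal(d_el, d_ep + d_pl, tolerance = 1e-10)
  bf_ep <- cmp$bayes_factor[cmp$m1 == "exponential" & cmp$m0 == "power"]
  bf_pe <- cmp$bayes_factor[cmp$m1 == "power" & cmp$m0 == "exponential"]
  expect_equal(bf_ep * bf_pe, 1, tolerance = 1e-12)

  # identical fits: delta AICc 0, BF 1, interpreted as supporting M0
  two <- list(fits$exponential, fits$exponential)
  two[[2]]$form <- "exponential2"
  cmp2 <- compare_models(two)
  expect_equal(cmp2$delta_aicc, c(0, 0))
  expect_equal(cmp2$bayes_factor, c(1, 1))
  expect_true(all(cmp2$interpretation == "Substantially supports the M0"))

  other <- fit_mle(1:36, g$score + 1, "exponential")
  expect_error(compare_models(list(fits$exponential, other)), "identical data")
})

test_that("participant-level fits respect individual bounds and flag clipping", {
  # noiseless heterogeneous participants are recovered exactly
  truths <- data.frame(A = c(8, 12, 16, 20, 10, 14), x0 = 0.5,
                       tau = c(3, 6, 9, 12, 15, 18))
  sl <- dplyr::bind_rows(lapply(1:6, function(i) {
    tibble::tibble(
      participant_id = sprintf("p%02d", i), block = 1:36,
      score = lc_predict("exponential",
                         c(truths$A[i], truths$x0[i], truths$tau[i]), 1:36)
    )
  }))
  pc <- fit_participants(sl, seed = 5)
  expect_true(all(pc$converged))
  expect_equal(pc$A, truths$A, tolerance = 1e-3)
  expect_equal(pc$tau, truths$tau, tolerance = 1e-3)

  # a true tau outside the [1, 50] bound pins the estimate at the bound
  far <- tibble::tibble(
    participant_id = "p99", block = 1:36,
    score = lc_predict("exponential", c(15, 0, 60), 1:36)
  )
  pf <- fit_participants(far, seed = 6)
  expect_equal(pf$tau, 50, tolerance = 1e-6)
  expect_match(pf$bounds_hit, "tau")
})

test_that("rank order of fitted tau tracks the generating tau across a cohort", {
  co <- simulate_cohort(24, seed = 7,
                        truth_args = list(A_mean = 13.25, A_sd = 2, tau_sd = 5))
  sl <- compute_sl_scores(summarize_blocks(co$trials), "raw")
  pc <- fit_participants(sl, seed = 3)
  m <- dplyr::inner_join(pc[pc$converged, ], co$truths, by = "participant_id")
  kt <- kendall_tau(m$tau, m$tau_true)
  expect_gte(kt$r, 0.6)
  expect_lt(kt$p, 0.01)
  expect_gte(kendall_tau(m$A, m$A_true)$r, 0.6)
})
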