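# Group-level summaries with known condition means per block, built directly.
make_group_summaries <- function(n_blocks = 36,
                                 rh = rep(280, n_blocks),
                                 rl = rep(290, n_blocks),
                                 ph = rep(284, n_blocks),
                                 acc = 0.92) {
  tibble::tibble(
    participant_id = "group",
    block = rep(seq_len(n_blocks), each = 3),
    condition = rep(c("Pattern-High", "Random-High", "Random-Low"), n_blocks),
    mean_rt_ms = as.vector(rbind(ph, rh, rl)),
    accuracy = acc,
    n_trials = 10L
  )
}

test_that("the probability-contrast design has the documented layout", {
  sm <- make_group_summaries()
  input <- build_design(sm, "probability", "rt")
  expect_equal(nrow(input), 72)
  expect_equal(sum(input$condition_code == 0), 36)
  expect_equal(sum(input$condition_code == 1), 36)
  expect_equal(mean(input$block_c), 0)
  expect_equal(sort(unique(input$block)), 1:36)
  # Random-High is the reference: code-0 rows carry the RH means
  expect_equal(unique(input$outcome[input$condition_code == 0]), 280)
  # type contrast references Pattern-High
  input_t <- build_design(sm, "type", "rt")
  expect_equal(unique(input_t$outcome[input_t$condition_code == 0]), 284)
  expect_error(
    build_design(sm[!(sm$block == 7 & sm$condition == "Random-Low"), ],
                 "probability", "rt"),
    "missing block")
})

test_that("the balanced centered fit recovers the reference-condition grand mean", {
  # closed-form two-group oracle: intercept = reference grand mean,
  # condition beta = difference of condition grand means
  withr::with_seed(21, {
    rh <- 280 + rnorm(36, 0, 2)
    rl <- 290 + rnorm(36, 0, 2)
  })
  fit <- fit_ols(build_design(make_group_summaries(rh = rh, rl = rl),
                              "probability", "rt"))
  co <- fit$coefficients
  expect_equal(co$beta[co$term == "(Constant)"], mean(rh), tolerance = 1e-10)
  expect_equal(co$beta[co$term == "Condition"], mean(rl) - mean(rh),
               tolerance = 1e-10)
})

test_that("OLS interpolates noiseless planted coefficients exactly", {
  input <- tidyr::expand_grid(block_c = (1:36) - 18.5, condition_code = c(0, 1))
  input$outcome <- 5 + 2 * input$block_c + 3 * input$condition_code +
    1 * input$block_c * input$condition_code
  fit <- suppressWarnings(fit_ols(input)) # lm warns on an exact fit
  co <- fit$coefficients
  expect_equal(co$beta[co$term == "(Constant)"], 5, tolerance = 1e-10)
  expect_equal(co$beta[co$term == "Block order"], 2, tolerance = 1e-10)
  expect_equal(co$beta[co$term == "Condition"], 3, tolerance = 1e-10)
  expect_equal(co$beta[co$term == "Interaction"], 1, tolerance = 1e-10)
})

test_that("degenerate and singular designs are handled explicitly", {
  input <- tidyr::expand_grid(block_c = (1:36) - 18.5, condition_code = c(0, 1))
  input$outcome <- 7
  fit <- suppressWarnings(fit_ols(input))
  expect_equal(fit$coefficients$beta[1], 7)
  expect_true(all(abs(fit$coefficients$beta[-1]) < 1e-10))
  expect_equal(fit$adj_r2, 0)

  bad <- input
  bad$condition_code <- 0 # no condition variation -> rank deficient
  expect_error(fit_ols(bad), "singular")
  expect_error(fit_ols(input[1:4, ]), "at least 8")
})

test_that("fit_ols matches the normal-equations oracle on random designs", {
  for (i in 1:20) {
    input <- withr::with_seed(500 + i, {
      nb <- sample(6:20, 1)
      d <- tidyr::expand_grid(block_c = seq_len(nb) - (nb + 1) / 2,
                              condition_code = c(0, 1))
      d$outcome <- rnorm(nrow(d), 300, 10)
      d
    })
    fit <- fit_ols(input)
    X <- cbind(1, input$block_c, input$condition_code,
               input$block_c * input$condition_code)
    expect_equal(unname(fit$coefficients$beta[
      match(c("(Constant)", "Block order", "Condition", "Interaction"),
            fit$coefficients$term)]),
      unname(oracle_ols_beta(X, input$outcome)), tolerance = 1e-8)
  }
})

test_that("row order does not affect the fit and centering shifts only level terms", {
  input <- tidyr::expand_grid(block_c = (1:36) - 18.5, condition_code = c(0, 1))
  input$outcome <- withr::with_seed(77, 280 + 9.8 * input$condition_code +
                                      2.9 * input$block_c * input$condition_code +
                                      rnorm(72, 0, 2))
  fit <- fit_ols(input)
  perm <- withr::with_seed(78, input[sample.int(72), ])
  fit_p <- fit_ols(perm)
  expect_equal(fit$coefficients, fit_p$coefficients, tolerance = 1e-10)
  expect_equal(fit$AICc, fit_p$AICc, tolerance = 1e-10)

  uncentered <- input
  uncentered$block_c <- uncentered$block_c + 18.5
  fit_u <- fit_ols(uncentered)
  co <- fit$coefficients; co_u <- fit_u$coefficients
  # slopes of block and interaction are invariant to centering
  expect_equal(co$beta[co$term == "Block order"],
               co_u$beta[co_u$term == "Block order"], tolerance = 1e-9)
  expect_equal(co$beta[co$term == "Interaction"],
               co_u$beta[co_u$term == "Interaction"], tolerance = 1e-9)
  expect_equal(fit$adj_r2, fit_u$adj_r2, tolerance = 1e-10)
})

test_that("planted condition and interaction effects are recovered from noisy data", {
  # condition offset 9.8 ms, interaction 2.9 ms per block unit, noise 2 ms;
  # averaged over 25 replicates the estimates must sit within 3 SE of the
  # replicate mean around the planted values
  fits <- lapply(1:25, function(s) {
    input <- tidyr::expand_grid(block_c = (1:36) - 18.5,
                                condition_code = c(0, 1))
    input$outcome <- withr::with_seed(900 + s, 280.5 - 1.0 * input$block_c +
                                        9.8 * input$condition_code +
                                        2.9 * input$block_c * input$condition_code +
                                        rnorm(72, 0, 2))
    fit_ols(input)$coefficients
  })
  for (term_val in list(c("Condition", 9.8), c("Interaction", 2.9),
                        c("Block order", -1.0))) {
    betas <- sapply(fits, function(co) co$beta[co$term == term_val[1]])
    ses <- sapply(fits, function(co) co$se[co$term == term_val[1]])
    expect_lt(abs(mean(betas) - as.numeric(term_val[2])),
              3 * mean(ses) / sqrt(25))
  }
})

test_that("interaction CI covers a zero true interaction at nominal rate", {
  covered <- sapply(1:100, function(i) {
    input <- tidyr::expand_grid(block_c = (1:36) - 18.5,
                                condition_code = c(0, 1))
    input$outcome <- withr::with_seed(1200 + i,
      280 - 1.0 * input$block_c + 9.8 * input$condition_code + rnorm(72, 0, 2))
    co <- fit_ols(input)$coefficients
    i <- which(co$term == "Interaction")
    co$ci_lo[i] <= 0 && 0 <= co$ci_hi[i]
  })
  expect_gte(mean(covered), 0.90)
})
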