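#' Build the block x condition regression design
#'
#' Averages the per-participant condition summaries to group level and lays
#' out the two-condition design for the effect-of-learning regressions:
#' outcome ~ centered block order + condition dummy + their interaction. The
#' `"probability"` contrast compares Random-High (code 0) against Random-Low
#' (code 1), so the interaction term captures the growth of the
#' statistical-learning effect over blocks; the `"type"` contrast compares
#' Pattern-High (code 0) against Random-High (code 1).
#'
#' @param summaries Output of [summarize_blocks()].
#' @param contrast `"probability"` or `"type"`.
#' @param outcome `"rt"` (mean RT, ms) or `"accuracy"`.
#' @return Tibble `block`, `block_c` (block order minus its mean),
#'   `condition_code` (0/1) and `outcome`; 2 x n_blocks rows.
#' @export
build_design <- function(summaries,
                         contrast = c("probability", "type"),
                         outcome = c("rt", "accuracy")) {
  contrast <- match.arg(contrast)
  outcome <- match.arg(outcome)
  conds <- switch(contrast,
    probability = c("Random-High", "Random-Low"),
    type = c("Pattern-High", "Random-High")
  )
  group <- summaries |>
    dplyr::filter(.data$condition %in% conds) |>
    dplyr::group_by(.data$block, .data$condition) |>
    dplyr::summarise(
      rt = mean(.data$mean_rt_ms, na.rm = TRUE),
      accuracy = mean(.data$accuracy, na.rm = TRUE),
      .groups = "drop"
    )
  blocks <- sort(unique(summaries$block))
  if (!all(table(group$condition) == length(blocks)) ||
      length(unique(group$condition)) != 2L) {
    stop("missing block x condition cells for contrast '", contrast, "'")
  }
  tibble::tibble(
    block = group$block,
    block_c = group$block - mean(blocks),
    condition_code = as.numeric(group$condition == conds[2L]),
    outcome = group[[outcome]]
  )
}

#' Fit the interaction regression by ordinary least squares
#'
#' `outcome ~ block_c * condition_code` via OLS, reported the way effect
#' tables in this literature are laid out: per-coefficient estimate, SE, t,
#' two-sided p and 95% CI, plus the model F test, adjusted R^2, and
#' AICc/BIC computed from the Gaussian log-likelihood with k = 5 (four
#' coefficients plus the error variance).
#'
#' @param input Tibble from [build_design()] (columns `block_c`,
#'   `condition_code`, `outcome`).
#' @return An `ols_fit` list: `coefficients` tibble (`term`, `beta`, `se`,
#'   `t`, `p`, `ci_lo`, `ci_hi`), `F`, `model_p`, `adj_r2`, `logL`, `AICc`,
#'   `BIC`, `n`, `k`, and the underlying `lm` object.
#' @export
fit_ols <- function(input) {
  stopifnot(all(c("block_c", "condition_code", "outcome") %in% names(input)))
  n <- nrow(input)
  if (n < 8L) stop("need at least 8 rows")
  X <- model.matrix(~ block_c * condition_code, data = input)
  if (qr(X)$rank < ncol(X)) {
    stop("singular design: rank ", qr(X)$rank, " < ", ncol(X))
  }
  fit <- lm(outcome ~ block_c * condition_code, data = input)
  sm <- summary(fit)
  df <- n - 4L
  tcrit <- qt(0.975, df)
  co <- sm$coefficients
  coefs <- tibble::tibble(
    term = c("(Constant)", "Block order", "Condition", "Interaction")[
      match(rownames(co),
            c("(Intercept)", "block_c", "condition_code",
              "block_c:condition_code"))],
    beta = unname(co[, 1]), se = unname(co[, 2]),
    t = unname(co[, 3]), p = unname(co[, 4]),
    ci_lo = unname(co[, 1] - tcrit * co[, 2]),
    ci_hi = unname(co[, 1] + tcrit * co[, 2])
  )

  rss <- sum(fit$residuals^2)
  tss <- sum((input$outcome - mean(input$outcome))^2)
  if (tss < .Machine$double.eps * n) {
    # zero-variance outcome: define a degenerate but finite summary
    adj_r2 <- 0
    f_stat <- NA_real_
    model_p <- NA_real_
  } else {
    adj_r2 <- sm$adj.r.squared
    f_stat <- unname(sm$fstatistic[1L])
    model_p <- pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
                  lower.tail = FALSE)
  }
  sigma2 <- max(rss / n, .Machine$double.xmin)
  logL <- -n / 2 * (log(2 * pi * sigma2) + 1)
  k <- 5L
  structure(
    list(
      coefficients = coefs,
      F = f_stat, model_p = unname(model_p), adj_r2 = adj_r2,
      logL = logL, AICc = aicc(k, n, logL), BIC = bic(k, n, logL),
      n = n, k = k, df = df, lm = fit
    ),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS interaction fit: n = %d, F(3,%d) = %.3f, adj R^2 = %.3f\n",
              x$n, x$df, x$F, x$adj_r2))
  print(as.data.frame(x$coefficients), digits = 4)
  cat(sprintf("AICc = %.2f, BIC = %.2f\n", x$AICc, x$BIC))
  invisible(x)
}

#' Render an OLS fit as a Markdown table
#'
#' @param fit An `ols_fit`.
#' @param digits Significant digits.
#' @return Character vector of Markdown lines.
#' @export
format_ols_markdown <- function(fit, digits = 4) {
  co <- fit$coefficients
  fmt <- function(v) signif(v, digits)
  c(
    "| Coefficient | beta | SE | t | P | CI95 |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %.3g | %s to %s |",
            co$term, fmt(co$beta), fmt(co$se), fmt(co$t), co$p,
            fmt(co$ci_lo), fmt(co$ci_hi)),
    "",
    sprintf("F(3,%d) = %.3f, P = %.3g, adj. R^2 = %.3f, AICc = %.2f, BIC = %.2f",
            fit$df, fit$F, fit$model_p, fit$adj_r2, fit$AICc, fit$BIC)
  )
}
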