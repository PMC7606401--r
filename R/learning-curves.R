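#' Evaluate a learning-curve model
#'
#' Three classical learning-curve families are supported, each with three
#' parameters:
#' * exponential: `y = w1 * (1 - exp(-(x - w2) / w3))` — `w1` is the
#'   saturation level (potential of learning, A), `w2` the x-intercept (x0)
#'   and `w3` the time constant (efficiency, tau); requires `w3 > 0`;
#' * power: `y = w1 * (x - w2)^w3` — requires `x - w2 > 0` over the range;
#' * linear: `y = w1 * (x - w2) + w3`.
#'
#' @param form `"exponential"`, `"power"` or `"linear"`.
#' @param params Numeric vector `(w1, w2, w3)`.
#' @param x Block orders (predictor).
#' @return Predicted SL scores.
#' @examples
#' lc_predict("exponential", c(13.25, -0.39, 10.28), x = -0.39 + 10.28)
#' # = 13.25 * (1 - 1/e), the 63.2% point
#' @export
lc_predict <- function(form = c("exponential", "power", "linear"), params, x) {
  form <- match.arg(form)
  stopifnot(length(params) >= 3L)
  w1 <- params[[1L]]; w2 <- params[[2L]]; w3 <- params[[3L]]
  switch(form,
    exponential = {
      if (w3 <= 0) stop("exponential model requires w3 (tau) > 0")
      w1 * (1 - exp(-(x - w2) / w3))
    },
    power = {
      if (any(x - w2 <= 0)) {
        stop("power model domain violation: x - w2 must be > 0")
      }
      w1 * (x - w2)^w3
    },
    linear = w1 * (x - w2) + w3
  )
}

#' Negative log-likelihood of a learning-curve fit
#'
#' Independent Gaussian observation model: the SL score of block `x_i` is
#' `N(predict(x_i), sigma^2)`. Missing scores are skipped (with `n` reduced
#' accordingly). Parameter combinations that violate the model domain or give
#' non-finite predictions return a large finite penalty so bounded optimizers
#' remain stable.
#'
#' @param par Numeric vector `(w1, w2, w3, sigma)`.
#' @param x Block orders.
#' @param y Observed SL scores (may contain NA).
#' @param form Model family, see [lc_predict()].
#' @param quiet Suppress the warning on penalty returns (used internally by
#'   the optimizer).
#' @return Scalar negative log-likelihood.
#' @export
neg_log_likelihood <- function(par, x, y, form = "exponential", quiet = FALSE) {
  keep <- !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (!length(y)) stop("no non-missing points")
  sigma <- par[[4L]]
  penalty <- 1e10
  if (!all(is.finite(par)) || sigma <= 0) return(penalty)
  mu <- tryCatch(lc_predict(form, par[1:3], x), error = function(e) NULL)
  if (is.null(mu) || !all(is.finite(mu))) {
    if (!quiet) warning("non-finite prediction for form '", form,
                        "'; returning penalty value")
    return(penalty)
  }
  -sum(dnorm(y, mean = mu, sd = sigma, log = TRUE))
}

#' Small-sample-corrected AIC and BIC
#'
#' `aicc(k, n, logL) = 2 k n / (n - k - 1) - 2 logL` and
#' `bic(k, n, logL) = k ln(n) - 2 logL` (natural logarithms).
#'
#' @param k Number of estimated parameters (curve parameters plus the
#'   residual SD).
#' @param n Number of data points.
#' @param logL Maximized log-likelihood.
#' @return Scalar criterion value.
#' @examples
#' aicc(4, 36, -100) # 8 * 36 / 31 + 200
#' bic(4, 36, -100)  # 4 * log(36) + 200
#' @export
aicc <- function(k, n, logL) {
  if (n <= k + 1) stop("AICc requires n > k + 1 (n = ", n, ", k = ", k, ")")
  2 * k * n / (n - k - 1) - 2 * logL
}

#' @rdname aicc
#' @export
bic <- function(k, n, logL) {
  k * log(n) - 2 * logL
}

#' BIC-approximated Bayes factor
#'
#' `BF(M1, M0) = exp(-0.5 * (BIC_M1 - BIC_M0))`; values above 1 favor M1.
#'
#' @param bic_m1,bic_m0 BIC of the candidate and reference model.
#' @return Scalar Bayes factor.
#' @examples
#' bayes_factor(12508, 12516) # exp(4) = 54.6
#' @export
bayes_factor <- function(bic_m1, bic_m0) {
  stopifnot(is.finite(bic_m1), is.finite(bic_m0))
  exp(-0.5 * (bic_m1 - bic_m0))
}

#' Interpretation scales for Bayes factors and AICc differences
#'
#' Conventional evidence bands for a comparison of model M1 against M0:
#' Bayes factor up to 1 substantially supports M0; 1-3 is not worth more than
#' a bare mention; 3-20 positively, 20-150 strongly, and above 150 very
#' strongly supports M1. The analogous AICc-difference bands are 2, 4, 7
#' and 10.
#'
#' @param bf Bayes factor of M1 against M0.
#' @param delta_aicc `AICc(M0) - AICc(M1)` (positive favors M1).
#' @return Interpretation label.
#' @export
interpret_bayes_factor <- function(bf) {
  dplyr::case_when(
    bf <= 1 ~ "Substantially supports the M0",
    bf < 3 ~ "Not worth more than a bare mention",
    bf < 20 ~ "Positively supports the M1",
    bf < 150 ~ "Strongly supports the M1",
    TRUE ~ "Very strongly supports the M1"
  )
}

#' @rdname interpret_bayes_factor
#' @export
interpret_delta_aicc <- function(delta_aicc) {
  dplyr::case_when(
    delta_aicc <= 2 ~ "Substantially supports the M0",
    delta_aicc < 4 ~ "Not worth more than a bare mention",
    delta_aicc < 7 ~ "Positively supports the M1",
    delta_aicc < 10 ~ "Strongly supports the M1",
    TRUE ~ "Very strongly supports the M1"
  )
}

#' Default parameter bounds for bounded MLE
#'
#' Individual exponential fits use the empirical boundaries A in
#' \[-500, 500\], x0 in \[0, 50\], tau in \[1, 50\] and residual SD in
#' (0, 30\]. The group-level fit widens the x0 bound to \[-50, 50\] (a group
#' curve may start marginally before block 1). Power and linear fits use
#' generous bounds; for the power family the upper bound of `w2` is capped
#' just below the smallest block order so the domain `x - w2 > 0` holds.
#'
#' @param form Model family.
#' @param scope `"individual"` or `"group"` (exponential x0 bound differs).
#' @param x_min Smallest block order to be fitted (power-domain cap).
#' @return List with numeric vectors `lower` and `upper` of length 4
#'   (`w1, w2, w3, sigma`).
#' @export
default_bounds <- function(form = "exponential",
                           scope = c("group", "individual"),
                           x_min = 1) {
  scope <- match.arg(scope)
  sigma <- c(1e-4, 30)
  switch(form,
    exponential = list(
      lower = c(-500, if (scope == "group") -50 else 0, 1, sigma[1]),
      upper = c(500, 50, 50, sigma[2])
    ),
    power = list(
      lower = c(-500, -50, -10, sigma[1]),
      upper = c(500, x_min - 1e-3, 10, sigma[2])
    ),
    linear = list(
      lower = c(-50, -50, -500, sigma[1]),
      upper = c(50, 50, 500, sigma[2])
    ),
    stop("unknown form: ", form)
  )
}

#' Fit a learning-curve model by bounded maximum likelihood
#'
#' Minimizes the Gaussian negative log-likelihood with the L-BFGS-B algorithm
#' from the initial parameter values (1, 1, 1, 1) (clamped into the bounds).
#' If that run fails to converge or stops on a bound, up to `restarts`
#' additional runs are started from seeded initial values drawn within the
#' bounds (log-uniformly for strictly positive parameters), and the best
#' converged solution is kept.
#'
#' @param x Block orders.
#' @param y SL scores (NA allowed; skipped).
#' @param form Model family, see [lc_predict()].
#' @param bounds List with `lower` and `upper` (length 4); defaults to
#'   [default_bounds()].
#' @param init Initial `(w1, w2, w3, sigma)`; default all ones.
#' @param restarts Number of jittered restarts in the fallback (default 10).
#' @param seed Seed for the restart jitter.
#' @param scope Passed to [default_bounds()] when `bounds` is NULL.
#' @return An `lc_fit` list: `form`, `w1`, `w2`, `w3`, `sigma`, `logL`, `k`,
#'   `n`, `AICc`, `BIC`, `converged`, `bounds_hit` (logical 4-vector),
#'   `bounds`, `init`.
#' @export
fit_mle <- function(x, y, form = c("exponential", "power", "linear"),
                    bounds = NULL, init = c(1, 1, 1, 1), restarts = 10,
                    seed = 1, scope = "group") {
  form <- match.arg(form)
  keep <- !is.na(y)
  if (sum(keep) < 5L) stop("need at least 5 non-missing points")
  if (is.null(bounds)) {
    bounds <- default_bounds(form, scope = scope, x_min = min(x[keep]))
  }
  lower <- bounds$lower; upper <- bounds$upper
  stopifnot(length(lower) == 4L, length(upper) == 4L, all(lower <= upper))
  init <- pmin(pmax(init, lower), upper)

  one_run <- function(start) {
    tryCatch(
      optim(start, neg_log_likelihood, x = x, y = y, form = form,
            quiet = TRUE, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
  }
  at_bound <- function(par) {
    tol <- 1e-6 * pmax(1, abs(upper - lower))
    (par - lower) < tol | (upper - par) < tol
  }

  fit <- one_run(init)
  ok <- !is.null(fit) && fit$convergence == 0 && is.finite(fit$value) &&
    fit$value < 1e9
  need_restart <- !ok || any(at_bound(fit$par)[1:3])

  if (need_restart && restarts > 0) {
    starts <- with_seed(seed, lapply(seq_len(restarts), function(i) {
      vapply(1:4, function(j) {
        lo <- lower[j]; hi <- upper[j]
        if (lo > 0) exp(runif(1, log(lo), log(hi))) else runif(1, lo, hi)
      }, numeric(1))
    }))
    candidates <- c(list(fit), lapply(starts, one_run))
    values <- vapply(candidates, function(f) {
      if (is.null(f) || f$convergence != 0 || !is.finite(f$value)) Inf else f$value
    }, numeric(1))
    if (any(is.finite(values))) fit <- candidates[[which.min(values)]]
  }

  converged <- !is.null(fit) && fit$convergence == 0 && is.finite(fit$value) &&
    fit$value < 1e9
  if (is.null(fit)) {
    par <- rep(NA_real_, 4L)
    logL <- NA_real_
  } else {
    par <- fit$par
    logL <- -fit$value
  }
  n <- sum(keep)
  k <- 4L
  structure(
    list(
      form = form,
      w1 = par[[1L]], w2 = par[[2L]], w3 = par[[3L]], sigma = par[[4L]],
      logL = logL, k = k, n = n,
      AICc = if (is.finite(logL)) aicc(k, n, logL) else NA_real_,
      BIC = if (is.finite(logL)) bic(k, n, logL) else NA_real_,
      converged = converged,
      bounds_hit = if (all(is.finite(par))) at_bound(par) else rep(NA, 4L),
      bounds = bounds,
      init = init,
      x = x, y = y
    ),
    class = "lc_fit"
  )
}

#' @export
print.lc_fit <- function(x, ...) {
  cat(sprintf("Learning-curve fit (%s), n = %d, k = %d\n", x$form, x$n, x$k))
  cat(sprintf("  w1 = %.4g, w2 = %.4g, w3 = %.4g, sigma = %.4g\n",
              x$w1, x$w2, x$w3, x$sigma))
  cat(sprintf("  logL = %.4f, AICc = %.4f, BIC = %.4f, converged = %s\n",
              x$logL, x$AICc, x$BIC, x$converged))
  invisible(x)
}

#' Compare fitted learning-curve models
#'
#' For every ordered pair of fits (on identical data) reports
#' `delta_aicc = AICc(M0) - AICc(M1)` (positive favors M1), the
#' BIC-approximated Bayes factor and its interpretation band. The best model
#' (smallest AICc) is stored in the `best_aicc` attribute, the smallest-BIC
#' model in `best_bic`; a disagreement between the two is flagged with a
#' warning.
#'
#' @param fits List of `lc_fit` objects fitted to the same series.
#' @return Tibble `m1`, `m0`, `delta_aicc`, `bayes_factor`, `interpretation`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2L)
  ys <- lapply(fits, function(f) f$y)
  if (!all(vapply(ys[-1], identical, logical(1), y = ys[[1]]))) {
    stop("all fits must be computed on identical data")
  }
  forms <- vapply(fits, function(f) f$form, character(1))
  pairs <- expand.grid(m1 = forms, m0 = forms, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$m1 != pairs$m0, , drop = FALSE]
  by_form <- setNames(fits, forms)
  out <- tibble::tibble(
    m1 = pairs$m1,
    m0 = pairs$m0,
    delta_aicc = vapply(seq_len(nrow(pairs)), function(i) {
      by_form[[pairs$m0[i]]]$AICc - by_form[[pairs$m1[i]]]$AICc
    }, numeric(1)),
    bayes_factor = vapply(seq_len(nrow(pairs)), function(i) {
      bayes_factor(by_form[[pairs$m1[i]]]$BIC, by_form[[pairs$m0[i]]]$BIC)
    }, numeric(1))
  )
  out$interpretation <- interpret_bayes_factor(out$bayes_factor)
  aiccs <- vapply(fits, function(f) f$AICc, numeric(1))
  bics <- vapply(fits, function(f) f$BIC, numeric(1))
  attr(out, "best_aicc") <- forms[which.min(aiccs)]
  attr(out, "best_bic") <- forms[which.min(bics)]
  if (forms[which.min(aiccs)] != forms[which.min(bics)]) {
    warning("AICc and BIC select different models (",
            forms[which.min(aiccs)], " vs ", forms[which.min(bics)], ")")
  }
  out
}

#' Fit the group-level learning curve
#'
#' Fits the three model families to the pooled SL-score series. By default
#' the per-block mean over participants is fitted (n = n_blocks); with
#' `pooling = "stacked"` every participant x block point enters the
#' likelihood.
#'
#' @param sl_scores Participant-level scores from [compute_sl_scores()] (or
#'   an already pooled tibble with `block`, `score`).
#' @param forms Model families to fit.
#' @param pooling `"mean"` (default) or `"stacked"`.
#' @param restarts,seed Passed to [fit_mle()].
#' @return List of `lc_fit`, named by form.
#' @export
fit_group_curve <- function(sl_scores,
                            forms = c("exponential", "power", "linear"),
                            pooling = c("mean", "stacked"),
                            restarts = 10, seed = 1) {
  pooling <- match.arg(pooling)
  if ("participant_id" %in% names(sl_scores) && pooling == "mean") {
    series <- group_sl_scores(sl_scores)
  } else {
    series <- sl_scores
  }
  setNames(lapply(forms, function(fm) {
    fit_mle(series$block, series$score, form = fm, scope = "group",
            restarts = restarts, seed = seed)
  }), forms)
}

#' Fit each participant's exponential learning curve
#'
#' Per-participant bounded MLE of the exponential model under the individual
#' empirical boundaries (A in \[-500, 500\], x0 in \[0, 50\], tau in
#' \[1, 50\], sigma in (0, 30\]). Non-converged participants are kept in the
#' output but flagged, so downstream correlation analyses can exclude them.
#'
#' @param sl_scores Tibble from [compute_sl_scores()].
#' @param bounds Bounds list; defaults to the individual exponential bounds.
#' @param restarts,seed Passed to [fit_mle()].
#' @return Tibble `participant_id`, `A`, `x0`, `tau`, `sigma`, `logL`,
#'   `converged`, `bounds_hit` (comma-separated names of pinned parameters,
#'   `""` if none).
#' @export
fit_participants <- function(sl_scores, bounds = NULL, restarts = 10, seed = 1) {
  if (is.null(bounds)) bounds <- default_bounds("exponential", "individual")
  ids <- unique(sl_scores$participant_id)
  fit_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(ids)))
  rows <- lapply(seq_along(ids), function(i) {
    d <- sl_scores[sl_scores$participant_id == ids[i], ]
    f <- fit_mle(d$block, d$score, form = "exponential", bounds = bounds,
                 restarts = restarts, seed = fit_seeds[i])
    hit <- c("A", "x0", "tau", "sigma")[which(f$bounds_hit)]
    tibble::tibble(
      participant_id = ids[i], A = f$w1, x0 = f$w2, tau = f$w3,
      sigma = f$sigma, logL = f$logL, converged = f$converged,
      bounds_hit = paste(hit, collapse = ",")
    )
  })
  out <- dplyr::bind_rows(rows)
  if (any(!out$converged)) {
    message(sum(!out$converged), " participant fit(s) did not converge; ",
            "flagged for exclusion from correlation analyses")
  }
  out
}
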