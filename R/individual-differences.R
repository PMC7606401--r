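#' Standardize scores to z-scores
#'
#' Centers to mean 0 and scales to sample SD 1. Rank-based statistics
#' (Kendall's tau) are invariant to this transform; it is applied so the
#' emitted standardized tables are comparable across tests.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param name Variable name used in error messages.
#' @return Standardized numeric vector.
#' @export
zscore <- function(values, name = deparse(substitute(values))) {
  if (length(values) < 2L) stop("zscore: need at least 2 values in ", name)
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    stop("zscore: zero variance in variable '", name, "'")
  }
  (values - mean(values)) / s
}

#' Kendall rank correlation (tau-b) with two-sided p-value
#'
#' Tie-corrected tau-b; the two-sided p-value uses the exact null
#' distribution for small untied samples and the normal approximation with
#' tie-adjusted variance otherwise (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length >= 5.
#' @return Tibble `r` (tau-b), `p` (two-sided), `n`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5L) stop("need at least 5 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("all-tied vector: Kendall's tau undefined")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlate learning parameters with neuropsych scores
#'
#' Kendall tau-b correlations of the fitted potential (A) and efficiency
#' (tau) of statistical learning with each of the ten executive-function test
#' scores, plus the A-tau correlation. All variables are z-transformed first
#' (which leaves the rank correlations unchanged). Participants flagged as
#' non-converged are excluded; missing values are handled pairwise.
#'
#' @param curves Tibble from [fit_participants()] (`participant_id`, `A`,
#'   `tau`, optionally `converged`).
#' @param scores Tibble from [generate_neuropsych_scores()] (or a user table
#'   with the same columns).
#' @return Tibble `parameter` (`"A"` or `"tau"`), `test`, `r`, `p`, `n`,
#'   ordered tests-within-parameter; the A-vs-tau correlation is attached as
#'   the `a_vs_tau` attribute (a one-row tibble).
#' @export
correlate_profiles <- function(curves, scores) {
  stopifnot("participant_id" %in% names(curves),
            "participant_id" %in% names(scores))
  tests <- intersect(.neuropsych_tests, names(scores))
  if (!length(tests)) stop("no recognized neuropsych test columns in scores")
  if ("converged" %in% names(curves)) {
    n_drop <- sum(!curves$converged)
    if (n_drop > 0) {
      message("excluding ", n_drop, " non-converged participant(s)")
    }
    curves <- curves[curves$converged, ]
  }
  merged <- dplyr::inner_join(curves, scores, by = "participant_id")
  if (nrow(merged) < 5L) {
    stop("fewer than 5 matched participants (", nrow(merged), ")")
  }

  z <- merged
  for (v in c("A", "tau", tests)) z[[v]] <- zscore(z[[v]], name = v)

  out <- tidyr::expand_grid(parameter = c("A", "tau"), test = tests)
  res <- lapply(seq_len(nrow(out)), function(i) {
    kendall_tau(z[[out$parameter[i]]], z[[out$test[i]]])
  })
  out <- dplyr::bind_cols(out, dplyr::bind_rows(res))
  attr(out, "a_vs_tau") <- dplyr::bind_cols(
    tibble::tibble(parameter = "A", test = "tau"),
    kendall_tau(z$A, z$tau)
  )
  out
}
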