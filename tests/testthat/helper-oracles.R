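# Independent oracles and small fixture builders used across the test files.

# Brute-force triplet classifier: decides probability by literal membership of
# the (first, mid, third) identity in the enumerated high-probability identity
# set, independently of the vectorized labeling code.
oracle_label_trials <- function(trials, pattern) {
  space <- enumerate_triplet_space(pattern)$identities
  high_set <- space[space$probability == "high", c("a", "x", "b")]
  in_high <- function(a, x, b) {
    any(high_set$a == a & high_set$x == x & high_set$b == b)
  }
  out <- character(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    prev <- trials[trials$participant_id == tr$participant_id &
                     trials$block == tr$block &
                     trials$trial %in% c(tr$trial - 2L, tr$trial - 1L), ]
    if (nrow(prev) < 2L || tr$role == "warmup" || any(prev$role == "warmup")) {
      out[i] <- "excluded"
    } else {
      first <- prev$target_pos[prev$trial == tr$trial - 2L]
      mid <- prev$target_pos[prev$trial == tr$trial - 1L]
      high <- in_high(first, mid, tr$target_pos)
      out[i] <- if (tr$role == "pattern") {
        "Pattern-High"
      } else if (high) "Random-High" else "Random-Low"
    }
  }
  out
}

# O(n^2) concordant/discordant pair-count Kendall tau-b.
oracle_kendall_tau_b <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tie_pairs <- function(v) sum(sapply(table(v), function(t) t * (t - 1) / 2))
  (C - D) / sqrt((n0 - tie_pairs(x)) * (n0 - tie_pairs(y)))
}

# Closed-form OLS via the normal equations.
oracle_ols_beta <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Small labeled trial table built by hand: one block, given roles/targets.
make_block_trials <- function(roles, targets, participant_id = "p01",
                              block = 1L) {
  tibble::tibble(
    participant_id = participant_id,
    block = block,
    trial = seq_along(roles),
    role = roles,
    target_pos = as.integer(targets)
  )
}

# Directly simulated group SL-score series from the exponential curve.
simulate_group_series <- function(A, x0, tau, noise_sd, seed,
                                  blocks = 1:36) {
  withr::with_seed(seed, {
    tibble::tibble(
      block = blocks,
      score = A * (1 - exp(-(blocks - x0) / tau)) + rnorm(length(blocks), 0, noise_sd)
    )
  })
}
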