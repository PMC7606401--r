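#' Define an ASRT session design
#'
#' An alternating serial reaction time (ASRT) session consists of `n_blocks`
#' blocks of `trials_per_block` trials. Each block opens with `n_warmup`
#' warm-up trials in random positions, followed by `unit_repeats` repetitions
#' of the 8-trial alternating unit in which pattern trials (fixed positions
#' following the session's cyclic pattern permutation) strictly alternate with
#' random trials.
#'
#' @param pattern Ordered 4-vector over positions 1..4: the cyclic pattern
#'   permutation defining the deterministic transitions `next(a)`.
#' @param n_blocks Number of blocks (default 36).
#' @param trials_per_block Trials per block (default 85).
#' @param n_warmup Warm-up trials at the start of each block (default 5).
#' @param unit_repeats Repetitions of the 8-trial alternating unit per block
#'   (default 10). Must satisfy `n_warmup + 8 * unit_repeats ==
#'   trials_per_block`.
#' @param stimulus_ms Stimulus presentation duration in ms (default 500).
#' @param iti_ms Inter-trial interval in ms (default 120).
#' @param lead_in_ms Lead-in display (four empty circles) at block start in ms
#'   (default 200).
#' @return A `session_design` list.
#' @examples
#' d <- session_design(pattern = c(3, 2, 4, 1))
#' block_duration_ms(d) # 52900
#' @export
session_design <- function(pattern = c(1L, 2L, 3L, 4L),
                           n_blocks = 36L,
                           trials_per_block = 85L,
                           n_warmup = 5L,
                           unit_repeats = 10L,
                           stimulus_ms = 500,
                           iti_ms = 120,
                           lead_in_ms = 200) {
  pattern <- as.integer(pattern)
  if (!identical(sort(pattern), 1:4)) {
    stop("`pattern` must be a permutation of 1:4, got: ",
         paste(pattern, collapse = ","))
  }
  if (n_warmup + 8L * unit_repeats != trials_per_block) {
    stop("design invariant violated: n_warmup + 8 * unit_repeats (",
         n_warmup + 8L * unit_repeats, ") != trials_per_block (",
         trials_per_block, ")")
  }
  structure(
    list(
      pattern = pattern,
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      n_warmup = as.integer(n_warmup),
      unit_repeats = as.integer(unit_repeats),
      stimulus_ms = stimulus_ms,
      iti_ms = iti_ms,
      lead_in_ms = lead_in_ms
    ),
    class = "session_design"
  )
}

#' All 24 pattern permutations of the four positions
#'
#' @return A 24 x 4 integer matrix, one permutation per row, in lexicographic
#'   order.
#' @export
all_pattern_permutations <- function() {
  perms <- matrix(0L, 24L, 4L)
  i <- 0L
  for (a in 1:4) for (b in setdiff(1:4, a)) for (ch in setdiff(1:4, c(a, b))) {
    i <- i + 1L
    perms[i, ] <- c(a, b, ch, setdiff(1:4, c(a, b, ch)))
  }
  perms
}

#' Assign a counterbalanced pattern permutation to a participant
#'
#' Across every 24 consecutive participant indices each of the 24 permutations
#' of (1,2,3,4) occurs exactly once; the order of assignment within a cycle is
#' a seeded shuffle, so cohorts with different master seeds rotate through the
#' permutations in different orders while remaining counterbalanced.
#'
#' @param seed Integer seed controlling the shuffle of the 24 permutations.
#' @param participant_index 0-based participant index.
#' @return Integer 4-vector, a permutation of 1:4.
#' @examples
#' make_pattern_permutation(1, 0)
#' @export
make_pattern_permutation <- function(seed, participant_index) {
  stopifnot(participant_index >= 0)
  perms <- all_pattern_permutations()
  ord <- with_seed(seed, sample.int(24L))
  perms[ord[(as.integer(participant_index) %% 24L) + 1L], ]
}

## Successor map of a cyclic pattern: nxt[a] is the pattern position that
## follows position a (pattern trial to next pattern trial).
pattern_successor <- function(pattern) {
  pattern <- as.integer(pattern)
  nxt <- integer(4L)
  nxt[pattern] <- pattern[c(2:4, 1L)]
  nxt
}

#' Generate the target sequence of one ASRT session
#'
#' Produces the ordered trial table for a single participant: warm-up and
#' random-trial targets drawn i.i.d. uniformly over the four positions,
#' pattern-trial targets following the cyclic pattern. The pattern cycle
#' continues across the 8-trial units within a block and restarts at the
#' permutation's first element at each new block.
#'
#' @param design A [session_design()].
#' @param seed Integer seed for the random-position draws.
#' @param participant_id Identifier stored in the `participant_id` column.
#' @return A tibble of trials with columns `participant_id`, `block`, `trial`,
#'   `role` (warmup/pattern/random) and `target_pos`; responses are absent
#'   (see [simulate_responses()]).
#' @export
generate_session <- function(design, seed, participant_id = "p01") {
  stopifnot(inherits(design, "session_design"))
  nb <- design$n_blocks
  tpb <- design$trials_per_block
  nw <- design$n_warmup

  role_block <- c(rep("warmup", nw),
                  rep(c("pattern", "random"), 4L * design$unit_repeats))
  role <- rep(role_block, nb)
  block <- rep(seq_len(nb), each = tpb)
  trial <- rep(seq_len(tpb), nb)

  target <- integer(nb * tpb)
  is_rand <- role != "pattern"
  target[is_rand] <- with_seed(seed, sample.int(4L, sum(is_rand), replace = TRUE))
  # pattern targets: 4 * unit_repeats per block, cycle restarts each block
  target[!is_rand] <- rep(rep(design$pattern, times = design$unit_repeats), nb)

  tibble::tibble(
    participant_id = participant_id,
    block = block,
    trial = trial,
    role = role,
    target_pos = target
  )
}

#' Block and session durations implied by a design
#'
#' One block lasts `lead_in_ms + trials_per_block * (stimulus_ms + iti_ms)`;
#' the default design gives 52,900 ms per block. The session duration excludes
#' the rest periods between blocks.
#'
#' @param design A [session_design()].
#' @return Duration in milliseconds.
#' @export
block_duration_ms <- function(design) {
  stopifnot(inherits(design, "session_design"))
  design$lead_in_ms + design$trials_per_block * (design$stimulus_ms + design$iti_ms)
}

#' @rdname block_duration_ms
#' @export
session_duration_ms <- function(design) {
  design$n_blocks * block_duration_ms(design)
}

#' Ground-truth learning parameters for one simulated participant
#'
#' Encodes the generative model of a participant's reaction times: a baseline
#' RT with an optional linear per-block practice speed-up, plus a
#' Random-Low-specific slowing that grows over blocks as the exponential
#' learning curve `gap(b) = A * (1 - exp(-(b - x0) / tau))`. The per-block
#' absolute Random-Low minus Random-High RT difference — the SL score — then
#' equals `gap(b)` in expectation.
#'
#' @param A_true Saturation of the RT gap, ms.
#' @param x0_true Curve x-intercept, block units.
#' @param tau_true Exponential time constant, block units; must be > 0.
#' @param base_rt_ms Condition-independent mean RT, ms.
#' @param practice_slope_ms General per-block speed-up, ms/block.
#' @param noise_sd_ms SD of trial-level Gaussian RT noise, ms.
#' @param p_correct Per-trial probability of a correct response.
#' @return A `ground_truth` list.
#' @export
participant_ground_truth <- function(A_true = 13.25,
                                     x0_true = -0.39,
                                     tau_true = 10.28,
                                     base_rt_ms = 280.5,
                                     practice_slope_ms = 1,
                                     noise_sd_ms = 5,
                                     p_correct = 0.92) {
  if (tau_true <= 0) stop("tau_true must be > 0")
  if (p_correct <= 0 || p_correct > 1) stop("p_correct must be in (0, 1]")
  if (noise_sd_ms < 0) stop("noise_sd_ms must be >= 0")
  structure(
    list(A_true = A_true, x0_true = x0_true, tau_true = tau_true,
         base_rt_ms = base_rt_ms, practice_slope_ms = practice_slope_ms,
         noise_sd_ms = noise_sd_ms, p_correct = p_correct),
    class = "ground_truth"
  )
}

#' Draw a heterogeneous cohort of ground-truth parameter sets
#'
#' Participant-level parameters are drawn around the group-level curve:
#' A ~ N(A_mean, A_sd), tau ~ N(tau_mean, tau_sd) clipped to stay inside the
#' individual fitting bounds, x0 ~ N(x0_mean, x0_sd) clipped to be
#' non-negative, base RT ~ N(base_rt_mean, base_rt_sd).
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param A_mean,A_sd,tau_mean,tau_sd,x0_mean,x0_sd,base_rt_mean,base_rt_sd
#'   Cohort distribution parameters.
#' @param practice_slope_ms,noise_sd_ms,p_correct Shared generative constants,
#'   see [participant_ground_truth()].
#' @return Tibble with one row per participant (`participant_id`, `A_true`,
#'   `x0_true`, `tau_true`, `base_rt_ms`, `practice_slope_ms`, `noise_sd_ms`,
#'   `p_correct`).
#' @export
sample_ground_truths <- function(n, seed,
                                 A_mean = 13.25, A_sd = 4,
                                 tau_mean = 10.28, tau_sd = 3,
                                 x0_mean = 0.5, x0_sd = 0.5,
                                 base_rt_mean = 280.5, base_rt_sd = 20,
                                 practice_slope_ms = 1,
                                 noise_sd_ms = 5,
                                 p_correct = 0.92) {
  with_seed(seed, {
    tibble::tibble(
      participant_id = sprintf("p%02d", seq_len(n)),
      A_true = rnorm(n, A_mean, A_sd),
      x0_true = pmin(pmax(rnorm(n, x0_mean, x0_sd), 0), 5),
      tau_true = pmin(pmax(rnorm(n, tau_mean, tau_sd), 1.5), 45),
      base_rt_ms = rnorm(n, base_rt_mean, base_rt_sd),
      practice_slope_ms = practice_slope_ms,
      noise_sd_ms = noise_sd_ms,
      p_correct = p_correct
    )
  })
}

## Expected Random-Low slowing at block b under the exponential curve.
learning_gap <- function(block, A, x0, tau) {
  A * (1 - exp(-(block - x0) / tau))
}

#' Simulate responses for a labeled target sequence
#'
#' Reaction times follow
#' `rt = base_rt - practice_slope * (block - 1) + gap(block) * [Random-Low] +
#' N(0, noise_sd)`, truncated below at `rt_floor_ms`, where
#' `gap(b) = A * (1 - exp(-(b - x0)/tau))`. Responses are correct with
#' probability `p_correct`; on errors the response position is drawn uniformly
#' from the three non-target positions. Trials must carry their triplet
#' `condition` (from [label_trials()]) so the Random-Low slowing can be
#' applied.
#'
#' @param trials Labeled trial tibble (needs `block`, `target_pos`,
#'   `condition`).
#' @param truth A [participant_ground_truth()] (or one row of
#'   [sample_ground_truths()]).
#' @param seed Integer seed (split into RT-noise and accuracy sub-streams).
#' @param rt_floor_ms Lower truncation for RTs, ms (default 100).
#' @return The input tibble with `response_pos`, `correct` and `rt_ms` filled
#'   in.
#' @export
simulate_responses <- function(trials, truth, seed, rt_floor_ms = 100) {
  if (is.data.frame(truth)) {
    stopifnot(nrow(truth) == 1L)
    truth <- participant_ground_truth(
      A_true = truth$A_true, x0_true = truth$x0_true,
      tau_true = truth$tau_true, base_rt_ms = truth$base_rt_ms,
      practice_slope_ms = truth$practice_slope_ms,
      noise_sd_ms = truth$noise_sd_ms, p_correct = truth$p_correct
    )
  }
  stopifnot(inherits(truth, "ground_truth"))
  if (!"condition" %in% names(trials)) {
    stop("trials must be labeled by label_trials() before simulating responses")
  }
  n <- nrow(trials)
  seeds <- substream_seeds(seed, c("rt_noise", "accuracy", "errors"))

  gap <- learning_gap(trials$block, truth$A_true, truth$x0_true, truth$tau_true)
  mu <- truth$base_rt_ms - truth$practice_slope_ms * (trials$block - 1) +
    gap * as.numeric(!is.na(trials$condition) & trials$condition == "Random-Low")
  rt <- mu + with_seed(seeds[["rt_noise"]], rnorm(n, 0, truth$noise_sd_ms))
  rt <- pmax(rt, rt_floor_ms)

  correct <- with_seed(seeds[["accuracy"]],
                       rbinom(n, 1L, truth$p_correct)) == 1L
  response <- trials$target_pos
  n_err <- sum(!correct)
  if (n_err > 0) {
    offsets <- with_seed(seeds[["errors"]], sample.int(3L, n_err, replace = TRUE))
    # uniform over the three non-target positions
    response[!correct] <- ((trials$target_pos[!correct] - 1L + offsets) %% 4L) + 1L
  }

  trials$response_pos <- response
  trials$correct <- correct
  trials$rt_ms <- rt
  trials
}

#' Generate neuropsychological test scores with requested rank correlations
#'
#' Scores for the ten executive-function tests are built with a Gaussian
#' copula: the designated learning parameter (A or tau) is mapped to normal
#' scores via its ranks, the test's latent variable is
#' `rho * z_param + sqrt(1 - rho^2) * noise` with
#' `rho = sin(pi * corr / 2)`, so that the expected Kendall correlation with
#' the parameter equals the requested `corr`
#' (`tau_kendall = (2/pi) * asin(rho)`). Latents are then rescaled to mean 50,
#' SD 10 — Kendall correlations are invariant to this.
#'
#' @param truths Tibble from [sample_ground_truths()] (needs
#'   `participant_id`, `A_true`, `tau_true`).
#' @param targets Tibble with columns `test` (one of the ten test names),
#'   `param` (`"A"` or `"tau"`) and `corr` (requested Kendall correlation in
#'   \[-1, 1\]). Defaults to [default_neuropsych_targets()]. Tests not listed
#'   get independent scores.
#' @param seed Integer seed.
#' @return Tibble: `participant_id` plus one column per test (Category,
#'   Letter, CST_F, CST_B, CBT_F, CBT_B, WCST, Stroop, ANT, GNG).
#' @export
generate_neuropsych_scores <- function(truths,
                                       targets = default_neuropsych_targets(),
                                       seed = 1) {
  stopifnot(all(c("participant_id", "A_true", "tau_true") %in% names(truths)))
  if (any(abs(targets$corr) > 1)) stop("requested |corr| > 1")
  bad <- setdiff(targets$test, .neuropsych_tests)
  if (length(bad)) stop("unknown test name(s): ", paste(bad, collapse = ", "))

  n <- nrow(truths)
  out <- tibble::tibble(participant_id = truths$participant_id)
  seeds <- substream_seeds(seed, .neuropsych_tests)
  for (test in .neuropsych_tests) {
    row <- targets[targets$test == test, , drop = FALSE]
    corr <- if (nrow(row)) row$corr[[1L]] else 0
    param <- if (nrow(row) && row$param[[1L]] == "tau") truths$tau_true else truths$A_true
    rho <- sin(pi * corr / 2)
    z <- qnorm((rank(param, ties.method = "average") - 0.5) / n)
    latent <- rho * z +
      sqrt(1 - rho^2) * with_seed(seeds[[test]], rnorm(n))
    out[[test]] <- 50 + 10 * latent
  }
  out
}

#' Default neuropsych correlation targets for the synthetic cohort
#'
#' Three tests carry a non-zero requested Kendall correlation with a learning
#' parameter (Corsi block-tapping forwards and the attention network test with
#' the potential A; the Wisconsin card sorting test with the time constant
#' tau); the remaining tests are independent of both.
#'
#' @return Tibble with columns `test`, `param`, `corr`.
#' @export
default_neuropsych_targets <- function() {
  tibble::tibble(
    test = c("CBT_F", "ANT", "WCST"),
    param = c("A", "A", "tau"),
    corr = c(0.268, 0.259, 0.244)
  )
}

#' Simulate a full ASRT cohort
#'
#' Draws per-participant ground truths, assigns counterbalanced pattern
#' permutations, generates target sequences, labels trials by the triplet
#' taxonomy and simulates responses, plus correlated neuropsych scores.
#'
#' @param n_participants Cohort size (default 40).
#' @param seed Master seed; split into sub-streams for truths, permutation
#'   order, per-participant sequences/responses, and neuropsych scores.
#' @param design_args Named list of overrides passed to [session_design()]
#'   (the `pattern` element is ignored: patterns are counterbalanced).
#' @param truth_args Named list of overrides passed to
#'   [sample_ground_truths()].
#' @param neuropsych_targets See [generate_neuropsych_scores()].
#' @return List with elements `trials` (labeled, with responses), `truths`,
#'   `neuropsych`, `patterns` (tibble participant_id, p1..p4).
#' @export
simulate_cohort <- function(n_participants = 40,
                            seed = 1,
                            design_args = list(),
                            truth_args = list(),
                            neuropsych_targets = default_neuropsych_targets()) {
  seeds <- substream_seeds(seed, c("truths", "patterns", "sessions",
                                   "responses", "neuropsych"))
  truths <- do.call(sample_ground_truths,
                    c(list(n = n_participants, seed = seeds[["truths"]]),
                      truth_args))
  session_seeds <- with_seed(seeds[["sessions"]],
                             sample.int(.Machine$integer.max - 1L, n_participants))
  response_seeds <- with_seed(seeds[["responses"]],
                              sample.int(.Machine$integer.max - 1L, n_participants))

  per_participant <- vector("list", n_participants)
  patterns <- matrix(0L, n_participants, 4L)
  for (i in seq_len(n_participants)) {
    pattern <- make_pattern_permutation(seeds[["patterns"]], i - 1L)
    patterns[i, ] <- pattern
    design <- do.call(session_design,
                      modifyList(design_args, list(pattern = pattern)))
    trials <- generate_session(design, session_seeds[i],
                               participant_id = truths$participant_id[i])
    trials <- label_trials(trials, pattern)
    per_participant[[i]] <- simulate_responses(trials, truths[i, ],
                                               response_seeds[i])
  }

  list(
    trials = dplyr::bind_rows(per_participant),
    truths = truths,
    neuropsych = generate_neuropsych_scores(truths, neuropsych_targets,
                                            seeds[["neuropsych"]]),
    patterns = tibble::tibble(
      participant_id = truths$participant_id,
      p1 = patterns[, 1], p2 = patterns[, 2],
      p3 = patterns[, 3], p4 = patterns[, 4]
    )
  )
}
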