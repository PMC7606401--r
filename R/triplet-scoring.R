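#' Enumerate the 64 triplet identities under a pattern permutation
#'
#' A triplet identity is the position triple (a, x, b) of three consecutive
#' trials; it is high-probability iff `b` is the pattern successor of `a`.
#' Every cyclic pattern yields exactly 16 high- and 48 low-probability
#' identities, so each high identity is expected 5 times as often as each low
#' identity (62.5%/16 : 37.5%/48 = 5:1).
#'
#' @param pattern Permutation of 1:4.
#' @return List with counts `high` and `low` and the full `identities` tibble
#'   (`a`, `x`, `b`, `probability`).
#' @examples
#' enumerate_triplet_space(c(3, 2, 4, 1))$high # 16
#' @export
enumerate_triplet_space <- function(pattern) {
  pattern <- as.integer(pattern)
  if (!identical(sort(pattern), 1:4)) stop("`pattern` must be a permutation of 1:4")
  nxt <- pattern_successor(pattern)
  ids <- tidyr::expand_grid(a = 1:4, x = 1:4, b = 1:4)
  ids$probability <- ifelse(ids$b == nxt[ids$a], "high", "low")
  list(
    high = sum(ids$probability == "high"),
    low = sum(ids$probability == "low"),
    identities = ids
  )
}

#' Label trials with their triplet condition
#'
#' Each trial is labeled by the triplet it terminates (its two in-block
#' predecessors plus itself): Pattern-High for pattern-terminated (P-R-P)
#' triplets, Random-High for random-terminated (R-P-R) triplets whose third
#' position is the pattern successor of the first, Random-Low otherwise.
#' Trials whose triplet involves a warm-up trial or fewer than two in-block
#' predecessors are `excluded`; triplets never span block boundaries.
#'
#' @param trials Trial tibble from [generate_session()] (columns
#'   `participant_id`, `block`, `trial`, `role`, `target_pos`), ordered by
#'   block and trial within participant.
#' @param pattern Either a single permutation of 1:4 applied to all
#'   participants, or a tibble with columns `participant_id`, `p1`..`p4`
#'   (as returned by [simulate_cohort()]) for per-participant patterns.
#' @return The input tibble with `first_pos`, `mid_pos` and `condition`
#'   (`"Pattern-High"`, `"Random-High"`, `"Random-Low"` or `"excluded"`)
#'   appended.
#' @export
label_trials <- function(trials, pattern) {
  req <- c("participant_id", "block", "trial", "role", "target_pos")
  stopifnot(all(req %in% names(trials)))
  key <- trials$block * (max(trials$trial) + 1) + trials$trial
  sorted <- vapply(split(key, trials$participant_id),
                   function(k) !is.unsorted(k, strictly = TRUE), logical(1))
  if (!all(sorted)) {
    stop("trials must be ordered by block and trial within each participant")
  }

  if (is.data.frame(pattern)) {
    stopifnot(all(c("participant_id", "p1", "p2", "p3", "p4") %in% names(pattern)))
    nxt_tab <- do.call(rbind, lapply(seq_len(nrow(pattern)), function(i) {
      pattern_successor(unlist(pattern[i, c("p1", "p2", "p3", "p4")]))
    }))
    rownames(nxt_tab) <- pattern$participant_id
    nxt_first <- function(pid, first) {
      nxt_tab[cbind(match(pid, rownames(nxt_tab)), first)]
    }
  } else {
    nxt <- pattern_successor(pattern)
    nxt_first <- function(pid, first) nxt[first]
  }

  labeled <- trials |>
    dplyr::group_by(.data$participant_id, .data$block) |>
    dplyr::mutate(
      first_pos = dplyr::lag(.data$target_pos, 2L),
      mid_pos = dplyr::lag(.data$target_pos, 1L),
      role_first = dplyr::lag(.data$role, 2L),
      role_mid = dplyr::lag(.data$role, 1L)
    ) |>
    dplyr::ungroup()

  excluded <- is.na(labeled$first_pos) |
    labeled$role == "warmup" | labeled$role_first == "warmup" |
    labeled$role_mid == "warmup"

  high <- !excluded &
    labeled$target_pos == nxt_first(labeled$participant_id, labeled$first_pos)

  condition <- rep(NA_character_, nrow(labeled))
  condition[excluded] <- "excluded"
  is_pat <- !excluded & labeled$role == "pattern"
  is_rnd <- !excluded & labeled$role == "random"
  condition[is_pat & high] <- "Pattern-High"
  condition[is_rnd & high] <- "Random-High"
  condition[is_rnd & !high] <- "Random-Low"
  if (any(is_pat & !high)) {
    # cannot arise from a well-formed session: pattern targets follow next()
    warning(sum(is_pat & !high),
            " pattern-role trial(s) disagree with the supplied pattern; ",
            "labeled as excluded")
    condition[is_pat & !high] <- "excluded"
  }

  labeled$condition <- condition
  labeled$role_first <- NULL
  labeled$role_mid <- NULL
  labeled
}

#' Per-block condition summaries
#'
#' One row per participant x block x condition: mean RT over correct trials
#' only, accuracy over all non-excluded trials of that condition, and the
#' trial count. A cell with no correct trial yields a missing mean RT (never
#' an error).
#'
#' @param labeled Labeled trials with responses (`condition`, `correct`,
#'   `rt_ms`).
#' @return Tibble `participant_id`, `block`, `condition`, `mean_rt_ms`,
#'   `accuracy`, `n_trials`.
#' @export
summarize_blocks <- function(labeled) {
  stopifnot(all(c("condition", "correct", "rt_ms") %in% names(labeled)))
  labeled |>
    dplyr::filter(.data$condition %in% .conditions) |>
    dplyr::group_by(.data$participant_id, .data$block, .data$condition) |>
    dplyr::summarise(
      mean_rt_ms = if (any(.data$correct)) mean(.data$rt_ms[.data$correct]) else NA_real_,
      accuracy = mean(.data$correct),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-block statistical-learning scores
#'
#' The raw SL score of a block is the absolute difference between the
#' Random-Low and Random-High mean RTs (correct trials only). Because overall
#' response speed differs between participants, the score can be normalized by
#' the block's overall mean RT (correct trials, all three conditions,
#' count-weighted); `"rescaled"` additionally multiplies the normalized score
#' by the participant's grand-mean RT so values are again on the millisecond
#' scale but freed of per-block speed differences.
#'
#' @param summaries Output of [summarize_blocks()].
#' @param mode `"raw"`, `"normalized"` or `"rescaled"` (default).
#' @return Tibble `participant_id`, `block`, `score` (attribute `mode`
#'   records the choice). Blocks missing a Random-High or Random-Low mean get
#'   a missing score, reported via a message.
#' @export
compute_sl_scores <- function(summaries,
                              mode = c("rescaled", "normalized", "raw")) {
  mode <- match.arg(mode)
  wide <- summaries |>
    dplyr::mutate(n_correct = .data$accuracy * .data$n_trials) |>
    dplyr::group_by(.data$participant_id, .data$block) |>
    dplyr::summarise(
      raw = abs(.data$mean_rt_ms[.data$condition == "Random-Low"][1] -
                  .data$mean_rt_ms[.data$condition == "Random-High"][1]),
      block_mean_rt = sum(.data$mean_rt_ms * .data$n_correct, na.rm = TRUE) /
        sum(.data$n_correct[!is.na(.data$mean_rt_ms)]),
      n_correct = sum(.data$n_correct),
      .groups = "drop"
    )
  if (anyNA(wide$raw)) {
    message(sum(is.na(wide$raw)),
            " block(s) lack a Random-High or Random-Low mean RT; ",
            "SL score set to NA")
  }
  wide <- wide |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      grand_mean_rt = sum(.data$block_mean_rt * .data$n_correct) /
        sum(.data$n_correct),
      normalized = .data$raw / .data$block_mean_rt,
      rescaled = .data$normalized * .data$grand_mean_rt
    ) |>
    dplyr::ungroup()

  out <- tibble::tibble(
    participant_id = wide$participant_id,
    block = wide$block,
    score = wide[[mode]]
  )
  attr(out, "mode") <- mode
  out
}

#' Group-level SL-score series
#'
#' Per-block mean of the participant SL scores (missing scores dropped
#' pairwise).
#'
#' @param sl_scores Output of [compute_sl_scores()].
#' @return Tibble `block`, `score`.
#' @export
group_sl_scores <- function(sl_scores) {
  out <- sl_scores |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(score = mean(.data$score, na.rm = TRUE), .groups = "drop") |>
    dplyr::arrange(.data$block)
  attr(out, "mode") <- attr(sl_scores, "mode")
  out
}
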