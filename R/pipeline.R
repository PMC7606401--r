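#' Default pipeline configuration
#'
#' A fully serializable list describing one end-to-end run: session design
#' overrides, cohort size and ground-truth distribution, SL-score mode,
#' fitting options and neuropsych correlation targets. Together with the
#' master seed it reproduces every output byte-identically.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(
    design = list(),          # overrides for session_design()
    cohort = list(n_participants = 40, truth = list()),
    sl_mode = "rescaled",     # raw | normalized | rescaled
    fit = list(restarts = 10, pooling = "mean"),
    neuropsych_targets = default_neuropsych_targets()
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path File path.
#' @param config Configuration list.
#' @return `read_config()` returns the configuration list.
#' @export
read_config <- function(path) {
  cfg <- utils::modifyList(default_config(), yaml::read_yaml(path))
  if (!is.null(cfg$neuropsych_targets)) {
    cfg$neuropsych_targets <- tibble::as_tibble(
      as.data.frame(lapply(as.data.frame(cfg$neuropsych_targets),
                           unlist),
                    stringsAsFactors = FALSE)
    )
  }
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  cfg <- config
  if (is.data.frame(cfg$neuropsych_targets)) {
    cfg$neuropsych_targets <- as.list(cfg$neuropsych_targets)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.stages <- c("simulate", "score", "regress", "fit", "correlate", "report")

stage_outputs <- function(stage) {
  switch(stage,
    simulate = c("trials.csv", "truths.csv", "neuropsych.csv", "patterns.csv"),
    score = c("summaries.csv", "sl_scores.csv", "group_sl.csv"),
    regress = c("regression.json", "regression.md"),
    fit = c("group_fits.json", "model_comparison.csv", "participants.csv"),
    correlate = c("correlations.csv", "a_vs_tau.csv"),
    report = c("report.md", "learning_curve.png")
  )
}

stage_inputs <- function(stage) {
  switch(stage,
    simulate = character(0),
    score = "trials.csv",
    regress = "summaries.csv",
    fit = "sl_scores.csv",
    correlate = c("participants.csv", "neuropsych.csv"),
    report = c("group_sl.csv", "group_fits.json", "model_comparison.csv",
               "regression.md", "correlations.csv")
  )
}

require_inputs <- function(stage, out_dir) {
  paths <- file.path(out_dir, stage_inputs(stage))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("stage '", stage, "' needs missing input file(s): ",
         paste(missing, collapse = ", "),
         " — run the upstream stage(s) first")
  }
  invisible(paths)
}

write_stage_manifest <- function(stage, out_dir, config, seed) {
  files <- c(stage_inputs(stage), stage_outputs(stage))
  paths <- file.path(out_dir, files)
  hashes <- as.list(tools::md5sum(paths[file.exists(paths)]))
  names(hashes) <- files[file.exists(paths)]
  cfg <- config
  if (is.data.frame(cfg$neuropsych_targets)) {
    cfg$neuropsych_targets <- as.list(cfg$neuropsych_targets)
  }
  manifest <- list(
    stage = stage,
    seed = seed,
    package_version = as.character(utils::packageVersion("slcurves")),
    config = cfg,
    file_md5 = hashes
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run one pipeline stage
#'
#' Stages are independently re-runnable: each reads its upstream artifacts
#' from `out_dir`, writes its outputs and a JSON manifest (seed, config
#' snapshot, file checksums) there, and fails fast, naming the missing file,
#' if an upstream stage has not been run.
#'
#' @param stage One of `"simulate"`, `"score"`, `"regress"`, `"fit"`,
#'   `"correlate"`, `"report"`.
#' @param config Configuration list, see [default_config()].
#' @param seed Master seed (stage seeds are derived sub-streams).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the stage's main result object.
#' @export
run_stage <- function(stage, config = default_config(), seed = 1,
                      out_dir = ".") {
  stage <- match.arg(stage, .stages)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  require_inputs(stage, out_dir)
  seeds <- substream_seeds(seed, .stages)
  res <- switch(stage,
    simulate = .stage_simulate(config, seeds[["simulate"]], out_dir),
    score = .stage_score(config, out_dir),
    regress = .stage_regress(config, out_dir),
    fit = .stage_fit(config, seeds[["fit"]], out_dir),
    correlate = .stage_correlate(config, out_dir),
    report = .stage_report(config, out_dir)
  )
  write_stage_manifest(stage, out_dir, config, seed)
  invisible(res)
}

#' Run the full pipeline
#'
#' Executes simulate, score, regress, fit, correlate and report in order.
#'
#' @inheritParams run_stage
#' @param stages Stages to run (default all, in canonical order).
#' @return Invisibly, `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1,
                         out_dir = ".", stages = .stages) {
  for (stage in stages) {
    message("[slcurves] stage: ", stage)
    run_stage(stage, config = config, seed = seed, out_dir = out_dir)
  }
  invisible(out_dir)
}

.stage_simulate <- function(config, seed, out_dir) {
  cohort <- simulate_cohort(
    n_participants = config$cohort$n_participants,
    seed = seed,
    design_args = config$design %||% list(),
    truth_args = config$cohort$truth %||% list(),
    neuropsych_targets = config$neuropsych_targets
  )
  trials <- cohort$trials
  trials$rt_ms <- round(trials$rt_ms, 3)
  trials$correct <- as.integer(trials$correct)
  readr::write_csv(trials, file.path(out_dir, "trials.csv"))
  readr::write_csv(cohort$truths, file.path(out_dir, "truths.csv"))
  readr::write_csv(cohort$neuropsych, file.path(out_dir, "neuropsych.csv"))
  readr::write_csv(cohort$patterns, file.path(out_dir, "patterns.csv"))
  cohort
}

.stage_score <- function(config, out_dir) {
  trials <- readr::read_csv(file.path(out_dir, "trials.csv"),
                            show_col_types = FALSE)
  trials$correct <- trials$correct == 1
  summaries <- summarize_blocks(trials)
  sl <- compute_sl_scores(summaries, mode = config$sl_mode %||% "rescaled")
  grp <- group_sl_scores(sl)
  readr::write_csv(summaries, file.path(out_dir, "summaries.csv"))
  readr::write_csv(sl, file.path(out_dir, "sl_scores.csv"))
  readr::write_csv(grp, file.path(out_dir, "group_sl.csv"))
  list(summaries = summaries, sl_scores = sl, group = grp)
}

.stage_regress <- function(config, out_dir) {
  summaries <- readr::read_csv(file.path(out_dir, "summaries.csv"),
                               show_col_types = FALSE)
  fits <- list()
  md <- character(0)
  for (contrast in c("probability", "type")) {
    for (outcome in c("accuracy", "rt")) {
      fit <- fit_ols(build_design(summaries, contrast, outcome))
      key <- paste(contrast, outcome, sep = "_")
      fits[[key]] <- list(
        coefficients = fit$coefficients, F = fit$F, model_p = fit$model_p,
        adj_r2 = fit$adj_r2, AICc = fit$AICc, BIC = fit$BIC,
        n = fit$n, k = fit$k
      )
      md <- c(md, paste0("## ", contrast, " contrast, ", outcome), "",
              format_ols_markdown(fit), "")
    }
  }
  jsonlite::write_json(fits, file.path(out_dir, "regression.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(md, file.path(out_dir, "regression.md"))
  fits
}

.stage_fit <- function(config, seed, out_dir) {
  sl <- readr::read_csv(file.path(out_dir, "sl_scores.csv"),
                        show_col_types = FALSE)
  restarts <- config$fit$restarts %||% 10
  fits <- fit_group_curve(sl, pooling = config$fit$pooling %||% "mean",
                          restarts = restarts, seed = seed)
  comparison <- suppressWarnings(compare_models(fits))
  participants <- fit_participants(sl, restarts = restarts, seed = seed)

  fit_records <- lapply(fits, function(f) {
    f[c("form", "w1", "w2", "w3", "sigma", "logL", "k", "n", "AICc", "BIC",
        "converged")]
  })
  jsonlite::write_json(
    list(best_aicc = attr(comparison, "best_aicc"),
         best_bic = attr(comparison, "best_bic"),
         fits = fit_records),
    file.path(out_dir, "group_fits.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  readr::write_csv(comparison, file.path(out_dir, "model_comparison.csv"))
  readr::write_csv(participants, file.path(out_dir, "participants.csv"))
  list(group = fits, comparison = comparison, participants = participants)
}

.stage_correlate <- function(config, out_dir) {
  participants <- readr::read_csv(file.path(out_dir, "participants.csv"),
                                  show_col_types = FALSE)
  scores <- readr::read_csv(file.path(out_dir, "neuropsych.csv"),
                            show_col_types = FALSE)
  correlations <- correlate_profiles(participants, scores)
  readr::write_csv(correlations, file.path(out_dir, "correlations.csv"))
  readr::write_csv(attr(correlations, "a_vs_tau"),
                   file.path(out_dir, "a_vs_tau.csv"))
  correlations
}

.stage_report <- function(config, out_dir) {
  grp <- readr::read_csv(file.path(out_dir, "group_sl.csv"),
                         show_col_types = FALSE)
  gf <- jsonlite::read_json(file.path(out_dir, "group_fits.json"),
                            simplifyVector = TRUE)
  comparison <- readr::read_csv(file.path(out_dir, "model_comparison.csv"),
                                show_col_types = FALSE)
  correlations <- readr::read_csv(file.path(out_dir, "correlations.csv"),
                                  show_col_types = FALSE)
  exp_fit <- gf$fits$exponential

  p <- plot_learning_curve(grp, exp_fit)
  ggplot2::ggsave(file.path(out_dir, "learning_curve.png"), p,
                  width = 6, height = 4, dpi = 150)

  cfg_yaml <- yaml::as.yaml(local({
    cfg <- config
    if (is.data.frame(cfg$neuropsych_targets)) {
      cfg$neuropsych_targets <- as.list(cfg$neuropsych_targets)
    }
    cfg
  }))
  md <- c(
    "# Statistical-learning pipeline report", "",
    "## Group learning curve (exponential)", "",
    sprintf("A (potential) = %.3f, x0 = %.3f, tau (efficiency) = %.3f blocks;",
            exp_fit$w1, exp_fit$w2, exp_fit$w3),
    sprintf("the curve reaches 63.2%% of A at block x0 + tau = %.2f.",
            exp_fit$w2 + exp_fit$w3), "",
    "![group SL scores and fitted curve](learning_curve.png)", "",
    "## Model comparison", "",
    "| M1 | M0 | dAICc | Bayes factor | Interpretation |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %.3f | %.3g | %s |",
            comparison$m1, comparison$m0, comparison$delta_aicc,
            comparison$bayes_factor, comparison$interpretation), "",
    sprintf("Best model by AICc: %s; by BIC: %s.",
            gf$best_aicc, gf$best_bic), "",
    "## Regression tables", "",
    readLines(file.path(out_dir, "regression.md")), "",
    "## Correlations (Kendall tau-b)", "",
    "| parameter | test | r | p | n |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %.3f | %.3f | %d |",
            correlations$parameter, correlations$test, correlations$r,
            correlations$p, correlations$n), "",
    "## Configuration", "",
    "```yaml", strsplit(cfg_yaml, "\n")[[1]], "```"
  )
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(md)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
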