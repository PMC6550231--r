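#' Run the full ingestion-modelling pipeline
#'
#' Orchestrates derive -> individual estimation -> population MCMC -> subgroup
#' comparison -> report, writing every stage artifact as plain CSV/JSON under
#' `out` so any stage can be inspected or re-run independently. Either `input`
#' (an ingestion-event CSV) or `scenario` (a [cohort_scenario()] or a JSON
#' file of its fields, simulated first) must be given. All randomness is
#' controlled by `seed`. Exclusions (e.g. single-dose patients) are logged
#' with reasons in `exclusions.csv`.
#'
#' @param input Path to an ingestion-event CSV (see [read_ingestion_logs()]).
#' @param scenario A [cohort_scenario()], or path to a JSON file with its
#'   fields, for simulation mode.
#' @param out Output directory.
#' @param seed Master seed for every stochastic stage.
#' @param covariates Optional covariates `data.frame` or CSV path.
#' @param mcmc An [mcmc_config()]; defaults to desk-scale settings seeded from
#'   `seed`.
#' @param full_scale If `TRUE`, run the population MCMC at full scale
#'   (3 x 200,000 kept, burn-in 50,000).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with `status` (0 on success), `artifacts` (named
#'   paths), and the fitted objects (`fit`, `population`, `subgroup`).
#' @export
run_pipeline <- function(input = NULL, scenario = NULL, out, seed = 1,
                         covariates = NULL, mcmc = NULL, full_scale = FALSE,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(input) && is.null(scenario)) {
    stopf("either input or scenario must be supplied")
  }
  if (!is.null(input) && !file.exists(input)) {
    stopf("missing input file: %s (exit code 2)", input)
  }
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE)) {
    stopf("cannot create output directory: %s", out)
  }
  artifacts <- list()
  if (is.character(scenario)) {
    if (!file.exists(scenario)) stopf("missing input file: %s (exit code 2)", scenario)
    fields <- jsonlite::read_json(scenario, simplifyVector = TRUE)
    scenario <- do.call(cohort_scenario, fields)
  }
  if (!is.null(scenario)) {
    say("stage simulate: %d patients", scenario$n_patients)
    cohort <- simulate_cohort(scenario, seed = seed)
    artifacts$cohort <- file.path(out, "cohort.csv")
    artifacts$truth <- file.path(out, "truth.csv")
    write_cohort(cohort, artifacts$cohort, artifacts$truth)
    logs <- cohort$logs
  } else {
    say("stage read: %s", input)
    logs <- read_ingestion_logs(input)
  }
  if (is.character(covariates)) {
    covariates <- utils::read.csv(covariates, stringsAsFactors = FALSE)
  }
  say("stage derive + fit-individual: %d logs", length(logs))
  fit <- dosechain(logs, covariates = covariates)
  artifacts$sequences <- file.path(out, "sequences.csv")
  write_sequences(fit$sequences, artifacts$sequences)
  artifacts$estimates <- file.path(out, "estimates.csv")
  utils::write.csv(fit$estimates, artifacts$estimates, row.names = FALSE)
  artifacts$exclusions <- file.path(out, "exclusions.csv")
  utils::write.csv(fit$exclusions, artifacts$exclusions, row.names = FALSE)
  if (nrow(fit$exclusions)) {
    say("  %d patient(s) excluded (see exclusions.csv)", nrow(fit$exclusions))
  }
  if (!is.null(fit$duration_fit)) {
    artifacts$duration_fit <- file.path(out, "duration_fit.csv")
    utils::write.csv(
      data.frame(upsilon = fit$duration_fit$upsilon,
                 kappa = fit$duration_fit$kappa,
                 loglik = fit$duration_fit$loglik,
                 flags = paste(fit$duration_fit$flags, collapse = ";")),
      artifacts$duration_fit, row.names = FALSE)
  }
  population <- NULL
  if (fit$n >= 10L) {
    if (is.null(mcmc)) mcmc <- mcmc_config(seed = seed, full_scale = full_scale)
    say("stage fit-population: %d chains x %d kept", mcmc$n_chains, mcmc$n_iter)
    population <- run_mcmc(fit, mcmc)
    posterior_dir <- file.path(out, "posterior")
    export_diagnostics(population, posterior_dir)
    for (ch in seq_len(mcmc$n_chains)) {
      artifacts[[sprintf("chain%d", ch)]] <-
        file.path(posterior_dir, sprintf("trace_chain%d.csv", ch))
    }
    artifacts$posterior_summary <- file.path(posterior_dir, "posterior_summary.csv")
    artifacts$psrf <- file.path(posterior_dir, "psrf.csv")
  } else {
    say("stage fit-population skipped: %d patients < 10", fit$n)
  }
  subgroup <- tryCatch(compare_groups(fit), error = function(e) e)
  if (inherits(subgroup, "error")) {
    say("stage subgroup skipped: %s", conditionMessage(subgroup))
    subgroup <- NULL
  } else {
    sub_files <- write_subgroup_report(subgroup, file.path(out, "subgroup"))
    artifacts$subgroup_stats <- sub_files[1]
    artifacts$subgroup_tests <- sub_files[2]
    artifacts$km_curves <- sub_files[3]
  }
  info <- list(seed = seed,
               package_version = as.character(utils::packageVersion("dosechain")),
               config_hash = config_hash(list(seed = seed, mcmc = mcmc,
                                              scenario = scenario)),
               n_patients = fit$n, n_excluded = nrow(fit$exclusions),
               stages = c("derive", "fit-individual",
                          if (!is.null(population)) "fit-population",
                          if (!is.null(subgroup)) "subgroup", "report"))
  artifacts$run_info <- file.path(out, "run_info.json")
  jsonlite::write_json(info, artifacts$run_info, auto_unbox = TRUE, digits = NA)
  artifacts$report <- render_report(out)
  say("pipeline complete: %s", out)
  invisible(list(status = 0L, artifacts = artifacts, fit = fit,
                 population = population, subgroup = subgroup))
}

config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Render a summary report from pipeline artifacts
#'
#' Emits `report.md`: cohort adherence characteristics (median, range and IQR
#' of observed ingestion percent, excess dosing rate and observed ingestion
#' duration), the Weibull duration fit, population posterior summaries with
#' convergence diagnostics, and the prompt-corrector subgroup comparison.
#' Missing artifacts are listed by name rather than failing.
#'
#' @param dir Pipeline output directory.
#' @return Path to `report.md`, invisibly.
#' @export
render_report <- function(dir) {
  path <- function(...) file.path(dir, ...)
  lines <- c("# Ingestion-modelling report", "")
  missing <- character()
  fmt_row <- function(lbl, v) {
    sprintf("| %s | %.3g | %.3g | %.3g - %.3g |", lbl,
            stats::median(v, na.rm = TRUE),
            stats::IQR(v, na.rm = TRUE),
            min(v, na.rm = TRUE), max(v, na.rm = TRUE))
  }
  if (file.exists(path("estimates.csv"))) {
    e <- utils::read.csv(path("estimates.csv"), stringsAsFactors = FALSE)
    lines <- c(lines,
      sprintf("Patients fitted: %d", nrow(e)), "",
      "## Adherence characteristics", "",
      "| quantity | median | IQR | range |",
      "|---|---|---|---|",
      fmt_row("Observed ingestion percent (%)", 100 * e$oip),
      fmt_row("Excess dosing rate (events/day)", e$lambda),
      fmt_row("Observed ingestion duration (days)", e$n_total),
      "")
    cls <- classify_pc(e)
    n_cls <- length(cls$pc_ids) + length(cls$npc_ids)
    if (n_cls > 0) {
      lines <- c(lines, sprintf(
        "Prompt correctors: %d of %d classifiable (%.1f%%); %d unclassifiable (no failures).",
        length(cls$pc_ids), n_cls, 100 * length(cls$pc_ids) / n_cls,
        length(cls$excluded_ids)), "")
    }
  } else missing <- c(missing, "estimates.csv")
  if (file.exists(path("duration_fit.csv"))) {
    d <- utils::read.csv(path("duration_fit.csv"))
    lines <- c(lines, sprintf(
      "Duration model: N_Total ~ Weibull(shape %.3g, scale %.3g).", d$upsilon,
      d$kappa), "")
  }
  if (file.exists(path("posterior", "posterior_summary.csv"))) {
    ps <- utils::read.csv(path("posterior", "posterior_summary.csv"))
    lines <- c(lines, "## Population posterior", "",
               "| parameter | mean | median | 95% CrI | PSRF |",
               "|---|---|---|---|---|",
               sprintf("| %s | %.3g | %.3g | [%.3g, %.3g] | %.3f |",
                       ps$parameter, ps$mean, ps$median, ps$q025, ps$q975,
                       ps$psrf),
               "",
               sprintf("Max Gelman-Rubin PSRF: %.4f (bound 1.05).",
                       max(ps$psrf)), "")
  } else missing <- c(missing, "posterior/posterior_summary.csv")
  if (file.exists(path("subgroup", "subgroup_tests.csv"))) {
    st <- utils::read.csv(path("subgroup", "subgroup_tests.csv"))
    lines <- c(lines, "## Prompt-corrector comparison", "",
               "| test | p-value |", "|---|---|",
               sprintf("| %s (%s) | %.4g |", st$name, st$test, st$p_value), "")
  } else {
    lines <- c(lines,
               "Subgroup classification skipped (no classifiable PC/NPC split).",
               "")
  }
  if (length(missing)) {
    lines <- c(lines, "## Missing artifacts", "", paste0("- ", missing), "")
  }
  out <- path("report.md")
  writeLines(lines, out)
  invisible(out)
}
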