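#' Run the end-to-end evaluation pipeline
#'
#' Ties the stages together on synthetic or user-supplied data:
#' simulate/ingest, QC, LD pruning, and leave-one-population-out
#' evaluation, writing every intermediate artifact plus a deterministic
#' JSON summary to `out_dir`. The resolved configuration (including the
#' seed, package version, and a timestamp) is written alongside as
#' `run_config.json`; the summary itself contains no timestamp, so a rerun
#' with the same configuration and seed reproduces it byte for byte.
#'
#' @param config A named list. Either `scenario` (arguments for
#'   [sim_scenario()]) for a synthetic run, or `genotypes` + `metadata`
#'   file paths for user-supplied data. Optional elements: `method`
#'   (default `"admixture"`), `condition` (default `"all_snps"`),
#'   `error_rate` (default 0.08), `maf_threshold` (0.05), `snp_missing_max`
#'   (0.10), `sample_missing_max` (0.10), `prune` (list of
#'   [prune_params()] arguments), `seed` (default 1).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `panel`, the `evaluation`
#'   (`ancestry_eval`), the `summary` list, and `paths` of written files.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  seed <- config$seed %||% 1
  method <- config$method %||% "admixture"
  condition <- config$condition %||% "all_snps"
  error_rate <- config$error_rate %||% 0.08
  maf_threshold <- config$maf_threshold %||% 0.05
  prune <- do.call(prune_params, config$prune %||% list())

  stage <- "configure"
  on.exit({
    if (!is.null(stage)) {
      writeLines(c("status: FAILED", paste0("failed_stage: ", stage)),
                 file.path(out_dir, "MANIFEST"))
    }
  })

  resolved <- config
  resolved$seed <- seed
  resolved$method <- method
  resolved$condition <- condition
  resolved$version <- as.character(utils::packageVersion("ancestrymix"))
  resolved$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(resolved, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  paths$config <- file.path(out_dir, "run_config.json")

  counts <- list()
  if (!is.null(config$scenario)) {
    stage <- "simulate"
    sc_args <- config$scenario
    sc_args$seed <- sc_args$seed %||% seed
    scn <- do.call(sim_scenario, sc_args)
    sim <- make_scenario(scn)
    panel <- sim$panel
    paths$genotypes <- file.path(out_dir, "reference_genotypes.tsv")
    write_genotype_tsv(panel$genotypes, paths$genotypes)
    paths$metadata <- file.path(out_dir, "metadata.tsv")
    readr::write_tsv(panel$samples, paths$metadata, progress = FALSE)
    if (!is.null(sim$truth)) {
      paths$truth <- file.path(out_dir, "truth.tsv")
      readr::write_tsv(sim$truth, paths$truth, progress = FALSE)
    }
  } else {
    stage <- "ingest"
    if (is.null(config$genotypes) || is.null(config$metadata)) {
      abort("Config needs either `scenario` or both `genotypes` and `metadata` paths.")
    }
    for (p in c(config$genotypes, config$metadata)) {
      if (!file.exists(p)) abort(paste0("Input path does not exist: ", p))
    }
    panel <- read_reference_panel(config$genotypes, config$metadata)
  }
  counts$samples_in <- n_samples(panel$genotypes)
  counts$snps_in <- n_snps(panel$genotypes)

  stage <- "qc"
  maf <- compute_maf(panel$genotypes)
  g <- filter_common(panel$genotypes, maf, threshold = maf_threshold)
  counts$snps_after_maf <- n_snps(g)
  g <- suppressMessages(filter_missingness(g,
                                           snp_max = config$snp_missing_max %||% 0.10,
                                           sample_max = config$sample_missing_max %||% 0.10))
  counts$snps_after_missingness <- n_snps(g)
  counts$samples_after_missingness <- n_samples(g)
  panel <- reference_panel(g, panel$samples)

  stage <- "prune"
  kept <- ld_prune(panel$genotypes, params = prune, reference_maf = maf)
  counts$snps_after_pruning <- length(kept)
  paths$kept_snps <- file.path(out_dir, "kept_snps.txt")
  writeLines(kept, paths$kept_snps)
  panel <- subset_panel(panel, snps = kept)

  stage <- "evaluate"
  snp_subset <- if (condition == "all_snps") NULL else config$snp_subset
  ev <- suppressMessages(withCallingHandlers(
    leave_one_population_out(panel, method = method, condition = condition,
                             error_rate = error_rate, snp_subset = snp_subset,
                             seed = seed),
    warning = function(w) invokeRestart("muffleWarning")))
  paths$assignments <- file.path(out_dir, "assignments.tsv")
  readr::write_tsv(ev$assignments, paths$assignments, progress = FALSE)

  stage <- "report"
  summary <- list(method = method, condition = condition, seed = seed,
                  counts = counts,
                  overall_error = ev$overall$error_rate,
                  overall_error_ci = c(ev$overall$lo, ev$overall$hi),
                  per_group = as.list(setNames(ev$per_group$error_rate,
                                               ev$per_group$group)),
                  failed_folds = ev$failed_folds)
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  paths$report <- file.path(out_dir, "report.md")
  writeLines(render_report(list(ev)), paths$report)

  stage <- NULL # success: no failure MANIFEST
  writeLines("status: OK", file.path(out_dir, "MANIFEST"))
  invisible(list(panel = panel, evaluation = ev, summary = summary,
                 paths = paths))
}

#' Render evaluation results as a markdown report
#'
#' Produces tables of per-group error rates with 95% confidence intervals
#' for every evaluation, and a slope/correlation table for every recovery
#' result. Regeneration from the same results is idempotent.
#'
#' @param results A list of `ancestry_eval` and/or `recovery_result`
#'   objects (may be empty).
#' @return A character vector of markdown lines.
#' @export
render_report <- function(results) {
  stopifnot(is.list(results))
  lines <- c("# Ancestry-inference evaluation report", "")
  evals <- Filter(function(x) inherits(x, "ancestry_eval"), results)
  recs <- Filter(function(x) inherits(x, "recovery_result"), results)
  if (length(evals) > 0) {
    lines <- c(lines, "## Classification error", "",
               "| method | condition | group | n | errors | error rate | 95% CI |",
               "|---|---|---|---|---|---|---|")
    for (ev in evals) {
      for (i in seq_len(nrow(ev$per_group))) {
        r <- ev$per_group[i, ]
        lines <- c(lines, sprintf("| %s | %s | %s | %d | %d | %.2f%% | [%.2f%%, %.2f%%] |",
                                  ev$method, ev$condition, r$group, r$n, r$errors,
                                  100 * r$error_rate, 100 * r$lo, 100 * r$hi))
      }
      lines <- c(lines, sprintf("| %s | %s | overall | %d | %d | %.2f%% | [%.2f%%, %.2f%%] |",
                                ev$method, ev$condition, ev$overall$n,
                                ev$overall$errors, 100 * ev$overall$error_rate,
                                100 * ev$overall$lo, 100 * ev$overall$hi))
    }
    lines <- c(lines, "")
  }
  if (length(recs) > 0) {
    lines <- c(lines, "## Admixture-proportion recovery", "",
               "| n | slope | intercept | r |", "|---|---|---|---|")
    for (rr in recs) {
      lines <- c(lines, sprintf("| %d | %.3f | %.3f | %.3f |",
                                rr$n, rr$slope, rr$intercept, rr$pearson_r))
    }
    lines <- c(lines, "")
  }
  lines
}
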