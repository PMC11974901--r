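#' Wilson score interval for a binomial proportion
#'
#' The 95% (by default) Wilson score interval for `k` successes out of `n`
#' trials. Chosen over the Wald interval because it behaves sensibly at
#' zero observed errors, where classification error rates of a good method
#' typically live.
#'
#' @param k Error (success) count, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(lo, hi)` within `[0, 1]`.
#' @export
#' @examples
#' wilson_ci(0, 100) # lower bound exactly 0
#' wilson_ci(2, 100) # ~ (0.0055, 0.0700)
wilson_ci <- function(k, n, conf = 0.95) {
  if (length(n) != 1 || n < 1) abort("`n` must be a single count >= 1.")
  if (k < 0 || k > n) abort("`k` must satisfy 0 <= k <= n.")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  # the bounds are exactly 0 at k = 0 and exactly 1 at k = n; computing them
  # through the general formula leaves floating-point residue
  c(lo = if (k == 0) 0 else max(0, centre - half),
    hi = if (k == n) 1 else min(1, centre + half))
}

# classify one query set against one reference panel with one method;
# returns tibble(sample_id, assigned_group)
classify_queries <- function(ref_panel, query, method, n_components = 5,
                             n_trees = 100, seed = 1) {
  method <- match.arg(method, c("admixture", "distance", "rf"))
  if (method == "admixture") {
    fit <- fit_supervised_admixture(ref_panel, query)
    calls <- assign_from_proportions(fit)
  } else {
    model <- fit_reference_pca(ref_panel, n_components = n_components)
    qs <- project_pca(model, query)
    calls <- if (method == "distance") {
      centroid_classify(model$scores, qs)
    } else {
      rf_classify(model$scores, qs, n_trees = n_trees, seed = seed)
    }
  }
  calls[, c("sample_id", "assigned_group")]
}

# per-fold reference preparation shared across error rates / methods:
# QC (reference MAF > maf_threshold, missingness) then LD pruning
prepare_fold <- function(panel, hold_out_samples, snp_subset, maf_threshold,
                         prune) {
  ref_samples <- setdiff(sample_ids(panel$genotypes), hold_out_samples)
  refp <- subset_panel(panel, samples = ref_samples, snps = snp_subset)
  maf <- compute_maf(refp$genotypes)
  g <- filter_common(refp$genotypes, maf, threshold = maf_threshold)
  g <- suppressMessages(filter_missingness(g))
  refp <- reference_panel(g, panel$samples)
  kept <- ld_prune(refp$genotypes, params = prune, reference_maf = maf)
  subset_panel(refp, snps = kept)
}

new_eval_result <- function(assignments, classes, condition, method,
                            failed_folds, class_col = "population") {
  conf <- table(factor(assignments$true_group, levels = classes),
                factor(assignments$assigned_group, levels = classes))
  per_group <- assignments |>
    dplyr::group_by(group = .data$true_group) |>
    dplyr::summarise(n = dplyr::n(), errors = sum(!.data$correct),
                     .groups = "drop") |>
    dplyr::mutate(error_rate = .data$errors / .data$n,
                  ci = purrr::map2(.data$errors, .data$n, wilson_ci),
                  lo = purrr::map_dbl(.data$ci, 1),
                  hi = purrr::map_dbl(.data$ci, 2)) |>
    dplyr::select(-"ci")
  per_unit <- assignments |>
    dplyr::group_by(unit = .data[[class_col]]) |>
    dplyr::summarise(n = dplyr::n(), errors = sum(!.data$correct),
                     error_rate = .data$errors / .data$n, .groups = "drop")
  k <- sum(!assignments$correct)
  n <- nrow(assignments)
  overall_ci <- wilson_ci(k, n)
  structure(list(assignments = assignments, confusion = conf,
                 per_group = per_group, per_population = per_unit,
                 overall = tibble(n = n, errors = k, error_rate = k / n,
                                  lo = overall_ci[["lo"]], hi = overall_ci[["hi"]]),
                 condition = condition, method = method,
                 failed_folds = failed_folds),
            class = "ancestry_eval")
}

#' Leave-one-population-out ancestry-inference error
#'
#' For every population in the panel, removes its individuals from the
#' reference, rebuilds the reference (MAF filter, missingness filter, LD
#' pruning — and, per method, PCA or group frequencies) on the reduced
#' panel, classifies the removed individuals, and compares assignments to
#' their population's true ancestry group. The three genotype conditions
#' mirror the usual study design: `all_snps` (the full panel), `sc_snps`
#' (restricted to `snp_subset`, a sparse panel of the scale recoverable
#' from scRNA-seq), and `sc_snps_error` (additionally injecting genotype
#' errors at `error_rate` into the held-out individuals' genotypes only).
#'
#' @param panel A [reference_panel()].
#' @param method One of `"admixture"`, `"distance"`, `"rf"`.
#' @param condition One of `"all_snps"`, `"sc_snps"`, `"sc_snps_error"`.
#' @param error_rate Genotype error rate for `sc_snps_error` (default
#'   0.08, the discordance measured for scRNA-seq genotype calls against
#'   arrays).
#' @param snp_subset Character vector of SNP ids defining the sparse panel
#'   (`NULL` = all SNPs).
#' @param seed Integer seed; per-fold error injection and the random forest
#'   derive sub-seeds from it.
#' @param prune [prune_params()] for the per-fold pruning.
#' @param maf_threshold Reference MAF cutoff (default 0.05).
#' @param n_components,n_trees Classifier settings.
#' @param folds Optional precomputed folds from [lopo_folds()]; lets a
#'   sweep or a multi-method comparison reuse the expensive per-fold
#'   reference preparation.
#' @return An `ancestry_eval` object: per-sample `assignments`, `confusion`
#'   matrix, `per_group` and `per_population` error tibbles with 95% Wilson
#'   CIs, `overall`, plus `condition`, `method`, `failed_folds`.
#' @export
leave_one_population_out <- function(panel, method = c("admixture", "distance", "rf"),
                                     condition = c("all_snps", "sc_snps", "sc_snps_error"),
                                     error_rate = 0.08, snp_subset = NULL, seed = 1,
                                     prune = prune_params(), maf_threshold = 0.05,
                                     n_components = 5, n_trees = 100, folds = NULL) {
  method <- match.arg(method)
  condition <- match.arg(condition)
  if (is.null(folds)) {
    folds <- lopo_folds(panel, snp_subset = snp_subset, prune = prune,
                        maf_threshold = maf_threshold)
  }
  groups <- panel_groups(panel)
  rows <- list()
  failed <- character(0)
  for (fold in folds) {
    query <- fold$query
    if (condition == "sc_snps_error") {
      query <- inject_genotype_errors(query, error_rate,
                                      derive_seed(seed, paste0("err-", fold$population)))
    }
    query <- query[, intersect(snp_ids(fold$reference$genotypes), snp_ids(query))]
    res <- tryCatch(
      suppressMessages(classify_queries(fold$reference, query, method,
                                        n_components = n_components,
                                        n_trees = n_trees,
                                        seed = derive_seed(seed, paste0("rf-", fold$population)))),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, fold$population)
      warn(paste0("Fold '", fold$population, "' failed: ", conditionMessage(res)))
      next
    }
    res$population <- fold$population
    res$true_group <- fold$true_group
    res$correct <- res$assigned_group == res$true_group
    rows[[fold$population]] <- res
  }
  assignments <- dplyr::bind_rows(rows)
  new_eval_result(assignments, groups, condition, method, failed)
}

#' Precompute leave-one-population-out folds
#'
#' Builds, for every population, the reduced QCed + pruned reference panel
#' and the held-out query matrix. Populations whose ancestry group would be
#' left with fewer than two populations in the reference trigger a warning
#' but are still evaluated.
#'
#' @inheritParams leave_one_population_out
#' @return A list of folds (`population`, `true_group`, `reference`,
#'   `query`), reusable across methods and error rates.
#' @export
lopo_folds <- function(panel, snp_subset = NULL, prune = prune_params(),
                       maf_threshold = 0.05) {
  pops <- panel_populations(panel)
  lapply(setNames(pops, pops), function(pop) {
    hold <- panel$samples$sample_id[panel$samples$population == pop]
    grp <- panel$samples$ancestry_group[panel$samples$population == pop][1]
    remaining <- panel$samples |>
      dplyr::filter(.data$ancestry_group == grp, .data$population != pop)
    if (length(unique(remaining$population)) < 2) {
      warn(paste0("Group '", grp, "' keeps fewer than 2 populations when '",
                  pop, "' is removed."))
    }
    reference <- suppressMessages(
      prepare_fold(panel, hold, snp_subset, maf_threshold, prune))
    query <- panel$genotypes[hold, ]
    if (!is.null(snp_subset)) query <- query[, intersect(snp_subset, snp_ids(query))]
    list(population = pop, true_group = grp, reference = reference, query = query)
  })
}

#' Genotype-error sweep
#'
#' Re-runs the leave-one-population-out evaluation over a grid of genotype
#' error rates with shared folds and seeds, so that only the error
#' injection differs between rates; rate 0 reproduces the error-free result
#' exactly.
#'
#' @inheritParams leave_one_population_out
#' @param rates Ascending numeric vector of error rates.
#' @return A tibble with one row per rate (`rate`, `n`, `errors`,
#'   `error_rate`, `lo`, `hi`) and the full `ancestry_eval` in a `result`
#'   list-column.
#' @export
error_rate_sweep <- function(panel, method = c("admixture", "distance", "rf"),
                             rates, snp_subset = NULL, seed = 1,
                             prune = prune_params(), maf_threshold = 0.05,
                             n_components = 5, n_trees = 100, folds = NULL) {
  method <- match.arg(method)
  stopifnot(length(rates) >= 1, !is.unsorted(rates))
  if (is.null(folds)) {
    folds <- lopo_folds(panel, snp_subset = snp_subset, prune = prune,
                        maf_threshold = maf_threshold)
  }
  res <- lapply(rates, function(r) {
    leave_one_population_out(panel, method = method, condition = "sc_snps_error",
                             error_rate = r, snp_subset = snp_subset, seed = seed,
                             n_components = n_components, n_trees = n_trees,
                             folds = folds)
  })
  dplyr::bind_cols(tibble(rate = rates),
                   dplyr::bind_rows(lapply(res, function(x) x$overall)),
                   tibble(result = res))
}

#' Admixture-proportion recovery statistics
#'
#' Ordinary least squares of estimated on true proportions (slope,
#' intercept) and the Pearson correlation — the concordance summary used to
#' compare admixture estimates from sparse panels against a gold standard.
#'
#' @param truth_q,est_q Paired per-sample proportions in `[0, 1]`, length
#'   >= 3.
#' @return A `recovery_result` with `slope`, `intercept`, `pearson_r`, `n`,
#'   and the paired `data` tibble.
#' @export
admixture_recovery <- function(truth_q, est_q) {
  stopifnot(length(truth_q) == length(est_q))
  if (length(truth_q) < 3) abort("Need at least 3 paired proportions.")
  if (var(truth_q) == 0) abort("Zero variance in the gold-standard proportions.")
  fit <- lm(est_q ~ truth_q)
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 pearson_r = cor(truth_q, est_q), n = length(truth_q),
                 data = tibble(truth = truth_q, estimate = est_q)),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> n=%d: slope = %.3f, intercept = %.3f, r = %.3f\n",
              x$n, x$slope, x$intercept, x$pearson_r))
  invisible(x)
}

#' @export
glance.recovery_result <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, pearson_r = x$pearson_r,
         n = x$n)
}

#' @export
tidy.recovery_result <- function(x, ...) x$data

#' @export
autoplot.recovery_result <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$truth, .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "gold-standard proportion", y = "estimated proportion",
                  subtitle = sprintf("slope = %.2f, r = %.2f", object$slope,
                                     object$pearson_r)) +
    ggplot2::theme_minimal()
}

#' Simulated admixture-recovery experiment
#'
#' The synthetic analogue of validating admixture estimates from sparse
#' panels against a gold standard: K ancestry groups are differentiated at
#' `fst`, a labelled reference panel is drawn, query individuals receive
#' mixing proportions `q ~ Dirichlet(1, ..., 1)` and genotypes from the
#' admixture generative model, optionally corrupted at `error_rate`; the
#' supervised admixture estimator is then fitted and, per ancestry
#' component, the estimated proportions are regressed on the true ones.
#'
#' @param n_groups Number of ancestry groups (default 3).
#' @param n_snps Panel size (default 5000).
#' @param ref_per_group Reference individuals per group (default 100).
#' @param n_query Admixed query individuals (default 50).
#' @param fst Balding-Nichols differentiation (default 0.1).
#' @param error_rate Genotype error rate injected into query genotypes
#'   (default 0).
#' @param seed Integer seed.
#' @return A list: `truth_q` and `est_q` (query-by-group matrices),
#'   `recovery` (tibble with one row per group: `group`, `slope`,
#'   `intercept`, `pearson_r`, `n`), `fit` (the `admixture_fit`), and
#'   `panel`.
#' @export
simulate_admixture_recovery <- function(n_groups = 3, n_snps = 5000,
                                        ref_per_group = 100, n_query = 50,
                                        fst = 0.1, error_rate = 0, seed = 1) {
  groups <- c("AFR", "AMR", "EAS", "EUR", "MEA", "SAS")[seq_len(n_groups)]
  snps <- make_snp_table(n_snps)
  fr <- sample_frequencies(n_snps, n_groups, fst, derive_seed(seed, "rec-freq"),
                           group_labels = groups)
  ref_list <- lapply(groups, function(g) {
    sample_genotypes(fr$group_freq[g, ], ref_per_group,
                     derive_seed(seed, paste0("rec-ref-", g)),
                     snps = snps, sample_prefix = paste0(g, "_i"))
  })
  d <- do.call(rbind, lapply(ref_list, function(x) x$dosages))
  panel <- reference_panel(
    genotype_matrix(d, snps),
    tibble(sample_id = rownames(d),
           population = rep(groups, each = ref_per_group),
           ancestry_group = rep(groups, each = ref_per_group)))
  truth_q <- with_local_seed(derive_seed(seed, "rec-q"), {
    q <- matrix(stats::rgamma(n_query * n_groups, shape = 1), n_query)
    q / rowSums(q)
  })
  colnames(truth_q) <- groups
  q_list <- lapply(seq_len(n_query), function(i) {
    sample_admixed_genotypes(fr$group_freq, truth_q[i, ], 1,
                             derive_seed(seed, paste0("rec-q-", i)),
                             snps = snps, sample_prefix = sprintf("q%03d_i", i))
  })
  qd <- do.call(rbind, lapply(q_list, function(x) x$dosages))
  queries <- genotype_matrix(qd, snps)
  queries <- inject_genotype_errors(queries, error_rate,
                                    derive_seed(seed, "rec-err"))
  rownames(truth_q) <- rownames(qd)
  fit <- fit_supervised_admixture(panel, queries)
  est_q <- fit$Q[fit$query_ids, , drop = FALSE]
  recovery <- dplyr::bind_rows(lapply(groups, function(g) {
    r <- admixture_recovery(truth_q[, g], est_q[, g])
    tibble(group = g, slope = r$slope, intercept = r$intercept,
           pearson_r = r$pearson_r, n = r$n)
  }))
  list(truth_q = truth_q, est_q = est_q, recovery = recovery, fit = fit,
       panel = panel)
}

#' Select gold-standard admixed individuals
#'
#' From a full-panel admixture fit, selects the query individuals whose
#' estimated proportion for `group` strictly exceeds `threshold` (default
#' 1/8 — at least one great-grandparent's worth of that ancestry), and
#' returns those proportions as the gold standard for recovery analyses on
#' sparser panels.
#'
#' @param fit An [fit_supervised_admixture()] fit over the full SNP panel.
#' @param group Ancestry-group label.
#' @param threshold Strict lower bound (default `1/8`).
#' @return A tibble `sample_id`, `gold` (possibly empty, with a warning).
#' @export
gold_standard_selection <- function(fit, group, threshold = 1 / 8) {
  stopifnot(inherits(fit, "admixture_fit"))
  if (!group %in% fit$groups) abort(paste0("Unknown group: ", group))
  q <- fit$Q[fit$query_ids, group]
  sel <- q > threshold
  if (!any(sel)) warn("No individual exceeds the gold-standard threshold.")
  tibble(sample_id = fit$query_ids[sel], gold = unname(q[sel]))
}

#' Within-group (sub-population) inference error
#'
#' Tests whether populations *within* one ancestry group can be told apart:
#' the group's populations become the classes and each individual is held
#' out in turn (leave-one-individual-out — removing a whole population
#' would remove its class), with the reference rebuilt per fold under the
#' same QC/pruning as the main evaluation. Singleton populations are
#' excluded with a warning.
#'
#' @inheritParams leave_one_population_out
#' @param group The ancestry-group label to analyse.
#' @return An `ancestry_eval` whose classes are the group's populations.
#' @export
within_group_inference <- function(panel, group,
                                   method = c("admixture", "distance", "rf"),
                                   condition = c("sc_snps", "sc_snps_error"),
                                   error_rate = 0.08, snp_subset = NULL, seed = 1,
                                   prune = prune_params(), maf_threshold = 0.05,
                                   n_components = 5, n_trees = 100) {
  method <- match.arg(method)
  condition <- match.arg(condition)
  sub <- panel$samples |> dplyr::filter(.data$ancestry_group == group)
  pop_sizes <- table(sub$population)
  single <- names(pop_sizes)[pop_sizes < 2]
  if (length(single) > 0) {
    warn(paste0("Excluding singleton population(s): ", paste(single, collapse = ", ")))
    sub <- sub |> dplyr::filter(!.data$population %in% single)
  }
  if (length(unique(sub$population)) < 2) {
    abort(paste0("Group '", group, "' has fewer than 2 usable populations."))
  }
  # classes are populations: relabel ancestry_group := population
  meta <- sub |> dplyr::mutate(ancestry_group = .data$population)
  gp <- if (is.null(snp_subset)) panel$genotypes[sub$sample_id, ] else
    panel$genotypes[sub$sample_id, intersect(snp_subset, snp_ids(panel$genotypes))]
  sub_panel <- reference_panel(gp, meta)
  classes <- sort(unique(meta$population))
  rows <- list()
  failed <- character(0)
  for (id in sub$sample_id) {
    reference <- suppressMessages(
      prepare_fold(sub_panel, id, NULL, maf_threshold, prune))
    query <- sub_panel$genotypes[id, , drop = FALSE]
    if (condition == "sc_snps_error") {
      query <- inject_genotype_errors(query, error_rate,
                                      derive_seed(seed, paste0("err-", id)))
    }
    query <- query[, intersect(snp_ids(reference$genotypes), snp_ids(query))]
    res <- tryCatch(
      suppressMessages(classify_queries(reference, query, method,
                                        n_components = n_components,
                                        n_trees = n_trees,
                                        seed = derive_seed(seed, paste0("rf-", id)))),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, id)
      next
    }
    res$population <- sub$population[sub$sample_id == id]
    res$true_group <- res$population
    res$correct <- res$assigned_group == res$true_group
    rows[[id]] <- res
  }
  assignments <- dplyr::bind_rows(rows)
  new_eval_result(assignments, classes, condition, method, failed)
}

#' @export
print.ancestry_eval <- function(x, ...) {
  cat(sprintf("<ancestry_eval> method=%s condition=%s: overall error %.2f%% (%d/%d), 95%% CI [%.2f%%, %.2f%%]\n",
              x$method, x$condition, 100 * x$overall$error_rate,
              x$overall$errors, x$overall$n, 100 * x$overall$lo, 100 * x$overall$hi))
  if (length(x$failed_folds) > 0) {
    cat("  failed folds:", paste(x$failed_folds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.ancestry_eval <- function(x, ...) {
  dplyr::mutate(x$per_group, method = x$method, condition = x$condition)
}

#' @export
glance.ancestry_eval <- function(x, ...) {
  dplyr::mutate(x$overall, method = x$method, condition = x$condition,
                n_failed_folds = length(x$failed_folds))
}

#' @export
autoplot.ancestry_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_group,
                  ggplot2::aes(.data$group, .data$error_rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "classification error",
                  subtitle = sprintf("%s, %s", object$method, object$condition)) +
    ggplot2::theme_minimal()
}
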