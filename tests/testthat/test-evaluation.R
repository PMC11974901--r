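test_that("Wilson intervals match the closed form and its edge cases", {
  expect_equal(wilson_ci(0, 100)[["lo"]], 0)
  expect_equal(wilson_ci(100, 100)[["hi"]], 1)
  ci <- wilson_ci(2, 100)
  expect_equal(ci[["lo"]], 0.0055, tolerance = 1e-2)
  expect_equal(ci[["hi"]], 0.0700, tolerance = 1e-3)
  expect_error(wilson_ci(1, 0), ">= 1")
  expect_error(wilson_ci(5, 3), "<= n")
})

test_that("recovery regression reproduces hand-computed OLS", {
  r <- admixture_recovery(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(r$slope, 1)
  expect_equal(r$pearson_r, 1)
  r2 <- admixture_recovery(c(0.1, 0.5, 0.9), c(0.9, 0.5, 0.1))
  expect_equal(r2$slope, -1)
  expect_equal(r2$pearson_r, -1)
  # truth (0.2, 0.5, 0.8), estimate (0.3, 0.5, 0.7): slope = 0.04/0.06
  r3 <- admixture_recovery(c(0.2, 0.5, 0.8), c(0.3, 0.5, 0.7))
  expect_equal(r3$slope, 2 / 3, tolerance = 1e-12)
  expect_equal(r3$pearson_r, 1, tolerance = 1e-12) # collinear
  expect_equal(r3$intercept, 0.5 - (2 / 3) * 0.5, tolerance = 1e-12)
  expect_error(admixture_recovery(c(0.5, 0.5, 0.5), c(0.1, 0.2, 0.3)),
               "Zero variance")
  expect_error(admixture_recovery(c(0.1, 0.2), c(0.1, 0.2)), "at least 3")
})

test_that("gold-standard selection is strictly greater than the threshold", {
  Q <- rbind(ref1 = c(1, 0), a = c(0.125, 0.875), b = c(0.1250001, 0.8749999),
             c = c(0.5, 0.5))
  colnames(Q) <- c("EUR", "AFR")
  fit <- structure(list(Q = Q, groups = c("AFR", "EUR"),
                        query_ids = c("a", "b", "c"), ref_ids = "ref1"),
                   class = "admixture_fit")
  sel <- gold_standard_selection(fit, "EUR")
  expect_equal(sel$sample_id, c("b", "c")) # exactly 1/8 excluded
  expect_equal(sel$gold, c(0.1250001, 0.5))
  expect_warning(out <- gold_standard_selection(fit, "EUR", threshold = 0.9),
                 "No individual")
  expect_equal(nrow(out), 0)
  expect_error(gold_standard_selection(fit, "SAS"), "Unknown group")
})

small_lopo_panel <- function(seed = 10) {
  # 20 samples/population keeps enough SNPs through per-fold pruning: with
  # far fewer samples, null-sampling r-squared routinely exceeds 0.1 and the
  # windowed pruning cascades
  toy_panel(n_groups = 3, pops_per_group = 2, n_per_pop = 20, n_snps = 400,
            fst = 0.1, fst_within = 0.01, seed = seed, missing_rate = 0.05)
}

test_that("LOPO folds never leak held-out samples and cover each population once", {
  sim <- small_lopo_panel()
  folds <- suppressWarnings(suppressMessages(lopo_folds(sim$panel)))
  expect_setequal(names(folds), panel_populations(sim$panel))
  for (fold in folds) {
    held <- sample_ids(fold$query)
    expect_setequal(held, sim$panel$samples$sample_id[
      sim$panel$samples$population == fold$population])
    expect_length(intersect(held, sample_ids(fold$reference$genotypes)), 0)
  }
})

test_that("LOPO error accounting is consistent and method-invariant in totals", {
  sim <- small_lopo_panel()
  folds <- suppressWarnings(suppressMessages(lopo_folds(sim$panel)))
  ev_adm <- suppressWarnings(suppressMessages(leave_one_population_out(
    sim$panel, "admixture", "all_snps", folds = folds)))
  ev_dst <- suppressWarnings(suppressMessages(leave_one_population_out(
    sim$panel, "distance", "all_snps", folds = folds)))
  # confusion totals do not depend on the method
  expect_equal(rowSums(ev_adm$confusion), rowSums(ev_dst$confusion))
  # overall error consistent with the confusion matrix
  off_diag <- sum(ev_adm$confusion) - sum(diag(ev_adm$confusion))
  expect_equal(ev_adm$overall$errors, off_diag)
  expect_equal(ev_adm$overall$error_rate,
               off_diag / sum(ev_adm$confusion))
  expect_equal(sum(ev_adm$per_group$n), nrow(ev_adm$assignments))
  expect_true(all(ev_adm$per_group$lo <= ev_adm$per_group$error_rate &
                    ev_adm$per_group$error_rate <= ev_adm$per_group$hi))
  # a strongly differentiated panel classifies held-out populations almost
  # perfectly even at this reduced scale (400 SNPs, 2 populations/group)
  expect_lte(ev_adm$overall$error_rate, 0.05)
  expect_lte(ev_dst$overall$error_rate, 0.05)
})

test_that("identical population frequencies give chance-level error", {
  base <- sample_genotypes(runif(300, 0.2, 0.8), 48, seed = 11)
  panel <- reference_panel(base, tibble::tibble(
    sample_id = sample_ids(base),
    population = rep(sprintf("p%d", 1:6), each = 8),
    ancestry_group = rep(c("A", "B", "C"), each = 16)))
  ev <- suppressWarnings(suppressMessages(leave_one_population_out(
    panel, "distance", "all_snps")))
  expect_gt(ev$overall$error_rate, 0.35) # chance is 1 - 1/3
  expect_lt(ev$overall$error_rate, 0.95)
})

test_that("the error sweep shares folds so rate 0 reproduces the plain run", {
  sim <- small_lopo_panel()
  sub <- snp_ids(sim$panel$genotypes)[1:200]
  folds <- suppressWarnings(suppressMessages(lopo_folds(sim$panel,
                                                        snp_subset = sub)))
  plain <- suppressWarnings(suppressMessages(leave_one_population_out(
    sim$panel, "admixture", "sc_snps", snp_subset = sub, seed = 3,
    folds = folds)))
  sweep <- suppressWarnings(suppressMessages(error_rate_sweep(
    sim$panel, "admixture", rates = c(0, 0.3), snp_subset = sub, seed = 3,
    folds = folds)))
  expect_identical(sweep$result[[1]]$assignments, plain$assignments)
  expect_identical(sweep$rate, c(0, 0.3))
  expect_error(error_rate_sweep(sim$panel, "admixture", rates = c(0.1, 0)),
               "unsorted|sorted", class = NULL)
})

test_that("within-group inference separates differentiated sub-populations", {
  sim <- toy_panel(n_groups = 2, pops_per_group = 2, n_per_pop = 30,
                   n_snps = 500, fst = 0.2, fst_within = 0.05, seed = 12,
                   missing_rate = 0)
  ev <- suppressWarnings(suppressMessages(within_group_inference(
    sim$panel, "AFR", method = "admixture", condition = "sc_snps")))
  expect_lte(ev$overall$error_rate, 0.05)
  expect_setequal(rownames(ev$confusion),
                  unique(sim$panel$samples$population[
                    sim$panel$samples$ancestry_group == "AFR"]))
  # reproducibility under the same seed
  ev2 <- suppressWarnings(suppressMessages(within_group_inference(
    sim$panel, "AFR", method = "admixture", condition = "sc_snps")))
  expect_identical(ev$assignments, ev2$assignments)
})

test_that("tidy and glance expose evaluation results as tibbles", {
  sim <- small_lopo_panel()
  ev <- suppressWarnings(suppressMessages(leave_one_population_out(
    sim$panel, "distance", "all_snps")))
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("group", "error_rate", "lo", "hi", "method") %in% names(td)))
  gl <- glance(ev)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$method, "distance")
  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
})
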