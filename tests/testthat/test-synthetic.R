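test_that("Balding-Nichols draws have the stated moments", {
  fr <- sample_frequencies(4000, 4, fst = 0.1, seed = 2)
  expect_true(all(fr$ancestral >= 0.05 & fr$ancestral <= 0.95))
  # E[f | p] = p, Var[f | p] = p(1-p) fst: regress empirical group moments
  dev <- sweep(fr$group_freq, 2, fr$ancestral)
  expect_lt(abs(mean(dev)), 0.01)
  vr <- colMeans(dev^2) / (fr$ancestral * (1 - fr$ancestral))
  expect_equal(mean(vr), 0.1, tolerance = 0.015)

  # small-fst limit: frequencies collapse onto the ancestral values
  fr0 <- sample_frequencies(500, 3, fst = 1e-4, seed = 3)
  expect_lt(max(abs(sweep(fr0$group_freq, 2, fr0$ancestral))), 0.05)

  # nested draws preserve the group mean
  nested <- sample_population_frequencies_nested(
    fr$group_freq[, 1:2000, drop = FALSE] |>
      (\(x) {rownames(x) <- paste0("G", 1:4); x})(), 0.01, 3, seed = 4)
  expect_equal(nrow(nested$pop_freq), 12)
  for (g in paste0("G", 1:4)) {
    pops <- nested$pop_map$population[nested$pop_map$ancestry_group == g]
    dev <- sweep(nested$pop_freq[pops, , drop = FALSE], 2,
                 fr$group_freq[match(g, paste0("G", 1:4)), 1:2000])
    expect_lt(abs(mean(dev)), 0.01)
  }
})

test_that("simulated genotypes reproduce the target FST under Weir-Cockerham", {
  fr <- sample_frequencies(1500, 5, fst = 0.1, seed = 5)
  gms <- lapply(1:5, function(k) {
    sample_genotypes(fr$group_freq[k, ], 50, seed = 100 + k)$dosages
  })
  d <- do.call(rbind, gms)
  pops <- rep(paste0("G", 1:5), each = 50)
  expect_equal(oracle_wc_fst(d, pops), 0.1, tolerance = 0.02)

  # nested scenario: within-group differentiation far below between-group
  sim <- toy_panel(n_groups = 4, pops_per_group = 3, n_per_pop = 25,
                   n_snps = 1200, fst = 0.1, fst_within = 0.01, seed = 6)
  lab <- sim$panel$samples
  d2 <- sim$panel$genotypes$dosages
  between <- oracle_wc_fst(d2, lab$ancestry_group)
  g1 <- lab$ancestry_group == lab$ancestry_group[1]
  within <- oracle_wc_fst(d2[g1, ], lab$population[g1])
  expect_gt(between, 5 * within)
  expect_equal(within, 0.01, tolerance = 0.01)
})

test_that("genotype sampling follows Binomial(2, f)", {
  expect_true(all(sample_genotypes(rep(0, 50), 20, seed = 1)$dosages == 0))
  expect_true(all(sample_genotypes(rep(1, 50), 20, seed = 1)$dosages == 2))
  m <- sample_genotypes(rep(0.5, 500), 20, seed = 2) # 10,000 draws
  expect_equal(mean(m$dosages), 1.0, tolerance = 0.03)
})

test_that("admixed genotypes follow the mixture law", {
  pf <- rbind(rep(1, 400), rep(0, 400))
  rownames(pf) <- c("A", "B")
  m <- sample_admixed_genotypes(pf, c(A = 0.5, B = 0.5), 25, seed = 3)
  # each copy is ALT with probability 0.5 independently
  expect_equal(mean(m$dosages), 1.0, tolerance = 0.05)
  expect_equal(mean(m$dosages == 1), 0.5, tolerance = 0.05)

  # one-hot q reduces to plain HWE sampling from that population
  pf2 <- rbind(runif(300, 0.1, 0.9), runif(300, 0.1, 0.9))
  rownames(pf2) <- c("A", "B")
  m2 <- sample_admixed_genotypes(pf2, c(A = 1, B = 0), 400, seed = 4)
  expect_equal(unname(colMeans(m2$dosages) / 2), pf2["A", ], tolerance = 0.11)

  # marginal allele frequency equals sum_k q_k f_kj
  q <- c(A = 0.3, B = 0.7)
  m3 <- sample_admixed_genotypes(pf2, q, 2500, seed = 5)
  expect_equal(mean(colMeans(m3$dosages) / 2 - as.vector(q %*% pf2)), 0,
               tolerance = 0.003)
})

test_that("SNP subsampling is order-preserving and deterministic", {
  m <- sample_genotypes(runif(200, 0.1, 0.9), 5, seed = 6)
  expect_identical(subsample_snps(m, 200, seed = 1)$dosages, m$dosages)
  s1 <- subsample_snps(m, 50, seed = 7)
  s2 <- subsample_snps(m, 50, seed = 7)
  expect_identical(s1$dosages, s2$dosages)
  expect_identical(snp_ids(s1), sort(snp_ids(s1))) # panel order preserved
  expect_equal(n_snps(s1), 50)
})

test_that("missingness injection hits cells at the stated rate", {
  m <- sample_genotypes(runif(500, 0.2, 0.8), 100, seed = 8)
  expect_identical(inject_missingness(m, 0, seed = 1)$dosages, m$dosages)
  expect_true(all(is.na(inject_missingness(m, 1, seed = 1)$dosages)))
  rate <- 0.1
  out <- inject_missingness(m, rate, seed = 9)
  frac <- mean(is.na(out$dosages))
  expect_lt(abs(frac - rate), 3 * sqrt(rate * (1 - rate) / length(m$dosages)))
})

test_that("genotype errors substitute uniformly among the other two values", {
  m <- sample_genotypes(runif(300, 0.2, 0.8), 60, seed = 10)
  m <- inject_missingness(m, 0.05, seed = 11)
  expect_identical(inject_genotype_errors(m, 0, seed = 1)$dosages, m$dosages)

  all_err <- inject_genotype_errors(m, 1, seed = 12)
  obs <- !is.na(m$dosages)
  expect_true(all(all_err$dosages[obs] != m$dosages[obs]))
  expect_identical(is.na(all_err$dosages), is.na(m$dosages)) # missing untouched

  # altered cells never equal their originals; both substitutions occur
  some <- inject_genotype_errors(m, 0.2, seed = 13)
  changed <- which(obs & some$dosages != m$dosages)
  expect_true(length(changed) > 0)
  expect_true(all(some$dosages[changed] != m$dosages[changed]))
  hets <- changed[m$dosages[changed] == 1]
  expect_true(all(c(0, 2) %in% some$dosages[hets]))
})

test_that("scenarios are pure functions of their seed", {
  scn <- sim_scenario(n_groups = 3, populations_per_group = 2,
                      samples_per_population = 5, n_snps = 100,
                      admixed = tibble::tibble(count = 4, AFR = 0.5,
                                               AMR = 0.25, EAS = 0.25),
                      seed = 42)
  a <- make_scenario(scn)
  b <- make_scenario(scn)
  expect_identical(a$panel$genotypes$dosages, b$panel$genotypes$dosages)
  expect_identical(a$queries$dosages, b$queries$dosages)
  expect_identical(a$truth, b$truth)

  expect_equal(n_samples(a$panel$genotypes), 3 * 2 * 5)
  expect_equal(nrow(a$truth), 4)
  expect_equal(a$truth$ancestry_group, rep("AFR", 4)) # argmax of q
  expect_equal(a$truth$q_AMR, rep(0.25, 4))

  # K = 6, 3 pops/group, 20 samples/pop panel size arithmetic
  full <- sim_scenario(seed = 1)
  expect_equal(full$n_groups * full$populations_per_group *
                 full$samples_per_population, 360)
})

test_that("the generative model maximizes its own likelihood at the truth", {
  fr <- sample_frequencies(4000, 3, fst = 0.1, seed = 14,
                           group_labels = c("A", "B", "C"))
  q <- c(A = 0.5, B = 0.3, C = 0.2)
  m <- sample_admixed_genotypes(fr$group_freq, q, 1, seed = 15)
  F <- pmin(pmax(fr$group_freq, 1e-6), 1 - 1e-6)
  ll_true <- admixture_loglik(m$dosages, matrix(q, 1), F)
  for (shift in list(c(0.2, -0.1, -0.1), c(-0.2, 0.2, 0), c(0.1, 0.1, -0.2))) {
    ll_alt <- admixture_loglik(m$dosages, matrix(q + shift, 1), F)
    expect_gt(ll_true, ll_alt)
  }
})
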