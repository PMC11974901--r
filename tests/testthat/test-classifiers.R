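test_that("proportions are assigned by argmax with lexicographic ties", {
  q <- rbind(c(0.7, 0.2, 0.1), c(0.5, 0.5, 0.0), c(0, 0, 1))
  colnames(q) <- c("AFR", "EUR", "EAS")
  rownames(q) <- c("a", "b", "c")
  calls <- assign_from_proportions(q)
  expect_equal(calls$assigned_group, c("AFR", "AFR", "EAS"))
  expect_equal(names(calls), c("sample_id", "AFR", "EAS", "EUR", "assigned_group"))
  q0 <- rbind(c(0, 0, 0))
  colnames(q0) <- c("A", "B", "C")
  rownames(q0) <- "z"
  expect_error(assign_from_proportions(q0), "All-zero")
})

test_that("centroid classification is exact at centroids and ties break lexicographically", {
  ref <- tibble::tibble(sample_id = sprintf("r%d", 1:4),
                        ancestry_group = c("A", "A", "B", "B"),
                        PC1 = c(-1, -3, 1, 3), PC2 = c(0, 0, 0, 0))
  # centroids: A at (-2, 0), B at (2, 0)
  query <- tibble::tibble(sample_id = c("at_A", "tie", "near_B"),
                          PC1 = c(-2, 0, 1.5), PC2 = c(0, 0, 0))
  calls <- centroid_classify(ref, query)
  expect_equal(calls$assigned_group, c("A", "A", "B"))
  expect_equal(calls$A[1], 1) # zero distance -> one-hot pseudo-score
  expect_equal(calls$A + calls$B, rep(1, 3))

  expect_error(centroid_classify(ref[0, ], query), "Empty")
})

test_that("centroid and RF classify a separable synthetic panel correctly", {
  sim <- toy_panel(n_groups = 3, n_per_pop = 20, n_snps = 500, seed = 6,
                   missing_rate = 0.05)
  # hold out 5 samples per group
  ids <- sim$panel$samples
  hold <- unlist(lapply(split(ids$sample_id, ids$ancestry_group), head, 5))
  train <- reference_panel(sim$panel$genotypes[setdiff(ids$sample_id, hold), ],
                           ids)
  model <- suppressMessages(fit_reference_pca(train))
  qs <- project_pca(model, sim$panel$genotypes[hold, ])
  truth <- ids$ancestry_group[match(hold, ids$sample_id)]

  cc <- centroid_classify(model$scores, qs)
  expect_equal(cc$assigned_group, truth)

  rf <- rf_classify(model$scores, qs, seed = 11)
  expect_equal(rf$assigned_group, truth)
  # deep-in-cluster training point gets high probability
  self <- rf_classify(model$scores, model$scores[1, ], seed = 11)
  expect_gte(self[[self$assigned_group[1]]][1], 0.9)
  # determinism under the same seed
  rf2 <- rf_classify(model$scores, qs, seed = 11)
  expect_identical(rf, rf2)
  # permutation equivariance in query order
  perm <- c(3, 1, 2, seq(4, nrow(qs)))
  rf3 <- rf_classify(model$scores, qs[perm, ], seed = 11)
  expect_equal(rf3$assigned_group, rf$assigned_group[perm])
  cc3 <- centroid_classify(model$scores, qs[perm, ])
  expect_equal(cc3$assigned_group, cc$assigned_group[perm])

  one_class <- model$scores[model$scores$ancestry_group == "AFR", ]
  expect_error(rf_classify(one_class, qs), "at least 2")
})

test_that("group frequencies match direct counting, with clamping and fallback", {
  d <- rbind(c(0L, 0L, NA), c(2L, 0L, NA), c(1L, 0L, 2L), c(2L, 0L, 0L))
  rownames(d) <- sprintf("i%d", 1:4)
  panel <- reference_panel(gm(d), tibble::tibble(
    sample_id = rownames(d), population = c("p1", "p1", "p2", "p2"),
    ancestry_group = c("G1", "G1", "G2", "G2")))
  expect_warning(f <- group_frequencies(panel), "panel-wide") # G1 empty at s003
  expect_equal(f["G1", "s001"], 0.5)        # dosages 0, 2
  expect_equal(f["G1", "s002"], 1e-6)       # all-REF clamped
  expect_equal(f["G2", "s003"], 0.5)        # dosages 2, 0
  expect_equal(f["G1", "s003"], f["G2", "s003"]) # G1 has no calls: panel-wide

  # group with no calls at a SNP falls back to the panel-wide frequency
  dd <- d; dd[3:4, 1] <- NA
  panel2 <- reference_panel(gm(dd), panel$samples)
  expect_warning(f3 <- group_frequencies(panel2), "panel-wide")
  expect_equal(f3["G2", "s001"], f3["G1", "s001"])

  # random panel vs a literal counting oracle
  sim <- toy_panel(n_groups = 3, n_per_pop = 12, n_snps = 120, seed = 7,
                   missing_rate = 0.1)
  f4 <- group_frequencies(sim$panel)
  for (g in panel_groups(sim$panel)) {
    sub <- sim$panel$genotypes$dosages[
      sim$panel$samples$ancestry_group == g, , drop = FALSE]
    manual <- apply(sub, 2, function(col) sum(col, na.rm = TRUE) /
                      (2 * sum(!is.na(col))))
    manual <- pmin(pmax(manual, 1e-6), 1 - 1e-6)
    expect_equal(unname(f4[g, ]), unname(manual))
  }
})

test_that("the admixture log-likelihood matches its closed form and oracle", {
  # K = 1, f = 0.5, one SNP, g = 1
  expect_equal(admixture_loglik(matrix(1L, 1, 1), matrix(1, 1, 1),
                                matrix(0.5, 1, 1)), log(0.5) + log(0.5))
  # all cells missing contribute zero
  expect_equal(admixture_loglik(matrix(NA_integer_, 2, 3),
                                matrix(1, 2, 1), matrix(0.5, 1, 3)), 0)
  # random instances vs the double-loop oracle
  withr::with_seed(21, {
    for (rep in 1:3) {
      n <- sample(3:8, 1); m <- sample(5:15, 1); K <- sample(2:4, 1)
      G <- matrix(sample(c(0:2, NA), n * m, replace = TRUE), n, m)
      Q <- matrix(rgamma(n * K, 1), n); Q <- Q / rowSums(Q)
      F <- matrix(runif(K * m, 0.05, 0.95), K)
      expect_equal(admixture_loglik(G, Q, F), oracle_loglik(G, Q, F),
                   tolerance = 1e-12)
    }
  })
  expect_error(admixture_loglik(matrix(1L, 1, 1), matrix(NaN, 1, 1),
                                matrix(0.5, 1, 1)), "NA/NaN")
})

test_that("em_step has the analytic stationary points and preserves the simplex", {
  F <- rbind(1 - 1e-6, 1e-6) # K = 2, one SNP, f1 -> 1, f2 -> 0
  # g = 1: q = (0.5, 0.5) is stationary
  out <- em_step(matrix(1L, 1, 1), matrix(0.5, 1, 2), F, frozen_F = TRUE)
  expect_equal(as.numeric(out$Q), c(0.5, 0.5), tolerance = 1e-9)
  # g = 2: q converges to (1, 0)
  Q <- matrix(0.5, 1, 2)
  for (i in 1:50) Q <- em_step(matrix(2L, 1, 1), Q, F, frozen_F = TRUE)$Q
  expect_equal(as.numeric(Q), c(1, 0), tolerance = 1e-4)

  # random instance: simplex preserved, log-likelihood never decreases
  withr::with_seed(33, {
    n <- 6; m <- 40; K <- 3
    G <- matrix(sample(c(0:2, NA), n * m, replace = TRUE,
                       prob = c(0.3, 0.3, 0.3, 0.1)), n, m)
    Q <- matrix(rgamma(n * K, 1), n); Q <- Q / rowSums(Q)
    F <- matrix(runif(K * m, 0.05, 0.95), K)
    ll <- admixture_loglik(G, Q, F)
    for (i in 1:100) {
      upd <- em_step(G, Q, F)
      Q <- upd$Q; F <- upd$F
      expect_equal(rowSums(Q), rep(1, n), tolerance = 1e-12)
      ll_new <- admixture_loglik(G, Q, F)
      expect_gte(ll_new, ll - 1e-9)
      ll <- ll_new
    }
  })

  # frozen rows and frozen F stay fixed
  withr::with_seed(34, {
    G <- matrix(sample(0:2, 20, replace = TRUE), 4, 5)
    Q <- matrix(rgamma(8, 1), 4); Q <- Q / rowSums(Q)
    F <- matrix(runif(10, 0.2, 0.8), 2)
    out <- em_step(G, Q, F, frozen_q_rows = c(1, 3), frozen_F = TRUE)
    expect_equal(out$Q[c(1, 3), ], Q[c(1, 3), ])
    expect_identical(out$F, F)
  })
})

test_that("supervised fits recover pure-group queries and flag flat likelihoods", {
  sim <- toy_panel(n_groups = 3, n_per_pop = 20, n_snps = 500, seed = 8,
                   missing_rate = 0.05)
  # a query duplicating a reference individual lands on its group
  dup <- sim$panel$genotypes[3, ]
  rownames(dup$dosages) <- "query_dup"
  fit <- suppressMessages(fit_supervised_admixture(sim$panel, dup))
  grp <- sim$panel$samples$ancestry_group[3]
  expect_gte(fit$Q["query_dup", grp], 0.9)
  expect_true(all(diff(fit$loglik_trace) > -1e-9))
  expect_equal(unname(rowSums(fit$Q)), rep(1, nrow(fit$Q)), tolerance = 1e-8)

  # literally identical group frequencies leave the likelihood flat and the
  # proportions at their uniform start
  base <- sample_genotypes(runif(300, 0.2, 0.8), 20, seed = 9)
  d3 <- rbind(base$dosages, base$dosages, base$dosages)
  rownames(d3) <- sprintf("i%03d", seq_len(60))
  panel_flat <- reference_panel(genotype_matrix(d3, base$snps), tibble::tibble(
    sample_id = rownames(d3),
    population = rep(c("p1", "p2", "p3"), each = 20),
    ancestry_group = rep(c("A", "B", "C"), each = 20)))
  qf <- sample_genotypes(runif(300, 0.2, 0.8), 1, seed = 10,
                         sample_prefix = "q")
  fit2 <- suppressMessages(fit_supervised_admixture(panel_flat, qf))
  expect_equal(unname(fit2$Q["q0001", ]), rep(1 / 3, 3), tolerance = 1e-6)

  # compiled fast path agrees with the plain-EM reference at the optimum
  Gq <- dup$dosages[, fit$snp_ids, drop = FALSE]
  F <- fit$F
  Q <- matrix(1 / 3, 1, 3, dimnames = list("query_dup", fit$groups))
  for (i in 1:4000) Q <- em_step(Gq, Q, F, frozen_F = TRUE)$Q
  expect_equal(unname(fit$Q["query_dup", ]), as.numeric(Q), tolerance = 1e-3)
})
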