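# synthetic SNP table: one chromosome, evenly spaced positions, A/G alleles
# (never strand-ambiguous), zero-padded ids
make_snp_table <- function(n_snps, chrom = "1") {
  tibble(id = sprintf("snp%06d", seq_len(n_snps)), chrom = chrom,
         pos = as.integer(seq_len(n_snps) * 1000L), ref = "A", alt = "G")
}

#' Simulation scenario
#'
#' Describes a synthetic study: K ancestry groups each containing several
#' populations, differentiated under the Balding-Nichols model
#' (between-group FST around 0.1, within-group around 0.01 — the
#' continental vs within-continental scale of human panels), a common-SNP
#' panel, per-cell missingness, a genotype error rate for query genotypes,
#' and optionally admixed query individuals with known mixing proportions.
#'
#' @param n_groups Number of ancestry groups K (default 6).
#' @param group_labels Group names; default the six continental-scale
#'   groups `AFR, AMR, EAS, EUR, MEA, SAS`.
#' @param populations_per_group Populations nested in each group (default 3).
#' @param samples_per_population Reference individuals per population
#'   (default 20).
#' @param n_snps Panel size (default 3000, the scale of common SNPs
#'   recoverable from scRNA-seq reads).
#' @param fst_between,fst_within Balding-Nichols differentiation between
#'   groups (default 0.1) and of populations around their group (default
#'   0.01); `fst_within` must be smaller.
#' @param maf_floor Ancestral frequencies are drawn uniformly on
#'   `[maf_floor, 1 - maf_floor]` (default 0.05, mirroring a common-SNP
#'   panel).
#' @param missing_rate Per-cell missingness (default 0.05, under the 10%
#'   per-SNP/per-sample QC exclusion threshold).
#' @param error_rate Genotype error rate applied to query genotypes by
#'   [make_scenario()] (default 0; evaluation functions inject error
#'   themselves).
#' @param admixed A data frame with one row per admixed-query design point:
#'   a `count` column and one column per group label giving the mixing
#'   proportions (rows on the simplex); `NULL` for none.
#' @param seed Integer master seed; every random draw derives from it.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_groups = 6,
                         group_labels = c("AFR", "AMR", "EAS", "EUR", "MEA", "SAS")[seq_len(n_groups)],
                         populations_per_group = 3,
                         samples_per_population = 20,
                         n_snps = 3000,
                         fst_between = 0.1,
                         fst_within = 0.01,
                         maf_floor = 0.05,
                         missing_rate = 0.05,
                         error_rate = 0,
                         admixed = NULL,
                         seed = 1) {
  stopifnot(n_groups >= 2, length(group_labels) == n_groups,
            populations_per_group >= 1, samples_per_population >= 1, n_snps >= 1,
            fst_between > 0, fst_between < 1, fst_within > 0, fst_within < 1,
            fst_within < fst_between,
            maf_floor >= 0, maf_floor < 0.5,
            missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  if (!is.null(admixed)) {
    admixed <- as_tibble(admixed)
    stopifnot(all(c("count", group_labels) %in% names(admixed)))
    qs <- as.matrix(admixed[, group_labels])
    stopifnot(all(qs >= 0), all(abs(rowSums(qs) - 1) < 1e-8))
  }
  structure(list(n_groups = n_groups, group_labels = sort(group_labels),
                 populations_per_group = populations_per_group,
                 samples_per_population = samples_per_population,
                 n_snps = n_snps, fst_between = fst_between,
                 fst_within = fst_within, maf_floor = maf_floor,
                 missing_rate = missing_rate, error_rate = error_rate,
                 admixed = admixed, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Draw ancestral and group allele frequencies
#'
#' Ancestral frequencies are uniform on `[maf_floor, 1 - maf_floor]`; each
#' group's frequencies are independent Balding-Nichols draws around them:
#' `f_kj ~ Beta(p_j (1-fst)/fst, (1-p_j)(1-fst)/fst)`, so
#' `E[f_kj] = p_j` and `Var[f_kj] = p_j (1-p_j) fst`.
#'
#' @param n_snps,n_groups Panel dimensions.
#' @param fst Differentiation parameter in `(0, 1)`.
#' @param seed Integer seed.
#' @param maf_floor Uniform margin for the ancestral frequency (default
#'   0.05).
#' @param group_labels Optional row names for the frequency matrix.
#' @return A list with `ancestral` (length `n_snps`) and `group_freq`
#'   (`n_groups` x `n_snps`).
#' @export
sample_frequencies <- function(n_snps, n_groups, fst, seed,
                               maf_floor = 0.05, group_labels = NULL) {
  stopifnot(fst > 0, fst < 1)
  with_local_seed(seed, {
    p <- runif(n_snps, maf_floor, 1 - maf_floor)
    a <- (1 - fst) / fst
    f <- matrix(rbeta(n_groups * n_snps, rep(p, each = n_groups) * a,
                      rep(1 - p, each = n_groups) * a),
                nrow = n_groups)
    if (!is.null(group_labels)) rownames(f) <- group_labels
    list(ancestral = p, group_freq = f)
  })
}

#' Draw population frequencies nested within groups
#'
#' A second Balding-Nichols layer: each population's frequencies are drawn
#' around its group's frequencies with `fst_within`, emulating populations
#' nested in continental-scale ancestry groups.
#'
#' @param group_freq Groups-by-SNPs frequency matrix (rownames = groups).
#' @param fst_within Within-group differentiation in `(0, 1)`.
#' @param populations_per_group Populations per group.
#' @param seed Integer seed.
#' @return A list with `pop_freq` (populations x SNPs; rownames like
#'   `EUR_p1`) and `pop_map` (tibble `population`, `ancestry_group`).
#' @export
sample_population_frequencies_nested <- function(group_freq, fst_within,
                                                 populations_per_group, seed) {
  stopifnot(fst_within > 0, fst_within < 1, !is.null(rownames(group_freq)))
  groups <- rownames(group_freq)
  a <- (1 - fst_within) / fst_within
  pops <- as.vector(t(outer(groups, seq_len(populations_per_group),
                            function(g, i) paste0(g, "_p", i))))
  with_local_seed(seed, {
    pf <- matrix(NA_real_, length(pops), ncol(group_freq),
                 dimnames = list(pops, colnames(group_freq)))
    for (g in groups) {
      for (i in seq_len(populations_per_group)) {
        base <- pmin(pmax(group_freq[g, ], 1e-9), 1 - 1e-9)
        pf[paste0(g, "_p", i), ] <- rbeta(ncol(group_freq), base * a, (1 - base) * a)
      }
    }
    list(pop_freq = pf,
         pop_map = tibble(population = pops,
                          ancestry_group = rep(groups, each = populations_per_group)))
  })
}

#' Draw genotypes under Hardy-Weinberg equilibrium
#'
#' `g_ij ~ Binomial(2, f_j)` independently across samples and SNPs.
#'
#' @param freqs Per-SNP ALT frequencies.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param snps Optional SNP table (see [genotype_matrix()]); generated to
#'   match `length(freqs)` when `NULL`.
#' @param sample_prefix Prefix for generated sample ids.
#' @return A [genotype_matrix()].
#' @export
sample_genotypes <- function(freqs, n, seed, snps = NULL, sample_prefix = "s") {
  m <- length(freqs)
  snps <- snps %||% make_snp_table(m)
  stopifnot(nrow(snps) == m)
  d <- with_local_seed(seed, {
    matrix(rbinom(n * m, 2L, rep(freqs, each = n)), nrow = n)
  })
  rownames(d) <- sprintf("%s%04d", sample_prefix, seq_len(n))
  colnames(d) <- snps$id
  genotype_matrix(d, snps)
}

#' Draw admixed genotypes
#'
#' Each of an individual's two allele copies independently picks an
#' ancestral population `k` with probability `q_k` and is then ALT with
#' probability `f_kj` — the generative process matching the admixture
#' likelihood, so the marginal ALT probability is `sum_k q_k f_kj`.
#'
#' @param pop_freq K-by-SNPs frequency matrix.
#' @param q Length-K mixing proportions (simplex vector, named or in
#'   `pop_freq` row order).
#' @param n Number of samples.
#' @inheritParams sample_genotypes
#' @return A [genotype_matrix()].
#' @export
sample_admixed_genotypes <- function(pop_freq, q, n, seed, snps = NULL,
                                     sample_prefix = "adm") {
  K <- nrow(pop_freq)
  m <- ncol(pop_freq)
  if (!is.null(names(q)) && !is.null(rownames(pop_freq))) {
    q <- q[rownames(pop_freq)]
  }
  stopifnot(length(q) == K, all(q >= 0), abs(sum(q) - 1) < 1e-8)
  snps <- snps %||% make_snp_table(m)
  d <- with_local_seed(seed, {
    copy <- function() {
      k <- sample.int(K, n * m, replace = TRUE, prob = q)
      f <- pop_freq[cbind(k, rep(seq_len(m), each = n))]
      matrix(rbinom(n * m, 1L, f), nrow = n)
    }
    copy() + copy()
  })
  rownames(d) <- sprintf("%s%04d", sample_prefix, seq_len(n))
  colnames(d) <- snps$id
  genotype_matrix(d, snps)
}

#' Randomly subsample SNPs
#'
#' Uniform subset without replacement, preserving panel order — emulates the
#' sparse SNP panels recoverable from scRNA-seq reads.
#'
#' @param m A [genotype_matrix()].
#' @param target_count Number of SNPs to keep.
#' @param seed Integer seed.
#' @return A [genotype_matrix()].
#' @export
subsample_snps <- function(m, target_count, seed) {
  stopifnot(target_count >= 1, target_count <= n_snps(m))
  keep <- with_local_seed(seed, sort(sample.int(n_snps(m), target_count)))
  m[, keep]
}

#' Inject missingness
#'
#' Sets each non-missing cell to missing independently with probability
#' `rate`.
#'
#' @param m A [genotype_matrix()].
#' @param rate Per-cell missingness probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [genotype_matrix()].
#' @export
inject_missingness <- function(m, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(m)
  d <- m$dosages
  obs <- which(!is.na(d))
  hit <- with_local_seed(seed, runif(length(obs)) < rate)
  d[obs[hit]] <- NA_integer_
  m$dosages <- d
  m
}

#' Inject genotype errors
#'
#' Each non-missing genotype is, independently with probability `rate`,
#' replaced by one of the two *other* values of `{0, 1, 2}`, chosen
#' uniformly; missing cells are untouched. An altered cell therefore never
#' equals its original value, so `rate` is exactly the expected discordance
#' against the original calls — the way the scRNA-seq genotype error rate is
#' measured against array genotypes.
#'
#' @inheritParams inject_missingness
#' @param rate Error probability per genotype in `[0, 1]`.
#' @return A [genotype_matrix()].
#' @export
inject_genotype_errors <- function(m, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(m)
  d <- m$dosages
  obs <- which(!is.na(d))
  d[obs] <- with_local_seed(seed, {
    hit <- runif(length(obs)) < rate
    shift <- integer(length(obs))
    shift[hit] <- sample(c(1L, 2L), sum(hit), replace = TRUE)
    (d[obs] + shift) %% 3L
  })
  m$dosages <- d
  m
}

#' Generate a full synthetic study
#'
#' Composes the generators into the stand-in for a labelled reference panel
#' plus query donors: group and nested population frequencies, reference
#' genotypes per population, optional admixed queries, missingness on
#' everything, and genotype errors on the queries at the scenario's
#' `error_rate`. Deterministic given the scenario seed.
#'
#' @param scenario A [sim_scenario()].
#' @return A list: `panel` (a [reference_panel()]), `queries` (a
#'   [genotype_matrix()] or `NULL`), `truth` (tibble `sample_id`,
#'   `ancestry_group` = argmax of the mixing vector, and one `q_<group>`
#'   column per group), `group_freq`, `pop_freq`.
#' @export
make_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  s <- scenario
  snps <- make_snp_table(s$n_snps)
  fr <- sample_frequencies(s$n_snps, s$n_groups, s$fst_between,
                           derive_seed(s$seed, "group-freq"),
                           maf_floor = s$maf_floor, group_labels = s$group_labels)
  nested <- sample_population_frequencies_nested(fr$group_freq, s$fst_within,
                                                 s$populations_per_group,
                                                 derive_seed(s$seed, "pop-freq"))
  gm_list <- lapply(nested$pop_map$population, function(pop) {
    sample_genotypes(nested$pop_freq[pop, ], s$samples_per_population,
                     derive_seed(s$seed, paste0("geno-", pop)),
                     snps = snps, sample_prefix = paste0(pop, "_i"))
  })
  d <- do.call(rbind, lapply(gm_list, function(g) g$dosages))
  ref_g <- genotype_matrix(d, snps)
  metadata <- tibble(
    sample_id = rownames(d),
    population = rep(nested$pop_map$population, each = s$samples_per_population),
    ancestry_group = rep(nested$pop_map$ancestry_group, each = s$samples_per_population))
  ref_g <- inject_missingness(ref_g, s$missing_rate, derive_seed(s$seed, "miss-ref"))
  panel <- reference_panel(ref_g, metadata)

  queries <- NULL
  truth <- NULL
  if (!is.null(s$admixed) && nrow(s$admixed) > 0) {
    qmat <- as.matrix(s$admixed[, s$group_labels])
    qg_list <- lapply(seq_len(nrow(s$admixed)), function(i) {
      sample_admixed_genotypes(fr$group_freq, qmat[i, ], s$admixed$count[i],
                               derive_seed(s$seed, paste0("adm-", i)),
                               snps = snps, sample_prefix = sprintf("adm%02d_i", i))
    })
    qd <- do.call(rbind, lapply(qg_list, function(g) g$dosages))
    queries <- genotype_matrix(qd, snps)
    queries <- inject_missingness(queries, s$missing_rate,
                                  derive_seed(s$seed, "miss-query"))
    queries <- inject_genotype_errors(queries, s$error_rate,
                                      derive_seed(s$seed, "err-query"))
    truth <- tibble(
      sample_id = rownames(qd),
      ancestry_group = rep(apply(qmat, 1, argmax_lex, labels = s$group_labels),
                           times = s$admixed$count))
    qtab <- qmat[rep(seq_len(nrow(qmat)), times = s$admixed$count), , drop = FALSE]
    colnames(qtab) <- paste0("q_", s$group_labels)
    truth <- dplyr::bind_cols(truth, as_tibble(as.data.frame(qtab)))
  }
  list(panel = panel, queries = queries, truth = truth,
       group_freq = fr$group_freq, pop_freq = nested$pop_freq)
}
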