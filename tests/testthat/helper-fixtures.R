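# small builders used across test files; everything generated in code

snp_tbl <- function(n, chrom = "1", ref = "A", alt = "G", pos = NULL) {
  tibble::tibble(id = sprintf("s%03d", seq_len(n)), chrom = chrom,
                 pos = pos %||% as.integer(seq_len(n) * 100L),
                 ref = ref, alt = alt)
}

# genotype_matrix from a samples x SNPs matrix (or vector = one SNP)
gm <- function(d, snps = NULL, prefix = "i") {
  if (!is.matrix(d)) d <- matrix(d, ncol = 1)
  if (is.null(rownames(d))) rownames(d) <- sprintf("%s%03d", prefix, seq_len(nrow(d)))
  snps <- snps %||% snp_tbl(ncol(d))
  colnames(d) <- snps$id
  genotype_matrix(d, snps)
}

# a small labelled panel: `groups` group labels, one population per group by
# default, genotypes drawn from Balding-Nichols group frequencies
toy_panel <- function(n_groups = 3, pops_per_group = 1, n_per_pop = 10,
                      n_snps = 300, fst = 0.1, fst_within = 0.01, seed = 1,
                      missing_rate = 0) {
  scn <- sim_scenario(n_groups = n_groups, populations_per_group = pops_per_group,
                      samples_per_population = n_per_pop, n_snps = n_snps,
                      fst_between = fst, fst_within = fst_within,
                      missing_rate = missing_rate, seed = seed)
  make_scenario(scn)
}

# write a VCF 4.2 text file; `records` is a data.frame with CHROM, POS, ID,
# REF, ALT and one column per sample holding GT strings
write_test_vcf <- function(path, records, samples) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- apply(records, 1, function(r) {
    paste(c(r[["CHROM"]], r[["POS"]], r[["ID"]], r[["REF"]], r[["ALT"]],
            ".", "PASS", ".", "GT", r[samples]), collapse = "\t")
  })
  writeLines(c(header, body), path)
  path
}

# dosage matrix with planned LD: each SNP is either fresh or a noisy copy of
# its predecessor (a fraction of entries resampled), plus optional missingness
ld_dosages <- function(n_samples, n_snps, copy_prob = 0.3, noise = 0.15,
                       miss = 0.02, seed = 1) {
  withr::with_seed(seed, {
    d <- matrix(NA_integer_, n_samples, n_snps)
    p <- runif(n_snps, 0.1, 0.9)
    d[, 1] <- rbinom(n_samples, 2, p[1])
    for (j in 2:n_snps) {
      if (runif(1) < copy_prob) {
        d[, j] <- d[, j - 1]
        flip <- runif(n_samples) < noise
        d[flip, j] <- rbinom(sum(flip), 2, p[j])
      } else {
        d[, j] <- rbinom(n_samples, 2, p[j])
      }
    }
    if (miss > 0) d[matrix(runif(length(d)) < miss, nrow(d))] <- NA_integer_
    rownames(d) <- sprintf("i%03d", seq_len(n_samples))
    d
  })
}
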