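#' Per-SNP allele frequencies and MAF
#'
#' Computes, for every SNP, the ALT-allele frequency over non-missing
#' genotypes, `p = sum(g) / (2 * n_obs)`, and the minor allele frequency
#' `MAF = min(p, 1 - p)`. SNPs with no non-missing genotype are flagged and
#' get `NA` frequencies.
#'
#' @param m A [genotype_matrix()] (or dosage matrix with SNP column names).
#' @return A tibble with columns `snp_id`, `n_obs`, `p_alt`, `maf`.
#' @export
#' @examples
#' snps <- tibble::tibble(id = "s1", chrom = "1", pos = 1L, ref = "A", alt = "G")
#' m <- genotype_matrix(matrix(c(0L, 1L, 2L, 2L, NA), 5, 1,
#'   dimnames = list(paste0("i", 1:5), "s1")), snps)
#' compute_maf(m) # p = 5/8, MAF = 0.375
compute_maf <- function(m) {
  d <- as_dosage_matrix(m)
  n_obs <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * n_obs)
  p[n_obs == 0] <- NA_real_
  if (any(n_obs == 0)) {
    warn(paste0(sum(n_obs == 0), " SNP(s) are all-missing; MAF undefined (NA)."))
  }
  tibble(snp_id = colnames(d), n_obs = as.integer(n_obs),
         p_alt = unname(p), maf = unname(pmin(p, 1 - p)))
}

# accept a compute_maf() tibble or a named numeric vector; return named vector
maf_vector <- function(reference_maf) {
  if (is.data.frame(reference_maf)) {
    setNames(reference_maf$maf, reference_maf$snp_id)
  } else {
    stopifnot(!is.null(names(reference_maf)))
    reference_maf
  }
}

#' Filter SNPs to those common in the reference panel
#'
#' Retains SNPs whose minor allele frequency in the *reference panel* is
#' strictly above `threshold` (default 5%, the usual common-variant cutoff).
#' The MAF must come from the reference, never from the query set: query
#' panels are small and error-prone, and the reference defines which sites
#' are informative.
#'
#' @param m A [genotype_matrix()].
#' @param reference_maf Output of [compute_maf()] on the reference panel, or
#'   a named numeric vector of per-SNP MAFs; must cover every SNP of `m`.
#' @param threshold Strict lower MAF bound; default `0.05`.
#' @return `m` restricted to common SNPs.
#' @export
filter_common <- function(m, reference_maf, threshold = 0.05) {
  maf <- maf_vector(reference_maf)
  missing_maf <- setdiff(snp_ids(m), names(maf))
  if (length(missing_maf) > 0) {
    abort(paste0("reference_maf lacks ", length(missing_maf), " SNP(s), e.g. ",
                 missing_maf[1], "."))
  }
  keep <- !is.na(maf[snp_ids(m)]) & maf[snp_ids(m)] > threshold
  m[, which(keep)]
}

#' Filter SNPs and samples by missingness
#'
#' Removes SNPs whose fraction of missing genotypes is strictly above
#' `snp_max`, then removes samples whose missingness over the *remaining*
#' SNPs is strictly above `sample_max` (SNP filter first; the order is part
#' of the contract). A sample or SNP at exactly the threshold is kept.
#'
#' @param m A [genotype_matrix()].
#' @param snp_max,sample_max Strict upper missingness bounds; default `0.10`.
#' @return Filtered [genotype_matrix()]; the counts removed are reported via
#'   a message.
#' @export
filter_missingness <- function(m, snp_max = 0.10, sample_max = 0.10) {
  d <- as_dosage_matrix(m)
  snp_miss <- colMeans(is.na(d))
  keep_snp <- snp_miss <= snp_max
  m2 <- m[, which(keep_snp)]
  if (n_snps(m2) == 0) abort("All SNPs removed by the missingness filter.")
  samp_miss <- rowMeans(is.na(m2$dosages))
  keep_samp <- samp_miss <= sample_max
  m3 <- m2[which(keep_samp), ]
  if (n_samples(m3) == 0) abort("All samples removed by the missingness filter.")
  inform(sprintf("filter_missingness: removed %d/%d SNP(s) and %d/%d sample(s).",
                 sum(!keep_snp), length(keep_snp), sum(!keep_samp), length(keep_samp)))
  m3
}

#' Squared Pearson correlation between two dosage vectors
#'
#' The LD statistic used for pruning: the squared Pearson correlation of
#' unstandardized dosages over pairwise-complete entries. Defined as 0 when
#' either vector is constant on the complete subset; fewer than two complete
#' pairs also yields 0, with a warning.
#'
#' @param x,y Equal-length dosage vectors (may contain `NA`).
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' pairwise_r2(c(0, 1, 2, 0), c(0, 1, 2, 2)) # ~0.2066
pairwise_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) {
    warn("Fewer than 2 pairwise-complete entries; r^2 undefined, returning 0.")
    return(0)
  }
  x <- x[ok]
  y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(0)
  unname(cor(x, y)^2)
}

#' LD-pruning parameters
#'
#' Parameters of windowed r-squared pruning in the style of PLINK's
#' `--indep-pairwise`: windows are counted in SNPs, not base pairs.
#'
#' @param window_snps Window width in SNPs (>= 2); default 50.
#' @param step_snps Window slide in SNPs (between 1 and `window_snps`);
#'   default 10.
#' @param r2_threshold Maximum tolerated pairwise r-squared in a window;
#'   default 0.1.
#' @return A `prune_params` list.
#' @export
prune_params <- function(window_snps = 50, step_snps = 10, r2_threshold = 0.1) {
  stopifnot(window_snps >= 2, step_snps >= 1, step_snps <= window_snps,
            r2_threshold > 0, r2_threshold <= 1)
  structure(list(window_snps = as.integer(window_snps),
                 step_snps = as.integer(step_snps),
                 r2_threshold = r2_threshold),
            class = "prune_params")
}

# banded pairwise-complete r^2 over the columns of `d`: entry [off, j] is the
# squared correlation of columns j and j + off, for off < `width` (compiled;
# constant columns and pairs with fewer than 2 complete entries give 0)
banded_r2 <- function(d, width) {
  storage.mode(d) <- "integer"
  cpp_banded_r2(d, as.integer(width))
}

# greedy clean-up of one window given the banded r^2 `band` over the pass's
# alive sequence. `wpos` are positions into `alive`; `active` is the pass-wide
# keep flag. Worst pair first (ties: smallest first, then second, position);
# within a pair remove the smaller-MAF SNP, MAF ties -> larger genomic
# position, then larger column index. Returns updated `active`.
prune_window_band <- function(wpos, band, active, alive, maf, pos, threshold) {
  wpos <- wpos[active[wpos]]
  k <- length(wpos)
  if (k < 2) return(active)
  r2 <- matrix(0, k, k)
  for (a in seq_len(k - 1)) {
    off <- wpos[(a + 1):k] - wpos[a]
    r2[a, (a + 1):k] <- band[cbind(off, wpos[a])]
  }
  live <- rep(TRUE, k)
  repeat {
    r2a <- r2
    r2a[!live, ] <- 0
    r2a[, !live] <- 0
    mx <- max(r2a)
    if (mx <= threshold) break
    hit <- which(r2a == mx, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    ci <- alive[wpos[i]]; cj <- alive[wpos[j]]
    drop_col <- pick_removal(ci, cj, maf, pos)
    k_loc <- if (drop_col == ci) i else j
    live[k_loc] <- FALSE
    active[wpos[k_loc]] <- FALSE
  }
  active
}

# which of two SNP column indices to remove under the deterministic rule
pick_removal <- function(i, j, maf, pos) {
  mi <- maf[i]; mj <- maf[j]
  mi <- ifelse(is.na(mi), -Inf, mi)
  mj <- ifelse(is.na(mj), -Inf, mj)
  if (mi < mj) return(i)
  if (mj < mi) return(j)
  if (pos[i] > pos[j]) return(i)
  if (pos[j] > pos[i]) return(j)
  max(i, j)
}

#' Windowed r-squared LD pruning
#'
#' Thins a SNP panel so that no pair of retained SNPs lying within
#' `window_snps` consecutive retained SNPs (per chromosome) has squared
#' dosage correlation above `r2_threshold`. Windows slide by `step_snps`
#' over the retained sequence and passes repeat until stable; a final
#' verification sweep over every window offset removes any residual
#' violating pairs by the same rule, so the stated post-condition holds
#' exactly. Within a window the worst (largest-r-squared) pair is treated
#' first; of the pair, the SNP with the smaller reference MAF is removed
#' (MAF tie: the one at the larger position). The procedure is fully
#' deterministic and idempotent.
#'
#' @param m A [genotype_matrix()] with SNPs ordered by `(chrom, pos)`.
#' @param params A [prune_params()] object.
#' @param reference_maf Optional [compute_maf()] tibble or named MAF vector
#'   used for the removal tie-break; computed from `m` when `NULL`. When
#'   pruning a reference panel this should be (and defaults to) that panel's
#'   own MAF.
#' @return Character vector of retained SNP ids, in panel order.
#' @export
ld_prune <- function(m, params = prune_params(), reference_maf = NULL) {
  d <- as_dosage_matrix(m)
  s <- m$snps
  ord <- order(s$chrom, s$pos)
  if (!identical(ord, seq_len(nrow(s)))) {
    abort("SNPs must be ordered by (chrom, pos) before pruning.")
  }
  maf <- if (is.null(reference_maf)) {
    mv <- compute_maf(m)
    setNames(mv$maf, mv$snp_id)
  } else {
    maf_vector(reference_maf)
  }
  maf <- unname(maf[s$id])
  pos <- s$pos
  w <- params$window_snps
  keep <- rep(TRUE, ncol(d))

  for (chrom in unique(s$chrom)) {
    cols <- which(s$chrom == chrom)
    repeat {
      alive <- cols[keep[cols]]
      n_alive <- length(alive)
      if (n_alive < 2) break
      band <- banded_r2(d[, alive, drop = FALSE], w)
      viol <- which(!is.na(band) & band > params$r2_threshold)
      if (length(viol) == 0) break
      active <- rep(TRUE, n_alive)
      starts <- unique(c(seq(1, n_alive, by = params$step_snps),
                         max(1, n_alive - w + 1)))
      for (st in starts) {
        wpos <- st:min(st + w - 1, n_alive)
        active <- prune_window_band(wpos, band, active, alive, maf, pos,
                                    params$r2_threshold)
      }
      if (all(active)) {
        # violating pairs straddle the stride windows: sweep every offset
        for (st in seq_len(n_alive - 1)) {
          wpos <- st:min(st + w - 1, n_alive)
          active <- prune_window_band(wpos, band, active, alive, maf, pos,
                                      params$r2_threshold)
        }
      }
      keep[alive[!active]] <- FALSE
      # removals may bring distant pairs within the window span; next pass
      # recomputes the band over the shortened sequence and re-checks
    }
  }
  s$id[keep]
}
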