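# independent oracles, written as literal translations of the definitions;
# they deliberately avoid the package's computational paths

# literal double-loop admixture log-likelihood
oracle_loglik <- function(G, Q, F) {
  ll <- 0
  for (i in seq_len(nrow(G))) {
    for (j in seq_len(ncol(G))) {
      g <- G[i, j]
      if (is.na(g)) next
      p <- 0
      q1 <- 0
      for (k in seq_len(nrow(F))) {
        p <- p + Q[i, k] * F[k, j]
        q1 <- q1 + Q[i, k] * (1 - F[k, j])
      }
      ll <- ll + g * log(p) + (2 - g) * log(q1)
    }
  }
  ll
}

# naive pairwise-complete r^2 via base R
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(0)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

# exhaustive windowed LD pruning implementing the stated rule with fresh,
# naive r^2 at every step: passes over the sequence of kept SNPs, stride
# `step` (plus the final window), greedily removing the worst pair per
# window (smaller MAF first, ties by larger position then larger index);
# when a pass removes nothing but a violating pair remains within the window
# span, a sweep over every offset cleans it; repeat until stable
oracle_ld_prune <- function(d, snps, maf, window, step, threshold) {
  keep <- rep(TRUE, ncol(d))
  pos <- snps$pos
  pick <- function(i, j) {
    mi <- if (is.na(maf[i])) -Inf else maf[i]
    mj <- if (is.na(maf[j])) -Inf else maf[j]
    if (mi < mj) return(i)
    if (mj < mi) return(j)
    if (pos[i] > pos[j]) return(i)
    if (pos[j] > pos[i]) return(j)
    max(i, j)
  }
  clean_window <- function(members) {
    # members: column indices fixed at call time; honours current `keep`
    repeat {
      act <- members[keep[members]]
      if (length(act) < 2) return(invisible())
      best <- NULL
      best_val <- threshold
      for (a in seq_len(length(act) - 1)) {
        for (b in (a + 1):length(act)) {
          v <- oracle_r2(d[, act[a]], d[, act[b]])
          if (v > best_val) {
            best <- c(act[a], act[b])
            best_val <- v
          }
        }
      }
      if (is.null(best)) return(invisible())
      keep[pick(best[1], best[2])] <<- FALSE
    }
  }
  for (chrom in unique(snps$chrom)) {
    cols <- which(snps$chrom == chrom)
    repeat {
      alive <- cols[keep[cols]]
      n_alive <- length(alive)
      if (n_alive < 2) break
      # any violating pair within the window span?
      has_viol <- FALSE
      for (a in seq_len(n_alive - 1)) {
        for (b in (a + 1):min(a + window - 1, n_alive)) {
          if (oracle_r2(d[, alive[a]], d[, alive[b]]) > threshold) {
            has_viol <- TRUE
            break
          }
        }
        if (has_viol) break
      }
      if (!has_viol) break
      before <- sum(keep)
      starts <- unique(c(seq(1, n_alive, by = step), max(1, n_alive - window + 1)))
      for (st in starts) {
        clean_window(alive[st:min(st + window - 1, n_alive)])
      }
      if (sum(keep) == before) {
        for (st in seq_len(n_alive - 1)) {
          clean_window(alive[st:min(st + window - 1, n_alive)])
        }
      }
    }
  }
  snps$id[keep]
}

# Weir & Cockerham (1984) multi-population FST estimator (ratio of sums over
# SNPs), from genotypes and population labels
oracle_wc_fst <- function(d, pops) {
  pops <- as.character(pops)
  labs <- unique(pops)
  r <- length(labs)
  num <- 0
  den <- 0
  for (j in seq_len(ncol(d))) {
    ni <- pi <- hi <- numeric(r)
    for (k in seq_len(r)) {
      g <- d[pops == labs[k], j]
      g <- g[!is.na(g)]
      ni[k] <- length(g)
      if (length(g) == 0) next
      pi[k] <- mean(g) / 2
      hi[k] <- mean(g == 1)
    }
    if (any(ni == 0)) next
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}
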