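#' Per-group ALT allele frequencies
#'
#' Observed ALT frequency of every SNP within each ancestry group of the
#' reference panel, the supervised initialization (and, with reference
#' labels frozen, the stationary value) of the ancestral frequencies `F` of
#' the admixture model. Frequencies are clamped to `[1e-6, 1 - 1e-6]` so the
#' binomial log-likelihood stays finite for discordant genotypes; a group
#' with no non-missing call at a SNP falls back to the panel-wide frequency
#' with a warning.
#'
#' @param ref A [reference_panel()].
#' @return A groups-by-SNPs numeric matrix (rownames = sorted group labels).
#' @export
group_frequencies <- function(ref) {
  stopifnot(inherits(ref, "reference_panel"))
  d <- ref$genotypes$dosages
  groups <- panel_groups(ref)
  panel_p <- colSums(d, na.rm = TRUE) / pmax(2 * colSums(!is.na(d)), 1)
  f <- matrix(NA_real_, length(groups), ncol(d),
              dimnames = list(groups, colnames(d)))
  n_fallback <- 0
  for (g in groups) {
    dg <- d[ref$samples$ancestry_group == g, , drop = FALSE]
    n_obs <- colSums(!is.na(dg))
    p <- colSums(dg, na.rm = TRUE) / (2 * n_obs)
    empty <- n_obs == 0
    if (any(empty)) {
      p[empty] <- panel_p[empty]
      n_fallback <- n_fallback + sum(empty)
    }
    f[g, ] <- p
  }
  if (n_fallback > 0) {
    warn(paste0(n_fallback, " group x SNP cell(s) had no non-missing call; ",
                "panel-wide frequency substituted."))
  }
  pmin(pmax(f, 1e-6), 1 - 1e-6)
}

#' Binomial admixture log-likelihood
#'
#' The log-likelihood of genotypes under the admixture model: each of an
#' individual's two allele copies at SNP `j` is ALT with probability
#' `sum_k q_ik f_kj`, so
#' `ll = sum_ij [ g_ij log(P_ij) + (2 - g_ij) log(1 - P_ij) ]` with
#' `P = Q F`, summing over non-missing genotypes only (missing cells
#' contribute 0).
#'
#' @param G A [genotype_matrix()] or dosage matrix (samples x SNPs).
#' @param Q Samples-by-K matrix of ancestry proportions (rows on the
#'   simplex).
#' @param F K-by-SNPs matrix of ancestral ALT frequencies in `(0, 1)`.
#' @return A finite scalar.
#' @export
admixture_loglik <- function(G, Q, F) {
  d <- as_dosage_matrix(G)
  Q <- as.matrix(Q)
  F <- as.matrix(F)
  if (anyNA(Q) || anyNA(F)) abort("Q and F must not contain NA/NaN.")
  if (any(F <= 0) || any(F >= 1)) abort("F entries must lie strictly in (0, 1).")
  if (length(d) == 0 || all(is.na(d))) return(0)
  W <- !is.na(d)
  g <- ifelse(W, d, 0)
  h <- ifelse(W, 2 - d, 0)
  P <- Q %*% F
  sum(g * log(P) + h * log(1 - P))
}

#' One EM step for the admixture model
#'
#' The expectation step attributes each observed allele copy to the K
#' ancestral populations with responsibilities proportional to
#' `q_ik f_kj` (ALT copies) and `q_ik (1 - f_kj)` (REF copies); the
#' maximization step re-estimates `Q` (per-sample mean attribution over the
#' `2 M_i` observed allele copies) and `F` (attributed ALT fraction). Both
#' updates use the same responsibilities, so the log-likelihood never
#' decreases. Rows listed in `frozen_q_rows` keep their proportions (the
#' supervised reference rows); `frozen_F` keeps `F`; `f_update_rows`
#' restricts which samples inform the `F` update (default all).
#'
#' @inheritParams admixture_loglik
#' @param frozen_q_rows Integer indices of rows of `Q` left unchanged.
#' @param frozen_F If `TRUE`, `F` is returned unchanged.
#' @param f_update_rows Integer indices of samples used in the `F` update;
#'   `NULL` means all.
#' @return A list with updated `Q` and `F`.
#' @export
em_step <- function(G, Q, F, frozen_q_rows = integer(0), frozen_F = FALSE,
                    f_update_rows = NULL) {
  d <- as_dosage_matrix(G)
  Q <- as.matrix(Q)
  F <- as.matrix(F)
  W <- !is.na(d)
  g <- ifelse(W, d, 0)
  h <- ifelse(W, 2 - d, 0)
  P <- Q %*% F
  RA <- g / P          # W already zeroes g,h at missing cells
  RB <- h / (1 - P)
  A <- (RA %*% t(F)) * Q        # sum_j a_ijk
  B <- (RB %*% t(1 - F)) * Q    # sum_j b_ijk
  Mi <- rowSums(W)
  Qnew <- (A + B) / pmax(2 * Mi, .Machine$double.eps)
  Qnew[Mi == 0, ] <- Q[Mi == 0, ]
  if (length(frozen_q_rows) > 0) Qnew[frozen_q_rows, ] <- Q[frozen_q_rows, ]
  Qnew <- Qnew / rowSums(Qnew)

  if (isTRUE(frozen_F)) {
    Fnew <- F
  } else {
    rows <- f_update_rows %||% seq_len(nrow(d))
    Qs <- Q[rows, , drop = FALSE]
    num <- F * (t(Qs) %*% RA[rows, , drop = FALSE])
    den <- num + (1 - F) * (t(Qs) %*% RB[rows, , drop = FALSE])
    Fnew <- ifelse(den > 0, num / den, F)
    Fnew <- pmin(pmax(Fnew, 1e-6), 1 - 1e-6)
  }
  list(Q = Qnew, F = Fnew)
}

#' Supervised admixture estimation by EM
#'
#' Estimates per-query ancestry proportions under the binomial admixture
#' model with the reference panel's ancestry groups as the K ancestral
#' populations: reference individuals' proportions are frozen to one-hot
#' vectors for their labelled group, queries start uniform at `1/K`, and
#' ancestral frequencies start at the observed group frequencies. EM runs
#' until the absolute log-likelihood change drops below `tol` or `max_iter`
#' is reached.
#'
#' By default `F` is informed by the reference rows only; with frozen
#' one-hot reference labels the observed group frequencies are then a
#' stationary point of the `F` update, so `F` stays fixed and only query
#' proportions move — the stable variant for small query sets. Setting
#' `update_F_with_queries = TRUE` re-estimates `F` jointly from reference
#' and query rows, the behaviour of classical supervised admixture fitting.
#'
#' @param ref A [reference_panel()].
#' @param query A [genotype_matrix()] sharing SNP ids with the reference.
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 2000).
#' @param update_F_with_queries Include query rows in the `F` update
#'   (default `FALSE`).
#' @return An object of class `admixture_fit`: `Q` (all samples x K, row
#'   names reference then query ids), `F`, `loglik_trace` (value before the
#'   first step and after every step), `converged`, `n_iter`, `groups`,
#'   `ref_ids`, `query_ids`, `snp_ids`.
#' @export
fit_supervised_admixture <- function(ref, query, tol = 1e-6, max_iter = 2000,
                                     update_F_with_queries = FALSE) {
  stopifnot(inherits(ref, "reference_panel"), inherits(query, "genotype_matrix"))
  shared <- intersect(snp_ids(ref$genotypes), snp_ids(query))
  if (length(shared) == 0) abort("Query shares no SNPs with the reference panel.")
  if (length(shared) < n_snps(ref$genotypes)) {
    inform(sprintf("fit_supervised_admixture: restricting to %d shared SNP(s).",
                   length(shared)))
  }
  refp <- subset_panel(ref, snps = shared)
  qg <- query[, shared]
  groups <- panel_groups(refp)
  K <- length(groups)
  F <- group_frequencies(refp)
  Gr <- refp$genotypes$dosages
  Gq <- qg$dosages
  Qr <- matrix(0, nrow(Gr), K, dimnames = list(rownames(Gr), groups))
  Qr[cbind(seq_len(nrow(Gr)), match(refp$samples$ancestry_group, groups))] <- 1
  Qq <- matrix(1 / K, nrow(Gq), K, dimnames = list(rownames(Gq), groups))

  check_ll <- function(ll, it) {
    if (!is.finite(ll)) {
      abort(sprintf("Non-finite log-likelihood at iteration %d.", it))
    }
    ll
  }

  if (!update_F_with_queries) {
    # F is stationary at the observed group frequencies; iterate queries only
    # (compiled EM loop; see em_step() for the reference implementation)
    ll_ref <- check_ll(admixture_loglik(Gr, Qr, F), 0)
    res <- cpp_em_fixed_f(Gq, F, Qq, tol, as.integer(max_iter))
    Qq <- res$Q
    dimnames(Qq) <- list(rownames(Gq), groups)
    trace <- ll_ref + res$trace
    converged <- res$converged
    it <- res$n_iter
    Q <- rbind(Qr, Qq)
  } else {
    G <- rbind(Gr, Gq)
    Q <- rbind(Qr, Qq)
    frozen <- seq_len(nrow(Gr))
    ll <- check_ll(admixture_loglik(G, Q, F), 0)
    trace <- ll
    converged <- FALSE
    it <- 0
    while (it < max_iter) {
      it <- it + 1
      upd <- em_step(G, Q, F, frozen_q_rows = frozen)
      Q <- upd$Q
      F <- upd$F
      ll_new <- check_ll(admixture_loglik(G, Q, F), it)
      trace <- c(trace, ll_new)
      if (abs(ll_new - ll) < tol) {
        converged <- TRUE
        ll <- ll_new
        break
      }
      ll <- ll_new
    }
  }
  structure(list(Q = Q, F = F, loglik_trace = trace, converged = converged,
                 n_iter = it, groups = groups,
                 ref_ids = rownames(Gr), query_ids = rownames(Gq),
                 snp_ids = shared),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> K=%d groups, %d reference + %d query samples, %d SNPs; %d EM iteration(s), %s (loglik %.2f)\n",
              length(x$groups), length(x$ref_ids), length(x$query_ids),
              length(x$snp_ids), x$n_iter,
              if (x$converged) "converged" else "NOT converged",
              tail(x$loglik_trace, 1)))
  invisible(x)
}

#' @export
tidy.admixture_fit <- function(x, ...) {
  q <- as.data.frame(x$Q)
  q$sample_id <- rownames(x$Q)
  q$role <- ifelse(q$sample_id %in% x$query_ids, "query", "reference")
  tidyr::pivot_longer(as_tibble(q), dplyr::all_of(x$groups),
                      names_to = "ancestry_group", values_to = "proportion")
}

#' @export
glance.admixture_fit <- function(x, ...) {
  tibble(k = length(x$groups), n_reference = length(x$ref_ids),
         n_query = length(x$query_ids), n_snps = length(x$snp_ids),
         n_iter = x$n_iter, converged = x$converged,
         loglik = tail(x$loglik_trace, 1))
}

#' @importFrom utils tail
NULL
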