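#' Standardize genotype dosages
#'
#' Centers and scales dosages with per-SNP constants, the usual
#' population-structure scaling: at a SNP with reference ALT frequency
#' `p`, the mean is `2p` and the scale `sqrt(2p(1-p))` (unit variance under
#' Hardy-Weinberg equilibrium). Missing genotypes become 0 after
#' standardization, i.e. they are mean-imputed.
#'
#' @param m A [genotype_matrix()] (or dosage matrix).
#' @param means,scales Named per-SNP numeric vectors covering all SNPs of
#'   `m`; scales must be strictly positive.
#' @return A numeric samples-by-SNPs matrix.
#' @export
standardize <- function(m, means, scales) {
  d <- as_dosage_matrix(m)
  ids <- colnames(d)
  if (!all(ids %in% names(means)) || !all(ids %in% names(scales))) {
    abort("`means`/`scales` must be defined for every SNP of `m`.")
  }
  mu <- means[ids]
  sc <- scales[ids]
  if (any(!is.finite(sc)) || any(sc <= 0)) {
    abort("Zero or non-finite scale encountered; monomorphic SNPs must be removed upstream.")
  }
  x <- sweep(d, 2, mu, "-")
  x <- sweep(x, 2, sc, "/")
  x[is.na(x)] <- 0
  x
}

#' Fit a principal-component model on a reference panel
#'
#' Computes per-SNP centering/scaling constants from reference allele
#' frequencies (`mean = 2p`, `scale = sqrt(2p(1-p))`), removes monomorphic
#' SNPs, and extracts the top right-singular vectors of the standardized
#' reference matrix as SNP loadings. Reference sample scores are stored with
#' their panel labels. A fixed sign convention — the largest-magnitude
#' loading entry of each component is positive — makes the model exactly
#' reproducible regardless of sample order.
#'
#' @param ref A [reference_panel()].
#' @param n_components Number of components (default 5, the depth at which
#'   continental structure is typically captured).
#' @return An object of class `ancestry_pca` with elements `snp_ids`,
#'   `means`, `scales`, `loadings` (SNPs x components, orthonormal),
#'   `explained_variance`, and `scores` (tibble of labelled reference
#'   scores).
#' @export
fit_reference_pca <- function(ref, n_components = 5) {
  stopifnot(inherits(ref, "reference_panel"))
  g <- ref$genotypes
  maf <- compute_maf(g)
  poly <- which(!is.na(maf$p_alt) & maf$p_alt > 0 & maf$p_alt < 1)
  if (length(poly) < n_snps(g)) {
    inform(sprintf("fit_reference_pca: excluding %d monomorphic/all-missing SNP(s).",
                   n_snps(g) - length(poly)))
  }
  g <- g[, poly]
  p <- maf$p_alt[poly]
  if (n_snps(g) < n_components || n_samples(g) < n_components) {
    abort(sprintf("Need at least %d polymorphic SNPs and samples; have %d x %d.",
                  n_components, n_samples(g), n_snps(g)))
  }
  means <- setNames(2 * p, snp_ids(g))
  scales <- setNames(sqrt(2 * p * (1 - p)), snp_ids(g))
  x <- standardize(g, means, scales)
  sv <- svd(x, nu = 0, nv = min(dim(x)))
  rank <- sum(sv$d > max(dim(x)) * .Machine$double.eps * sv$d[1])
  if (rank < n_components) {
    abort(sprintf("Reference matrix rank %d is below the requested %d components.",
                  rank, n_components))
  }
  v <- sv$v[, seq_len(n_components), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (k in seq_len(n_components)) {
    pivot <- which.max(abs(v[, k]))
    if (v[pivot, k] < 0) v[, k] <- -v[, k]
  }
  rownames(v) <- snp_ids(g)
  colnames(v) <- paste0("PC", seq_len(n_components))
  scores <- x %*% v
  score_tbl <- dplyr::bind_cols(ref$samples,
                                as_tibble(as.data.frame(scores)))
  structure(list(snp_ids = snp_ids(g), means = means, scales = scales,
                 loadings = v, n_components = as.integer(n_components),
                 explained_variance = sv$d[seq_len(n_components)]^2 / (nrow(x) - 1),
                 scores = score_tbl),
            class = "ancestry_pca")
}

#' @export
print.ancestry_pca <- function(x, ...) {
  cat(sprintf("<ancestry_pca> %d SNPs, %d components; explained variance: %s\n",
              length(x$snp_ids), x$n_components,
              paste(signif(x$explained_variance, 3), collapse = ", ")))
  invisible(x)
}

#' Project samples onto fitted principal components
#'
#' Standardizes the query genotypes with the *reference* means/scales and
#' multiplies by the loadings. SNPs of the model absent from the query are
#' treated as missing (standardized 0), which shrinks scores toward the
#' origin in proportion to missingness but requires no imputation model.
#'
#' @param model An `ancestry_pca` from [fit_reference_pca()].
#' @param m A [genotype_matrix()] of query samples.
#' @return A tibble `sample_id`, `PC1` ... `PCn`.
#' @export
project_pca <- function(model, m) {
  stopifnot(inherits(model, "ancestry_pca"))
  shared <- intersect(model$snp_ids, snp_ids(m))
  if (length(shared) == 0) abort("Query shares no SNPs with the PCA model.")
  d <- matrix(NA_integer_, n_samples(m), length(model$snp_ids),
              dimnames = list(sample_ids(m), model$snp_ids))
  d[, shared] <- as_dosage_matrix(m[, shared])
  x <- standardize(d, model$means, model$scales)
  scores <- x %*% model$loadings
  dplyr::bind_cols(tibble(sample_id = sample_ids(m)),
                   as_tibble(as.data.frame(scores)))
}

#' @export
tidy.ancestry_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, dplyr::starts_with("PC"),
                      names_to = "component", values_to = "score")
}

#' @export
glance.ancestry_pca <- function(x, ...) {
  tibble(n_snps = length(x$snp_ids), n_samples = nrow(x$scores),
         n_components = x$n_components,
         pc1_variance = x$explained_variance[1],
         pc2_variance = x$explained_variance[2])
}

#' @export
autoplot.ancestry_pca <- function(object, x = "PC1", y = "PC2", ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data[[x]], .data[[y]], colour = .data$ancestry_group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = "ancestry group") +
    ggplot2::theme_minimal()
}
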