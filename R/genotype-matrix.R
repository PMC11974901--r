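#' Genotype matrix container
#'
#' A `genotype_matrix` holds hard-called diploid genotypes for a set of
#' samples at a set of biallelic SNPs, coded as ALT-allele dosages:
#' 0 (homozygous REF), 1 (heterozygous), 2 (homozygous ALT), with `NA`
#' marking a missing call. Dosages are stored as a samples-by-SNPs integer
#' matrix; SNP identity (id, chromosome, 1-based position, REF/ALT alleles)
#' travels alongside as a tibble so that panels from different call sets can
#' be intersected and allele-harmonized.
#'
#' @param dosages Integer matrix, samples in rows (rownames = sample ids),
#'   SNPs in columns (colnames = SNP ids), values in `{0, 1, 2, NA}`.
#' @param snps Tibble with columns `id`, `chrom`, `pos`, `ref`, `alt`; one
#'   row per column of `dosages`, in column order.
#' @return An object of class `genotype_matrix`.
#' @export
#' @examples
#' snps <- tibble::tibble(id = "rs1", chrom = "1", pos = 100L, ref = "A", alt = "G")
#' gm <- genotype_matrix(matrix(c(0L, 1L, 2L), 3, 1,
#'   dimnames = list(c("s1", "s2", "s3"), "rs1")), snps)
#' gm
genotype_matrix <- function(dosages, snps) {
  if (!is.matrix(dosages)) abort("`dosages` must be a matrix.")
  storage.mode(dosages) <- "integer"
  snps <- as_tibble(snps)
  validate_genotype_matrix(structure(list(dosages = dosages, snps = snps),
                                     class = "genotype_matrix"))
}

validate_genotype_matrix <- function(m) {
  d <- m$dosages
  s <- m$snps
  req <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(s))) {
    abort(paste0("`snps` must have columns: ", paste(req, collapse = ", ")))
  }
  if (ncol(d) != nrow(s)) abort("Number of dosage columns must match number of SNP records.")
  if (is.null(rownames(d))) abort("`dosages` must carry sample ids as rownames.")
  if (anyDuplicated(rownames(d))) abort("Sample ids must be unique.")
  if (anyDuplicated(s$id)) abort("SNP ids must be unique.")
  if (!identical(colnames(d), as.character(s$id))) {
    if (is.null(colnames(d))) colnames(m$dosages) <- s$id else abort("Dosage column names must equal SNP ids, in order.")
  }
  bad <- d[!is.na(d) & !(d %in% 0:2)]
  if (length(bad) > 0) {
    abort(paste0("Dosages must be in {0, 1, 2, NA}; found value(s): ",
                 paste(unique(bad), collapse = ", ")))
  }
  if (nrow(s) > 0) {
    if (any(s$pos < 1)) abort("SNP positions must be >= 1.")
    if (any(!(s$ref %in% c("A", "C", "G", "T")) | !(s$alt %in% c("A", "C", "G", "T")))) {
      abort("REF/ALT alleles must be single nucleotides in {A, C, G, T}.")
    }
    if (any(s$ref == s$alt)) abort("REF and ALT alleles must differ.")
  }
  m
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- if (length(x$dosages) > 0) mean(is.na(x$dosages)) else 0
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs (%.1f%% missing)\n",
              n_samples(x), n_snps(x), 100 * miss))
  invisible(x)
}

#' Dimensions and identifiers of a genotype matrix
#'
#' @param m A [genotype_matrix()].
#' @return `n_samples()`/`n_snps()` return integers; `sample_ids()`/`snp_ids()`
#'   character vectors.
#' @export
n_samples <- function(m) nrow(m$dosages)

#' @rdname n_samples
#' @export
n_snps <- function(m) ncol(m$dosages)

#' @rdname n_samples
#' @export
sample_ids <- function(m) rownames(m$dosages)

#' @rdname n_samples
#' @export
snp_ids <- function(m) m$snps$id

#' Subset a genotype matrix
#'
#' `i` selects samples, `j` SNPs; either can be ids, logical, or integer
#' indices. SNP records are subset in step with the dosage columns.
#'
#' @param x A [genotype_matrix()].
#' @param i,j Sample / SNP selectors.
#' @param ... Unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(j)) j <- match(j, x$snps$id)
  if (anyNA(j)) abort("Unknown SNP id in subset.")
  if (is.character(i)) i <- match(i, rownames(x$dosages))
  if (anyNA(i)) abort("Unknown sample id in subset.")
  d <- x$dosages[i, j, drop = FALSE]
  structure(list(dosages = d, snps = x$snps[j, , drop = FALSE]),
            class = "genotype_matrix")
}

#' @export
as_tibble.genotype_matrix <- function(x, ...) {
  tibble(sample_id = rep(sample_ids(x), times = n_snps(x)),
         snp_id = rep(snp_ids(x), each = n_samples(x)),
         dosage = as.integer(x$dosages))
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# coerce genotype_matrix or plain matrix to a dosage matrix
as_dosage_matrix <- function(m) {
  if (inherits(m, "genotype_matrix")) m$dosages else as.matrix(m)
}

#' Labelled reference panel
#'
#' Bundles a [genotype_matrix()] with per-sample population and
#' ancestry-group labels — the structure of a reference panel such as a
#' harmonized whole-genome diversity panel, where each of K continental-scale
#' ancestry groups contains several populations.
#'
#' @param genotypes A [genotype_matrix()].
#' @param metadata Data frame with columns `sample_id`, `population`,
#'   `ancestry_group`; must cover every sample of `genotypes`.
#' @return An object of class `reference_panel` with elements `genotypes`
#'   and `samples` (a tibble aligned to the genotype rows).
#' @export
reference_panel <- function(genotypes, metadata) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  metadata <- as_tibble(metadata)
  req <- c("sample_id", "population", "ancestry_group")
  if (!all(req %in% names(metadata))) {
    abort(paste0("`metadata` must have columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(metadata$sample_id)) abort("Duplicated sample_id in metadata.")
  missing_meta <- setdiff(sample_ids(genotypes), metadata$sample_id)
  if (length(missing_meta) > 0) {
    abort(paste0("Sample(s) in genotype data absent from metadata: ",
                 paste(head(missing_meta, 5), collapse = ", "),
                 if (length(missing_meta) > 5) ", ..." else ""))
  }
  samples <- metadata[match(sample_ids(genotypes), metadata$sample_id), req]
  if (anyNA(samples$population) || anyNA(samples$ancestry_group)) {
    abort("Every sample must carry both a population and an ancestry_group label.")
  }
  pop_map <- unique(samples[, c("population", "ancestry_group")])
  if (anyDuplicated(pop_map$population)) {
    abort("Each population must map to exactly one ancestry group.")
  }
  if (length(unique(samples$ancestry_group)) < 2) {
    abort("A reference panel needs at least 2 ancestry groups.")
  }
  structure(list(genotypes = genotypes, samples = samples),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d samples, %d SNPs, %d populations in %d ancestry groups\n",
              n_samples(x$genotypes), n_snps(x$genotypes),
              length(unique(x$samples$population)),
              length(unique(x$samples$ancestry_group))))
  invisible(x)
}

#' Groups and populations of a reference panel
#'
#' @param panel A [reference_panel()].
#' @return Sorted character vector of labels.
#' @export
panel_groups <- function(panel) sort(unique(panel$samples$ancestry_group))

#' @rdname panel_groups
#' @export
panel_populations <- function(panel) sort(unique(panel$samples$population))

# subset a panel by sample selector and/or SNP selector, keeping labels aligned
subset_panel <- function(panel, samples = NULL, snps = NULL) {
  g <- panel$genotypes
  keep <- if (is.null(samples)) sample_ids(g) else samples
  if (!is.null(snps)) g <- g[keep, snps] else g <- g[keep, ]
  reference_panel(g, panel$samples)
}
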