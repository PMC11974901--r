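#' Read genotypes from a VCF file
#'
#' Parses the GT field of a VCF 4.x file (plain or bgzipped) into a
#' [genotype_matrix()] of ALT-allele dosages. Only hard-called diploid
#' genotypes are used: `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`,
#' `./.` (or any call with a missing allele) -> `NA`. Phased separators
#' (`|`) are treated like unphased ones.
#'
#' @param path Path to a VCF or VCF.gz file.
#' @param biallelic_only If `TRUE` (default), records that are not biallelic
#'   single-nucleotide variants (indels, multiallelic sites, symbolic
#'   alleles) are skipped.
#' @return A [genotype_matrix()]. SNPs lacking a VCF ID (`.`) are assigned
#'   the id `chrom:pos:ref:alt`.
#' @export
read_vcf <- function(path, biallelic_only = TRUE) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("Failed to parse VCF '", path, "': ", conditionMessage(e)))
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("No variant records retained from VCF (empty matrix).")
  keep <- rep(TRUE, nrow(fix))
  if (isTRUE(biallelic_only)) {
    nt <- c("A", "C", "G", "T")
    keep <- fix$REF %in% nt & fix$ALT %in% nt
  }
  if (!any(keep)) abort("No variant records retained from VCF (empty matrix).")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  gt_chr <- gsub("\\|", "/", as.character(gt))
  code <- rep(NA_integer_, length(gt_chr))
  code[gt_chr %in% "0/0"] <- 0L
  code[gt_chr %in% c("0/1", "1/0")] <- 1L
  code[gt_chr %in% "1/1"] <- 2L
  unknown <- !is.na(gt_chr) & !(gt_chr %in% c("0/0", "0/1", "1/0", "1/1", "./.", "."))
  if (any(unknown)) {
    warn(paste0(sum(unknown), " GT call(s) with unexpected allele codes set to missing."))
  }
  # gt is SNPs x samples; transpose to samples x SNPs
  d <- matrix(code, nrow = nrow(gt), ncol = ncol(gt))
  d <- t(d)
  rownames(d) <- colnames(gt)

  id <- fix$ID
  auto <- is.na(id) | id == "."
  id[auto] <- paste(fix$CHROM[auto], fix$POS[auto], fix$REF[auto], fix$ALT[auto], sep = ":")
  snps <- tibble(id = id, chrom = as.character(fix$CHROM),
                 pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT)
  colnames(d) <- snps$id
  genotype_matrix(d, snps)
}

#' Read sample metadata
#'
#' Reads a tab-separated table with header columns `sample_id`,
#' `population`, `ancestry_group` describing the reference panel labels.
#'
#' @param path Path to a TSV file.
#' @return A tibble with the three label columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("Metadata file not found: ", path))
  md <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  req <- c("sample_id", "population", "ancestry_group")
  if (!all(req %in% names(md))) {
    abort(paste0("Metadata must have header columns: ", paste(req, collapse = ", ")))
  }
  md <- md[, req]
  dup <- md$sample_id[duplicated(md$sample_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicated sample_id in metadata: ", paste(unique(dup), collapse = ", ")))
  }
  if (anyNA(md) || any(md == "", na.rm = TRUE)) {
    abort("Metadata contains empty cells; every sample needs all three labels.")
  }
  md
}

#' Intersect two genotype matrices on shared SNPs
#'
#' Matches SNPs between two call sets on `(chrom, pos)` — identifiers are
#' not trusted across call sets — and reconciles alleles so that both
#' matrices count the ALT allele of `a` (the orientation authority, normally
#' the reference panel). Sites where `b`'s REF/ALT are swapped relative to
#' `a` have `b`'s dosages flipped `g -> 2 - g`; allele pairs that neither
#' match nor swap are dropped, as are strand-ambiguous A/T and C/G SNPs when
#' `drop_ambiguous` is set (their orientation cannot be resolved without
#' strand information).
#'
#' @param a,b [genotype_matrix()] objects.
#' @param drop_ambiguous Drop A/T and C/G SNPs (default `TRUE`).
#' @return A list with elements `a` and `b`, both restricted to the matched
#'   SNPs in `a`'s order, with identical SNP lists.
#' @export
align_on_shared_snps <- function(a, b, drop_ambiguous = TRUE) {
  key <- function(s) paste(s$chrom, s$pos, sep = ":")
  ka <- key(a$snps)
  kb <- key(b$snps)
  ib <- match(ka, kb)
  matched <- which(!is.na(ib))
  n_candidates <- length(matched)

  sa <- a$snps[matched, , drop = FALSE]
  sb <- b$snps[ib[matched], , drop = FALSE]
  same <- sa$ref == sb$ref & sa$alt == sb$alt
  swapped <- sa$ref == sb$alt & sa$alt == sb$ref
  ambiguous <- (sa$ref == "A" & sa$alt == "T") | (sa$ref == "T" & sa$alt == "A") |
    (sa$ref == "C" & sa$alt == "G") | (sa$ref == "G" & sa$alt == "C")
  keep <- (same | swapped) & !(isTRUE(drop_ambiguous) & ambiguous)

  dropped <- (nrow(a$snps) - n_candidates) + sum(!keep)
  inform(sprintf("align_on_shared_snps: matched %d SNP(s); dropped %d from `a` (unmatched/irreconcilable/ambiguous), flipped %d in `b`.",
                 sum(keep), dropped, sum(swapped & keep)))

  ia_keep <- matched[keep]
  ib_keep <- ib[ia_keep]
  a2 <- a[, ia_keep]
  b2 <- b[, ib_keep]
  flip <- swapped[keep]
  if (any(flip)) {
    b2$dosages[, flip] <- 2L - b2$dosages[, flip]
    b2$snps$ref[flip] <- a2$snps$ref[flip]
    b2$snps$alt[flip] <- a2$snps$alt[flip]
  }
  # after reconciliation both call sets describe the same alleles; adopt a's ids
  b2$snps$id <- a2$snps$id
  colnames(b2$dosages) <- a2$snps$id
  list(a = a2, b = b2)
}

#' Write / read a genotype matrix as TSV
#'
#' The TSV has one row per sample (first column `sample_id`) and one column
#' per SNP, cells in `{0, 1, 2, NA}`. SNP records (chromosome, position,
#' REF/ALT) are stored in `#SNP` comment lines above the header so that the
#' file round-trips exactly.
#'
#' @param m A non-empty [genotype_matrix()].
#' @param path Output / input file path.
#' @return `write_genotype_tsv()` returns `path` invisibly;
#'   `read_genotype_tsv()` returns a [genotype_matrix()].
#' @export
write_genotype_tsv <- function(m, path) {
  stopifnot(inherits(m, "genotype_matrix"))
  if (n_samples(m) == 0 || n_snps(m) == 0) {
    abort("Refusing to write an empty genotype matrix.")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#SNP", m$snps$id, m$snps$chrom, m$snps$pos, m$snps$ref, m$snps$alt,
                   sep = "\t"), con)
  writeLines(paste(c("sample_id", m$snps$id), collapse = "\t"), con)
  body <- apply(m$dosages, 1, function(r) paste(ifelse(is.na(r), "NA", r), collapse = "\t"))
  writeLines(paste(sample_ids(m), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("Genotype TSV not found: ", path))
  lines <- readLines(path)
  snp_lines <- grep("^#SNP\t", lines)
  if (length(snp_lines) == 0) abort("Genotype TSV lacks #SNP header lines.")
  snp_fields <- strsplit(lines[snp_lines], "\t", fixed = TRUE)
  bad <- which(lengths(snp_fields) != 6)
  if (length(bad) > 0) abort(paste0("Malformed #SNP line at line ", snp_lines[bad[1]], "."))
  snps <- tibble(id = vapply(snp_fields, `[[`, "", 2),
                 chrom = vapply(snp_fields, `[[`, "", 3),
                 pos = as.integer(vapply(snp_fields, `[[`, "", 4)),
                 ref = vapply(snp_fields, `[[`, "", 5),
                 alt = vapply(snp_fields, `[[`, "", 6))
  body <- lines[-snp_lines]
  if (length(body) < 2) abort("Genotype TSV has no sample rows.")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "sample_id" || !identical(header[-1], snps$id)) {
    abort("Genotype TSV header does not match #SNP records.")
  }
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(header))
  if (length(bad) > 0) {
    abort(paste0("Inconsistent column count at data line ", bad[1], " of ", path, "."))
  }
  ids <- vapply(rows, `[[`, "", 1)
  d <- matrix(NA_integer_, nrow = length(rows), ncol = nrow(snps),
              dimnames = list(ids, snps$id))
  for (i in seq_along(rows)) {
    v <- rows[[i]][-1]
    d[i, ] <- suppressWarnings(as.integer(ifelse(v == "NA", NA, v)))
  }
  genotype_matrix(d, snps)
}

#' Assemble a reference panel from files
#'
#' Convenience wrapper joining genotypes (VCF or genotype TSV) with a
#' metadata TSV into a [reference_panel()].
#'
#' @param genotype_path VCF(.gz) or genotype TSV path.
#' @param metadata_path Sample metadata TSV path (see [read_metadata()]).
#' @param ... Passed to [read_vcf()] for VCF input.
#' @return A [reference_panel()].
#' @export
read_reference_panel <- function(genotype_path, metadata_path, ...) {
  g <- if (grepl("\\.vcf(\\.gz)?$", genotype_path)) {
    read_vcf(genotype_path, ...)
  } else {
    read_genotype_tsv(genotype_path)
  }
  reference_panel(g, read_metadata(metadata_path))
}
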