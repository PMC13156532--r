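#' Construct a genotype table
#'
#' The central container of the package: biallelic SNP genotypes for a set of
#' diploid individuals, stored as phased haplotypes together with per-genotype
#' depth and quality metadata. Sites are kept sorted by contig then position.
#'
#' @param contig character vector of contig names, one per site.
#' @param pos integer vector of 1-based positions, one per site.
#' @param ref,alt single-character REF/ALT alleles per site.
#' @param qual numeric site QUAL (Phred-scaled) per site.
#' @param hap integer matrix of phased alleles (0 = REF, 1 = ALT, NA =
#'   missing), with `2 * n_individuals` rows (haplotype 1 and 2 of individual
#'   i in rows `2i - 1` and `2i`) and one column per site.
#' @param dp integer matrix (individuals x sites) of per-genotype read depth.
#' @param gq integer matrix (individuals x sites) of per-genotype quality.
#' @param samples character vector of individual identifiers.
#' @param is_indel logical per site; defaults to all `FALSE`.
#' @param phased logical scalar; whether haplotype phase is meaningful.
#'
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(contig, pos, ref, alt, qual, hap, dp, gq, samples,
                           is_indel = rep(FALSE, length(pos)),
                           phased = TRUE) {
  n_site <- length(pos)
  n_ind <- length(samples)
  stopifnot(
    length(contig) == n_site, length(ref) == n_site, length(alt) == n_site,
    length(qual) == n_site, length(is_indel) == n_site,
    is.matrix(hap), nrow(hap) == 2L * n_ind, ncol(hap) == n_site,
    is.matrix(dp), nrow(dp) == n_ind, ncol(dp) == n_site,
    is.matrix(gq), nrow(gq) == n_ind, ncol(gq) == n_site
  )
  ord <- order(contig, pos)
  if (anyDuplicated(paste(contig, pos))) {
    stop("duplicated contig/position pairs in genotype table")
  }
  storage.mode(hap) <- "integer"
  storage.mode(dp) <- "integer"
  storage.mode(gq) <- "integer"
  obj <- structure(list(
    contig = as.character(contig)[ord], pos = as.integer(pos)[ord],
    ref = as.character(ref)[ord], alt = as.character(alt)[ord],
    qual = as.numeric(qual)[ord],
    is_indel = as.logical(is_indel)[ord],
    hap = hap[, ord, drop = FALSE],
    dp = dp[, ord, drop = FALSE], gq = gq[, ord, drop = FALSE],
    samples = as.character(samples), phased = isTRUE(phased)
  ), class = "genotype_table")
  obj
}

#' Number of sites / individuals in a genotype table
#' @param gt a `genotype_table`.
#' @return integer scalar.
#' @export
n_sites <- function(gt) length(gt$pos)

#' @rdname n_sites
#' @export
n_individuals <- function(gt) length(gt$samples)

#' Diploid dosage matrix
#'
#' Collapses the phased haplotypes to ALT-allele dosages 0/1/2 per individual
#' and site; a genotype is `NA` when either haplotype is missing.
#'
#' @param gt a `genotype_table`.
#' @return integer matrix, individuals x sites.
#' @export
dosage <- function(gt) {
  h1 <- gt$hap[seq(1L, nrow(gt$hap), by = 2L), , drop = FALSE]
  h2 <- gt$hap[seq(2L, nrow(gt$hap), by = 2L), , drop = FALSE]
  d <- h1 + h2
  rownames(d) <- gt$samples
  d
}

#' Extract the phased haplotype matrix
#'
#' @param gt a `genotype_table`.
#' @return a `haplotype_matrix`: integer matrix (haplotypes x sites) with
#'   attributes `contig` and `pos`.
#' @export
haplotypes <- function(gt) {
  if (!gt$phased) stop("genotypes are unphased; the sweep scan needs phased input")
  structure(gt$hap, contig = gt$contig, pos = gt$pos,
            class = c("haplotype_matrix", "matrix"))
}

#' Subset a genotype table
#'
#' @param gt a `genotype_table`.
#' @param sites logical or integer index over sites (optional).
#' @param individuals logical or integer index over individuals (optional).
#' @return a `genotype_table`.
#' @export
subset_gt <- function(gt, sites = NULL, individuals = NULL) {
  if (!is.null(sites)) {
    keep <- if (is.logical(sites)) which(sites) else sites
    for (f in c("contig", "pos", "ref", "alt", "qual", "is_indel")) {
      gt[[f]] <- gt[[f]][keep]
    }
    gt$hap <- gt$hap[, keep, drop = FALSE]
    gt$dp <- gt$dp[, keep, drop = FALSE]
    gt$gq <- gt$gq[, keep, drop = FALSE]
  }
  if (!is.null(individuals)) {
    ki <- if (is.logical(individuals)) which(individuals) else individuals
    hap_rows <- as.vector(rbind(2L * ki - 1L, 2L * ki))
    gt$hap <- gt$hap[hap_rows, , drop = FALSE]
    gt$dp <- gt$dp[ki, , drop = FALSE]
    gt$gq <- gt$gq[ki, , drop = FALSE]
    gt$samples <- gt$samples[ki]
  }
  gt
}

#' Site identifiers ("contig:pos")
#' @param gt a `genotype_table`.
#' @return character vector.
#' @export
site_ids <- function(gt) paste0(gt$contig, ":", gt$pos)

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d sites x %d individuals (%s), %d contig(s)\n",
              n_sites(x), n_individuals(x),
              if (x$phased) "phased" else "unphased",
              length(unique(x$contig))))
  invisible(x)
}

#' Test equality of two genotype tables
#'
#' Compares coordinates, alleles, QUAL, haplotypes and per-genotype metadata.
#' Used mainly for round-trip checks of the VCF writer/reader.
#'
#' @param a,b `genotype_table` objects.
#' @return logical scalar.
#' @export
gt_equal <- function(a, b) {
  isTRUE(all.equal(a$contig, b$contig)) &&
    isTRUE(all.equal(a$pos, b$pos)) &&
    isTRUE(all.equal(a$ref, b$ref)) && isTRUE(all.equal(a$alt, b$alt)) &&
    isTRUE(all.equal(a$qual, b$qual, tolerance = 1e-6)) &&
    identical(unname(a$hap), unname(b$hap)) &&
    identical(unname(a$dp), unname(b$dp)) &&
    identical(unname(a$gq), unname(b$gq)) &&
    identical(a$samples, b$samples)
}
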