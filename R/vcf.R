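#' Write a genotype table to VCF 4.2
#'
#' Emits phased GT (separator `|`; `.|.` for missing), per-genotype DP and GQ,
#' and site QUAL. Sites must be sorted by contig and position (the container
#' guarantees this).
#'
#' @param gt a [genotype_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path) {
  for (ctg in unique(gt$contig)) {
    p <- gt$pos[gt$contig == ctg]
    if (is.unsorted(p, strictly = TRUE)) stop("positions not sorted on ", ctg)
  }
  sep <- if (gt$phased) "|" else "/"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=beescape",
    paste0("##contig=<ID=", unique(gt$contig), ">"),
    "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Number of samples with data\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gt$samples), collapse = "\t")
  ), con)
  m <- n_sites(gt)
  if (m > 0L) {
    n <- n_individuals(gt)
    h1 <- gt$hap[seq(1L, 2L * n, by = 2L), , drop = FALSE]
    h2 <- gt$hap[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    a1 <- ifelse(is.na(h1), ".", h1)
    a2 <- ifelse(is.na(h2), ".", h2)
    cells <- matrix(paste0(a1, sep, a2, ":", gt$dp, ":", gt$gq), n, m)
    sample_cols <- apply(cells, 2L, paste, collapse = "\t")
    ns <- colSums(!is.na(h1))
    writeLines(paste(gt$contig, gt$pos, site_ids(gt), gt$ref, gt$alt,
                     format(gt$qual, trim = TRUE, scientific = FALSE),
                     "PASS", paste0("NS=", ns), "GT:DP:GQ", sample_cols,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a genotype table
#'
#' Parses with \pkg{vcfR} and converts to the package container. Multiallelic
#' records are rejected; indel flags come from REF/ALT lengths. Phase is taken
#' from the GT separator of the first record.
#'
#' @param path VCF file path.
#' @return a [genotype_table()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0L) stop("VCF contains no variant records")
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) stop("multiallelic records not supported")
  gt_str <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  samples <- colnames(gt_str)
  m <- nrow(fix); n <- length(samples)
  phased <- any(grepl("|", gt_str[1, ], fixed = TRUE))
  a1 <- suppressWarnings(as.integer(substr(gt_str, 1L, 1L)))
  a2 <- suppressWarnings(as.integer(substr(gt_str, 3L, 3L)))
  hap <- matrix(NA_integer_, 2L * n, m)
  hap[seq(1L, 2L * n, by = 2L), ] <- t(matrix(a1, m, n))
  hap[seq(2L, 2L * n, by = 2L), ] <- t(matrix(a2, m, n))
  dp[is.na(dp)] <- 0L
  gq[is.na(gq)] <- 0L
  genotype_table(
    contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = alt,
    qual = as.numeric(fix[, "QUAL"]),
    is_indel = nchar(fix[, "REF"]) != 1L | nchar(alt) != 1L,
    hap = hap, dp = t(dp), gq = t(gq), samples = samples, phased = phased
  )
}
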