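#' Unstandardised nSL scan
#'
#' For every focal SNP, haplotype pairs are split into the ancestral group A
#' (both carry the REF allele, treated as ancestral) and the derived group D
#' (both carry ALT). For each pair the identity tract spanning the focal SNP
#' is the maximal run of agreeing sites containing it, measured in number of
#' segregating sites (the focal site included); `SL_A` and `SL_D` are the
#' group means and `nSL = log(SL_A / SL_D)`, so an excess of long shared
#' haplotypes around the derived allele gives negative values. Pairs that
#' mismatch at the focal site belong to neither group.
#'
#' Tracts are truncated at contig ends; a focal SNP is dropped when more
#' than `max_edge_frac` of either group's tracts reach an end, mirroring how
#' haplotype scans skip loci whose homozygosity has not decayed at a
#' chromosome edge.
#'
#' Focal SNPs need at least two carriers of each allele and a minor allele
#' frequency of at least `min_maf`.
#'
#' @param hap a [haplotypes()] matrix (phased, no missing values).
#' @param min_maf minimum focal minor allele frequency (default 0.05).
#' @param max_edge_frac maximum tolerated fraction of edge-truncated tracts
#'   per group (default 0.05).
#' @return an `nsl_scan` data.frame: contig, pos, freq (derived allele
#'   frequency), sl_a, sl_d, nsl; only retained focal SNPs appear.
#' @export
nsl_scan <- function(hap, min_maf = 0.05, max_edge_frac = 0.05) {
  if (anyNA(hap)) {
    stop("haplotypes contain missing values; impute before scanning (see impute_haplotypes)")
  }
  contig <- attr(hap, "contig"); pos <- attr(hap, "pos")
  h_all <- unclass(hap)
  out <- list()
  for (ctg in unique(contig)) {
    cols <- which(contig == ctg)
    h <- h_all[, cols, drop = FALSE]
    S <- ncol(h); H <- nrow(h)
    sumA <- sumD <- cntA <- cntD <- numeric(S)
    edgeA <- edgeD <- numeric(S)
    for (i in seq_len(H - 1)) {
      hi <- h[i, ]
      for (j in seq(i + 1, H)) {
        hj <- h[j, ]
        m <- which(hi != hj)
        js <- findInterval(seq_len(S), m)
        prev <- c(0L, m)[js + 1L]        # last mismatch at or before s (0 if none)
        nxt <- c(m, S + 1L)[js + 1L]     # first mismatch after s (S+1 if none)
        # mismatch positions themselves contribute to no group below
        tract <- nxt - prev - 1L
        edge <- (prev == 0L) | (nxt == S + 1L)
        bothA <- (hi == 0L) & (hj == 0L)
        bothD <- (hi == 1L) & (hj == 1L)
        sumA[bothA] <- sumA[bothA] + tract[bothA]
        cntA[bothA] <- cntA[bothA] + 1
        edgeA[bothA & edge] <- edgeA[bothA & edge] + 1
        sumD[bothD] <- sumD[bothD] + tract[bothD]
        cntD[bothD] <- cntD[bothD] + 1
        edgeD[bothD & edge] <- edgeD[bothD & edge] + 1
      }
    }
    freq <- colMeans(h)
    usable <- freq * H >= 2 & (1 - freq) * H >= 2 &
      pmin(freq, 1 - freq) >= min_maf &
      cntA > 0 & cntD > 0 &
      edgeA / pmax(cntA, 1) <= max_edge_frac &
      edgeD / pmax(cntD, 1) <= max_edge_frac
    if (any(usable)) {
      sl_a <- sumA[usable] / cntA[usable]
      sl_d <- sumD[usable] / cntD[usable]
      out[[ctg]] <- data.frame(contig = ctg, pos = pos[cols][usable],
                               freq = freq[usable], sl_a = sl_a, sl_d = sl_d,
                               nsl = log(sl_a / sl_d))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(contig = character(0), pos = integer(0), freq = numeric(0),
               sl_a = numeric(0), sl_d = numeric(0), nsl = numeric(0))
  }
  rownames(res) <- NULL
  class(res) <- c("nsl_scan", "data.frame")
  res
}

#' Impute missing haplotype alleles with the major allele
#'
#' The sweep scan requires complete phased haplotypes; missing alleles are
#' replaced by each site's major allele.
#'
#' @param hap a [haplotypes()] matrix possibly containing `NA`.
#' @return a complete `haplotype_matrix`.
#' @export
impute_haplotypes <- function(hap) {
  h <- unclass(hap)
  cm <- colMeans(h, na.rm = TRUE)
  fill <- as.integer(cm >= 0.5)
  idx <- which(is.na(h), arr.ind = TRUE)
  if (nrow(idx)) h[idx] <- fill[idx[, 2]]
  structure(h, contig = attr(hap, "contig"), pos = attr(hap, "pos"),
            class = c("haplotype_matrix", "matrix"))
}

#' Frequency-bin standardisation of nSL scores
#'
#' SNPs are binned by derived allele frequency into `n_bins` equal-width
#' bins; bins holding fewer than two SNPs are merged with the nearest
#' occupied bin. Within each (merged) bin, `z = (nsl - mean) / sd`, using
#' the moment (population, n-denominator) standard deviation as the scan
#' normalisation utilities do; a two-point bin at \{-1, 1\} therefore gives
#' z exactly \{-1, 1\}. SNPs with `|z| >= z_cut` are flagged as outliers.
#'
#' @param scan an [nsl_scan()] result.
#' @param n_bins number of derived-allele-frequency bins (default 100).
#' @param z_cut outlier threshold on `|z|` (default 2).
#' @return the scan with added columns `bin`, `z`, `outlier`; attribute
#'   `merged_bins` records bin merges.
#' @export
normalize_nsl <- function(scan, n_bins = 100L, z_cut = 2) {
  if (nrow(scan) == 0) {
    scan$bin <- integer(0); scan$z <- numeric(0); scan$outlier <- logical(0)
    return(scan)
  }
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- cut(scan$freq, breaks, include.lowest = TRUE, labels = FALSE)
  # merge under-filled bins into the nearest occupied bin
  merged <- integer(0)
  repeat {
    counts <- table(factor(bin, levels = seq_len(n_bins)))
    small <- which(counts > 0 & counts < 2)
    viable <- which(counts >= 2)
    if (!length(small) || !length(viable)) break
    b <- small[1]
    target <- viable[which.min(abs(viable - b))]
    bin[bin == b] <- target
    merged <- rbind(merged, c(from = b, to = target))
  }
  if (length(unique(bin)) == 1L && stats::sd(scan$nsl) == 0) {
    stop("degenerate scan: a single bin with zero variance")
  }
  z <- numeric(nrow(scan))
  for (b in unique(bin)) {
    sel <- bin == b
    mu <- mean(scan$nsl[sel])
    sdv <- sqrt(mean((scan$nsl[sel] - mu)^2))
    if (sum(sel) < 2 || sdv == 0) {
      stop("bin with undefined standard deviation after merging")
    }
    z[sel] <- (scan$nsl[sel] - mu) / sdv
  }
  scan$bin <- bin
  scan$z <- z
  scan$outlier <- abs(z) >= z_cut
  attr(scan, "merged_bins") <- merged
  scan
}

#' Merge outlier SNPs into candidate sweep regions
#'
#' Per contig, outlier SNPs sorted by position are linked whenever the gap to
#' the previous outlier is at most `gap_bp`; each linked run forms one region
#' spanning its first to last member (1-based inclusive; singletons give
#' width-0 regions).
#'
#' @param scan a [normalize_nsl()] result with `outlier` flags.
#' @param gap_bp maximum within-region gap (default 50000).
#' @return data.frame: contig, start, end, n_snps, max_abs_z.
#' @export
merge_outlier_regions <- function(scan, gap_bp = 50000L) {
  out <- scan[scan$outlier, , drop = FALSE]
  if (nrow(out) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0),
                      max_abs_z = numeric(0)))
  }
  out <- out[order(out$contig, out$pos), ]
  res <- lapply(split(out, out$contig), function(d) {
    brk <- c(0L, cumsum(diff(d$pos) > gap_bp))
    do.call(rbind, lapply(split(d, brk), function(g) {
      data.frame(contig = g$contig[1], start = min(g$pos), end = max(g$pos),
                 n_snps = nrow(g), max_abs_z = max(abs(g$z)))
    }))
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res[order(res$contig, res$start), ]
}

#' Overlap between GEA candidates and sweep regions, with a
#' density-preserving permutation test
#'
#' The observed statistic k counts GEA candidate SNPs lying within
#' `pad_bp` of any sweep region (inclusive bounds). Under the null,
#' candidate labels are reassigned uniformly at random to the observed SNP
#' positions within the same contig — preserving the SNP position set, the
#' per-contig SNP density and the per-contig candidate counts —
#' and k is recomputed; `p = (#{k* >= k} + 1) / (n_perm + 1)`.
#'
#' @param gea_candidates data.frame with `contig` and `pos` of candidate SNPs.
#' @param regions sweep regions from [merge_outlier_regions()].
#' @param all_snps data.frame with `contig` and `pos` of every analysed SNP.
#' @param pad_bp padding around regions (default 10000).
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @return list with `k`, `p`, `n_perm`, `null_k`.
#' @export
overlap_permutation_test <- function(gea_candidates, regions, all_snps,
                                     pad_bp = 10000L, n_perm = 1000L,
                                     seed = 1L) {
  if (!all(gea_candidates$contig %in% all_snps$contig)) {
    stop("candidate on a contig absent from the SNP set")
  }
  count_overlap <- function(cand) {
    k <- 0L
    for (ctg in unique(cand$contig)) {
      rg <- regions[regions$contig == ctg, , drop = FALSE]
      pp <- cand$pos[cand$contig == ctg]
      if (!nrow(rg) || !length(pp)) next
      hit <- vapply(pp, function(p) {
        any(p >= rg$start - pad_bp & p <= rg$end + pad_bp)
      }, logical(1))
      k <- k + sum(hit)
    }
    k
  }
  k_obs <- count_overlap(gea_candidates)
  set.seed(seed)
  snp_by_ctg <- split(all_snps$pos, all_snps$contig)
  cand_n <- table(gea_candidates$contig)
  null_k <- vapply(seq_len(n_perm), function(b) {
    cand <- do.call(rbind, lapply(names(cand_n), function(ctg) {
      data.frame(contig = ctg,
                 pos = sample(snp_by_ctg[[ctg]], cand_n[[ctg]]))
    }))
    count_overlap(cand)
  }, integer(1))
  p <- (sum(null_k >= k_obs) + 1) / (n_perm + 1)
  list(k = k_obs, p = p, n_perm = n_perm, null_k = null_k)
}
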