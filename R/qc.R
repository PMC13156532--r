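#' Variant filtering presets
#'
#' Three presets form the filtering ladder used throughout the package.
#' `initial` retains SNPs genotyped in at least 50% of individuals with
#' QUAL >= 30, minor allele count >= 3 and per-genotype depth >= 3.
#' `strict` (diversity/structure analyses) additionally requires a call rate
#' >= 0.95, MAF >= 0.05, mean depth in \[5, 100\], removes indels, removes
#' sites with observed heterozygosity > 0.6 (paralog screen) and turns LD
#' pruning on. `relaxed` (association/sweep analyses) is identical except the
#' call-rate requirement is 0.75 and LD pruning is off.
#'
#' `max_missing` follows the VCFtools convention: the minimum fraction of
#' individuals that must be genotyped at a site.
#'
#' @param name one of `"initial"`, `"strict"`, `"relaxed"`.
#' @return a `filter_preset` list of thresholds.
#' @export
filter_preset <- function(name = c("strict", "relaxed", "initial")) {
  name <- match.arg(name)
  base <- list(name = name, max_missing = 0.5, maf = 0, mac = 3L,
               min_qual = 30, min_gt_depth = 3L, min_mean_dp = -Inf,
               max_mean_dp = Inf, drop_indels = FALSE, max_ind_missing = 0.5,
               max_obs_het = 1, ld_prune = FALSE)
  if (name == "strict") {
    base[c("max_missing", "maf", "min_mean_dp", "max_mean_dp", "drop_indels",
           "max_obs_het", "ld_prune")] <-
      list(0.95, 0.05, 5, 100, TRUE, 0.6, TRUE)
  } else if (name == "relaxed") {
    base[c("max_missing", "maf", "min_mean_dp", "max_mean_dp", "drop_indels",
           "max_obs_het")] <- list(0.75, 0.05, 5, 100, TRUE, 0.6)
  }
  structure(base, class = "filter_preset")
}

#' Apply site-level filters
#'
#' Rules are applied in a fixed, auditable order: per-genotype depth masking
#' (genotypes with DP below `min_gt_depth` are set missing before any site
#' statistic), indel removal, QUAL, minor allele count, site missingness,
#' MAF, mean depth bounds, and the observed-heterozygosity paralog screen.
#' Boundary conventions: QUAL >= `min_qual` retained; observed heterozygosity
#' strictly greater than `max_obs_het` removed.
#'
#' @param gt a [genotype_table()].
#' @param preset a [filter_preset()] (or a compatible list of thresholds).
#' @return list with `genotypes` (filtered table) and `report` (data.frame:
#'   rule, n_removed, n_remaining).
#' @export
apply_site_filters <- function(gt, preset = filter_preset("strict")) {
  report <- data.frame(rule = character(0), n_removed = integer(0),
                       n_remaining = integer(0))
  log_step <- function(rule, removed, remaining) {
    rbind(report, data.frame(rule = rule, n_removed = removed,
                             n_remaining = remaining))
  }
  if (n_sites(gt) == 0L) {
    return(list(genotypes = gt,
                report = log_step("input", 0L, 0L)))
  }
  # 1. genotype-depth masking
  low <- gt$dp < preset$min_gt_depth
  if (any(low)) {
    idx <- which(low)
    n <- n_individuals(gt)
    r <- ((idx - 1L) %% n) + 1L
    cc <- ((idx - 1L) %/% n) + 1L
    gt$hap[cbind(2L * r - 1L, cc)] <- NA_integer_
    gt$hap[cbind(2L * r, cc)] <- NA_integer_
  }
  report <- log_step("genotype_depth_mask", sum(low), n_sites(gt))

  drop_and_log <- function(gt, keep, rule) {
    removed <- sum(!keep)
    gt <- subset_gt(gt, sites = keep)
    report <<- log_step(rule, removed, n_sites(gt))
    gt
  }
  if (preset$drop_indels) {
    gt <- drop_and_log(gt, !gt$is_indel, "indels")
  }
  gt <- drop_and_log(gt, gt$qual >= preset$min_qual, "qual")

  d <- dosage(gt)
  alt_count <- colSums(d, na.rm = TRUE)
  n_called <- colSums(!is.na(d))
  mac <- pmin(alt_count, 2L * n_called - alt_count)
  gt <- drop_and_log(gt, n_called > 0L & mac >= preset$mac, "mac")

  d <- dosage(gt)
  call_rate <- colMeans(!is.na(d))
  gt <- drop_and_log(gt, call_rate >= preset$max_missing, "missingness")

  d <- dosage(gt)
  n_called <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(p, 1 - p)
  gt <- drop_and_log(gt, maf >= preset$maf, "maf")

  mean_dp <- colMeans(gt$dp)
  gt <- drop_and_log(gt, mean_dp >= preset$min_mean_dp &
                       mean_dp <= preset$max_mean_dp, "mean_depth")

  d <- dosage(gt)
  obs_het <- colMeans(d == 1L, na.rm = TRUE)
  gt <- drop_and_log(gt, !(obs_het > preset$max_obs_het), "obs_het")

  list(genotypes = gt, report = report)
}

#' Remove individuals with excessive missingness
#'
#' Individuals whose fraction of missing genotypes is strictly greater than
#' the threshold are dropped (an individual at exactly the threshold is
#' retained).
#'
#' @param gt a [genotype_table()].
#' @param max_ind_missing maximum tolerated missing fraction (default 0.5).
#' @return a [genotype_table()].
#' @export
drop_high_missing_individuals <- function(gt, max_ind_missing = 0.5) {
  d <- dosage(gt)
  frac <- rowMeans(is.na(d))
  keep <- frac <= max_ind_missing
  if (!any(keep)) stop("all individuals exceed the missingness threshold")
  subset_gt(gt, individuals = keep)
}

#' Windowed LD pruning
#'
#' Within each sliding window of `window_snps` SNPs (advanced by `step_snps`,
#' per contig), while any retained pair has squared genotype correlation
#' exceeding `r2_max`, the later SNP of the offending pair is removed.
#' Correlations use pairwise-complete dosages.
#'
#' @param gt a [genotype_table()].
#' @param window_snps window size in SNPs.
#' @param step_snps window step in SNPs.
#' @param r2_max maximum tolerated squared correlation.
#' @return a [genotype_table()] containing the retained subset of sites.
#' @export
ld_prune <- function(gt, window_snps = 50L, step_snps = 5L, r2_max = 0.5) {
  d <- dosage(gt)
  keep <- rep(TRUE, n_sites(gt))
  for (ctg in unique(gt$contig)) {
    idx <- which(gt$contig == ctg)
    s <- 1L
    repeat {
      w <- idx[seq(s, min(s + window_snps - 1L, length(idx)))]
      w_live <- w[keep[w]]
      if (length(w_live) > 1L) {
        r <- suppressWarnings(stats::cor(d[, w_live, drop = FALSE],
                                         use = "pairwise.complete.obs"))
        r2 <- r^2
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        repeat {
          bad <- which(r2 > r2_max, arr.ind = TRUE)
          if (nrow(bad) == 0L) break
          bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
          victim <- min(bad[, 2])  # earliest "later SNP" of an offending pair
          keep[w_live[victim]] <- FALSE
          r2[victim, ] <- 0
          r2[, victim] <- 0
        }
      }
      if (s + window_snps - 1L >= length(idx)) break
      s <- s + step_snps
    }
  }
  subset_gt(gt, sites = keep)
}

#' KING-robust pairwise kinship
#'
#' For each pair of individuals, over the sites non-missing in both:
#' `phi = (N_Aa,Aa - 2 * N_AA,aa) / (N_Aa(i) + N_Aa(j))`, where `N_Aa,Aa`
#' counts sites where both are heterozygous, `N_AA,aa` counts opposite
#' homozygotes, and `N_Aa(.)` counts heterozygous sites of each individual
#' within the shared mask. A zero denominator yields `NaN` (flagged, not an
#' error). An individual paired with itself gives 0.5.
#'
#' @param gt a [genotype_table()].
#' @param flag_threshold kinship above which a pair is flagged as related;
#'   default 0.177 (second-degree boundary of the conventional KING bands).
#' @return a `kinship_matrix`: list with `phi` (n x n, diagonal 0.5),
#'   `n_shared` (shared-site counts) and `flagged` (data.frame of pairs with
#'   `phi >= flag_threshold`).
#' @export
king_kinship <- function(gt, flag_threshold = 0.177) {
  d <- dosage(gt)
  obs <- !is.na(d)
  het <- (d == 1L) & obs
  hom0 <- (d == 0L) & obs
  hom2 <- (d == 2L) & obs
  het[is.na(het)] <- FALSE; hom0[is.na(hom0)] <- FALSE; hom2[is.na(hom2)] <- FALSE
  storage.mode(het) <- "numeric"
  storage.mode(hom0) <- "numeric"; storage.mode(hom2) <- "numeric"
  obs_n <- matrix(as.numeric(obs), nrow(obs))
  n_both_het <- tcrossprod(het)
  n_opp <- tcrossprod(hom0, hom2) + tcrossprod(hom2, hom0)
  het_in_shared_i <- tcrossprod(het, obs_n)      # [i, j] = het sites of i observed in j
  denom <- het_in_shared_i + t(het_in_shared_i)
  phi <- (n_both_het - 2 * n_opp) / denom
  diag(phi) <- 0.5
  n_shared <- tcrossprod(obs_n)
  dimnames(phi) <- dimnames(n_shared) <- list(gt$samples, gt$samples)
  ut <- which(upper.tri(phi), arr.ind = TRUE)
  hot <- ut[!is.nan(phi[ut]) & phi[ut] >= flag_threshold, , drop = FALSE]
  flagged <- data.frame(ind1 = gt$samples[hot[, 1]],
                        ind2 = gt$samples[hot[, 2]],
                        phi = phi[hot],
                        n_shared = n_shared[hot])
  structure(list(phi = phi, n_shared = n_shared, flagged = flagged),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d individuals, %d flagged pair(s)\n",
              nrow(x$phi), nrow(x$flagged)))
  invisible(x)
}
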