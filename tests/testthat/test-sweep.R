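test_that("nSL is zero under symmetric tract structure", {
  # two ancestral and two derived haplotypes with mirrored flanking patterns
  h <- rbind(c(1, 0, 0, 0, 1, 0, 1),
             c(1, 0, 0, 0, 1, 0, 1),
             c(0, 1, 1, 1, 0, 1, 0),
             c(0, 1, 1, 1, 0, 1, 0))
  scan <- nsl_scan(hapmat(h), min_maf = 0, max_edge_frac = 1)
  expect_true(all(abs(scan$nsl) < 1e-12))
})

test_that("a 6-haplotype toy matches the brute-force pairwise-tract oracle", {
  # tabulated fixture: 6 haplotypes x 9 segregating sites
  h <- rbind(c(0, 1, 0, 0, 1, 0, 1, 0, 1),
             c(0, 1, 0, 0, 1, 0, 0, 1, 0),
             c(1, 0, 1, 0, 1, 1, 0, 1, 0),
             c(1, 0, 1, 1, 1, 1, 0, 0, 1),
             c(0, 0, 1, 1, 1, 1, 0, 1, 1),
             c(1, 1, 0, 0, 1, 0, 1, 0, 0))
  scan <- nsl_scan(hapmat(h), min_maf = 0, max_edge_frac = 1)
  oracle <- nsl_oracle(hapmat(h), min_maf = 0, max_edge_frac = 1)
  expect_equal(nrow(scan), nrow(oracle))
  expect_equal(scan$pos, oracle$pos)
  expect_equal(scan$sl_a, oracle$sl_a, tolerance = 1e-12)
  expect_equal(scan$sl_d, oracle$sl_d, tolerance = 1e-12)
  expect_equal(scan$nsl, oracle$nsl, tolerance = 1e-12)
})

test_that("the scan equals the oracle on random fixtures up to 12 x 40", {
  for (s in 1:8) {
    set.seed(300 + s)
    H <- sample(4:12, 1); S <- sample(10:40, 1)
    h <- matrix(stats::rbinom(H * S, 1, stats::runif(1, 0.3, 0.7)), H, S)
    # two contigs to exercise per-contig handling
    ctg <- rep(c("cA", "cB"), c(ceiling(S / 2), floor(S / 2)))
    hm <- hapmat(h, contig = ctg, pos = ave(seq_len(S), ctg, FUN = seq_along) * 50L)
    scan <- nsl_scan(hm, min_maf = 0.05, max_edge_frac = 0.05)
    oracle <- nsl_oracle(hm, min_maf = 0.05, max_edge_frac = 0.05)
    expect_equal(scan$pos, oracle$pos, info = paste("seed", s))
    expect_equal(scan$nsl, oracle$nsl, tolerance = 1e-12,
                 info = paste("seed", s))
  }
  expect_error(nsl_scan(hapmat(matrix(c(1, NA, 0, 1), 2, 2))), "missing")
})

test_that("frequency-bin standardisation centres and flags correctly", {
  # two SNPs sharing a bin with nsl {-1, 1} -> z exactly {-1, 1}
  scan <- data.frame(contig = "c1", pos = c(100L, 200L),
                     freq = c(0.412, 0.418), sl_a = 1, sl_d = 1,
                     nsl = c(-1, 1))
  class(scan) <- c("nsl_scan", "data.frame")
  ns <- normalize_nsl(scan)
  expect_equal(ns$z, c(-1, 1))   # moment SD of a two-point bin
  expect_false(any(ns$outlier))

  # per-bin means vanish after standardisation on a full-scale scan, and
  # under approximate normality the outlier share sits near 4.6%
  sim <- simulate_metapopulation(sim_config(n_pops = 6, n_dip_per_pop = 6,
                                            n_contigs = 4,
                                            snps_per_contig = 1000,
                                            n_sweep_loci = 0, seed = 33))
  scan2 <- nsl_scan(impute_haplotypes(haplotypes(sim$genotypes)))
  ns2 <- normalize_nsl(scan2)
  for (b in unique(ns2$bin)) {
    expect_lt(abs(mean(ns2$z[ns2$bin == b])), 1e-12)
  }
  # outlier flag is exactly |z| >= 2
  expect_equal(ns2$outlier, abs(ns2$z) >= 2)
  expect_lt(abs(mean(ns2$outlier) - 0.046), 0.02)
})

test_that("outlier merging follows the 50 kb linkage rule", {
  scan <- data.frame(contig = "c1", pos = c(10000L, 45000L, 120000L),
                     freq = 0.3, sl_a = 1, sl_d = 1, nsl = 0,
                     bin = 1L, z = c(2.5, -2.1, 3.0), outlier = TRUE)
  reg <- merge_outlier_regions(scan)
  expect_equal(reg$start, c(10000L, 120000L))
  expect_equal(reg$end, c(45000L, 120000L))
  expect_equal(reg$n_snps, c(2L, 1L))
  expect_equal(reg$max_abs_z, c(2.5, 3.0))

  none <- scan; none$outlier <- FALSE
  expect_equal(nrow(merge_outlier_regions(none)), 0)
})

test_that("merging equals an interval-union oracle on random position sets", {
  set.seed(44)
  for (rep in 1:200) {
    pos <- sort(sample.int(5e5, sample(2:25, 1)))
    scan <- data.frame(contig = "cX", pos = pos, freq = 0.3, sl_a = 1,
                       sl_d = 1, nsl = 0, bin = 1L, z = 2.5, outlier = TRUE)
    reg <- merge_outlier_regions(scan, gap_bp = 50000L)
    orc <- merge_oracle(pos, 50000L)
    expect_equal(reg$start, orc$start)
    expect_equal(reg$end, orc$end)
  }
})

test_that("overlap padding is inclusive at exactly 10 kb", {
  regions <- data.frame(contig = "c1", start = 100000L, end = 100000L,
                        n_snps = 1L, max_abs_z = 3)
  all_snps <- data.frame(contig = "c1",
                         pos = c(110000L, 110001L, seq(1000L, 90000L, 1000L)))
  inside <- overlap_permutation_test(
    data.frame(contig = "c1", pos = 110000L), regions, all_snps,
    n_perm = 49, seed = 1)
  outside <- overlap_permutation_test(
    data.frame(contig = "c1", pos = 110001L), regions, all_snps,
    n_perm = 49, seed = 1)
  expect_equal(inside$k, 1L)
  expect_equal(outside$k, 0L)
  expect_error(overlap_permutation_test(
    data.frame(contig = "c9", pos = 1L), regions, all_snps), "absent")
})

test_that("the permutation p follows its counting formula and preserves density", {
  set.seed(55)
  all_snps <- data.frame(contig = rep(c("c1", "c2"), each = 200),
                         pos = c(sort(sample.int(1e6, 200)),
                                 sort(sample.int(1e6, 200))))
  regions <- data.frame(contig = "c1", start = 1L, end = 200000L,
                        n_snps = 5L, max_abs_z = 2.5)
  cand <- data.frame(contig = rep(c("c1", "c2"), c(6, 4)),
                     pos = c(all_snps$pos[1:6], all_snps$pos[201:204]))
  res <- overlap_permutation_test(cand, regions, all_snps,
                                  n_perm = 200, seed = 2)
  expect_equal(res$p, (sum(res$null_k >= res$k) + 1) / 201)
  # with padding covering everything, every permutation reproduces k = total
  all_cover <- data.frame(contig = c("c1", "c2"), start = 1L, end = 1000000L,
                          n_snps = 1L, max_abs_z = 2)
  res2 <- overlap_permutation_test(cand, all_cover, all_snps,
                                   n_perm = 50, seed = 3)
  expect_equal(res2$k, 10L)
  expect_true(all(res2$null_k == 10L))  # per-contig candidate counts preserved
  expect_equal(res2$p, 1)
})

test_that("planted sweeps are recovered and uniform candidates are not enriched", {
  sim <- simulate_metapopulation(sim_config(n_contigs = 2,
                                            snps_per_contig = 400,
                                            n_sweep_loci = 2,
                                            sweep_freq = 0.4, seed = 66))
  scan <- normalize_nsl(nsl_scan(impute_haplotypes(haplotypes(sim$genotypes))))
  reg <- merge_outlier_regions(scan)
  hits <- vapply(sim$truth$sweep_locus_ids, function(id) {
    ctg <- sub(":.*", "", id); p <- as.integer(sub(".*:", "", id))
    r <- reg[reg$contig == ctg, ]
    nrow(r) > 0 && any(p >= r$start - 10000 & p <= r$end + 10000)
  }, logical(1))
  expect_true(all(hits))
})
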