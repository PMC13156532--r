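pops2 <- function(gt, split_at) {
  data.frame(pop = rep(c("A", "B"), c(split_at, n_individuals(gt) - split_at)),
             individual = gt$samples)
}

test_that("expected heterozygosity and its callable-site adjustment", {
  # a site at p = 0.5 contributes He = 0.5; monomorphic sites are excluded
  d <- cbind(c(0L, 1L, 1L, 2L), rep(2L, 4), c(0L, 0L, 2L, 2L))
  gt <- gt_from_dosage(d)
  pops <- data.frame(pop = "A", individual = gt$samples)
  he <- expected_heterozygosity(gt, pops, c(A = 1000))
  expect_equal(he$n_polymorphic, 2)
  expect_equal(he$H_EXP, 0.5)           # both polymorphic sites have p = 0.5
  expect_equal(he$adjH_EXP, 0.5 * 2 / 1000)
  expect_error(expected_heterozygosity(gt, pops, c(A = 0)), "positive")

  # the printed-formula check: H 0.25, 2000 polymorphic, 1e6 callable
  expect_equal(0.25 * 2000 / 1e6, 5e-4)
})

test_that("per-population He equals an independent per-site loop", {
  sim <- simulate_metapopulation(sim_config(n_pops = 4, n_dip_per_pop = 5,
                                            n_contigs = 1,
                                            snps_per_contig = 80,
                                            missing_rate = 0.05, seed = 9))
  he <- expected_heterozygosity(sim$genotypes, sim$pops,
                                sim$truth$n_callable)
  d <- dosage(sim$genotypes)
  for (pp in unique(sim$pops$pop)) {
    rows <- which(sim$genotypes$samples %in%
                    sim$pops$individual[sim$pops$pop == pp])
    hes <- c(); npoly <- 0
    for (j in seq_len(ncol(d))) {
      g <- d[rows, j]; g <- g[!is.na(g)]
      if (!length(g)) next
      p <- sum(g) / (2 * length(g))
      if (p > 0 && p < 1) {
        npoly <- npoly + 1
        hes <- c(hes, 1 - p^2 - (1 - p)^2)
      }
    }
    row <- he[he$pop == pp, ]
    expect_equal(row$n_polymorphic, npoly)
    expect_equal(row$H_EXP, mean(hes))
    expect_equal(row$adjH_EXP, row$H_EXP * row$n_polymorphic / row$n_callable)
  }
})

test_that("Weir-Cockerham theta is 1 under complete fixation", {
  d <- rbind(matrix(0L, 5, 10), matrix(2L, 5, 10))
  gt <- gt_from_dosage(d)
  fst <- pairwise_fst(gt, pops2(gt, 5), n_boot = 50, seed = 1)
  expect_equal(fst$fst["A", "B"], 1)
  expect_equal(fst$fst["B", "A"], 1)
  expect_equal(diag(fst$fst), c(A = 0, B = 0))
})

test_that("multilocus theta matches the variance-components oracle on a 5-locus fixture", {
  d1 <- rbind(c(0L, 1L, 2L, 1L, 0L),
              c(1L, 1L, 2L, 0L, 0L),
              c(0L, 2L, 1L, 1L, 1L),
              c(1L, 0L, 2L, 2L, 0L))
  d2 <- rbind(c(2L, 0L, 0L, 1L, 1L),
              c(2L, 1L, 0L, 0L, 2L),
              c(1L, 0L, 1L, 1L, 1L),
              c(2L, 0L, 0L, 2L, 2L))
  gt <- gt_from_dosage(rbind(d1, d2))
  fst <- pairwise_fst(gt, pops2(gt, 4), n_boot = 50, seed = 2)
  expect_equal(fst$fst["A", "B"], wc84_theta_oracle(d1, d2), tolerance = 1e-12)
  # linearisation invariant
  expect_equal(fst$linearized, fst$fst / (1 - fst$fst))
})

test_that("panmictic samples give theta near zero with CIs covering zero", {
  covered <- 0; thetas <- numeric(10)
  for (s in 1:10) {
    set.seed(100 + s)
    m <- 400
    p <- stats::runif(m, 0.1, 0.9)
    d <- t(replicate(12, stats::rbinom(m, 2, p)))
    storage.mode(d) <- "integer"
    gt <- gt_from_dosage(d)
    fst <- pairwise_fst(gt, pops2(gt, 6), n_boot = 200, seed = s)
    thetas[s] <- fst$fst["A", "B"]
    if (fst$ci_lower["A", "B"] <= 0 && fst$ci_upper["A", "B"] >= 0) {
      covered <- covered + 1
    }
  }
  expect_lt(abs(mean(thetas)), 0.02)
  expect_gte(covered, 9)   # >= 90% of replicates
})

test_that("Mantel r is exact for proportional matrices and enumerable at n = 4", {
  geo <- as.matrix(stats::dist(cbind(c(0, 1, 3, 7), c(0, 2, 1, 4))))
  gen <- 2 * geo
  res <- mantel_ibd(gen, geo, log_geo = FALSE, n_perm = 99)
  expect_equal(res$r, 1)

  set.seed(5)
  gen2 <- as.matrix(stats::dist(stats::rnorm(4)))
  r_obs <- stats::cor(gen2[upper.tri(gen2)], geo[upper.tri(geo)])
  ex <- mantel_ibd(gen2, geo, log_geo = FALSE, method = "exact")
  # oracle: enumerate all 24 relabelings independently
  rs <- vapply(perms_oracle(4), function(p) {
    stats::cor(gen2[upper.tri(gen2)], geo[p, p][upper.tri(geo)])
  }, numeric(1))
  expect_equal(ex$p, mean(rs >= r_obs - 1e-12))
  expect_equal(ex$n_perm, 24)

  # sampled p agrees with the exact p within Monte-Carlo error
  sm <- mantel_ibd(gen2, geo, log_geo = FALSE, n_perm = 4999, seed = 3)
  expect_lt(abs(sm$p - ex$p), 3 * sqrt(ex$p * (1 - ex$p) / 5000) + 1e-3)
})

test_that("jointly permuting both matrices leaves Mantel r unchanged", {
  set.seed(8)
  a <- as.matrix(stats::dist(stats::rnorm(6)))
  b <- as.matrix(stats::dist(stats::rnorm(6)))
  r0 <- mantel_ibd(a, b, log_geo = FALSE, n_perm = 9)$r
  p <- sample(6)
  r1 <- mantel_ibd(a[p, p], b[p, p], log_geo = FALSE, n_perm = 9)$r
  expect_equal(r0, r1)
  expect_error(mantel_ibd(matrix(1, 4, 4) - diag(4) * 0, b, log_geo = FALSE),
               "constant")
})

test_that("Mantel test agrees with an established implementation", {
  skip_if_not_installed("vegan")
  set.seed(12)
  a <- as.matrix(stats::dist(stats::rnorm(8)))
  b <- as.matrix(stats::dist(stats::rnorm(8)))
  ours <- mantel_ibd(a, b, log_geo = FALSE, n_perm = 999, seed = 1)
  ref <- vegan::mantel(a, b, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
})

test_that("BIC cluster search finds planted structure and its absence", {
  set.seed(14)
  # two clusters separated at 30% of loci by strongly shifted frequencies
  m <- 300
  p <- stats::runif(m, 0.2, 0.8)
  sep <- sample(m, 90)
  p1 <- p; p1[sep] <- pmin(0.98, p[sep] + 0.45)
  p2 <- p; p2[sep] <- pmax(0.02, p[sep] - 0.45)
  d <- rbind(t(replicate(30, stats::rbinom(m, 2, p1))),
             t(replicate(30, stats::rbinom(m, 2, p2))))
  storage.mode(d) <- "integer"
  sol <- cluster_bic(gt_from_dosage(d), K_max = 5, seed = 2)
  expect_equal(sol$chosen_K, 2)
  expect_length(sol$bic, 5)
  expect_equal(length(unique(sol$assignments[1:30])), 1)

  # one panmictic pool
  d2 <- t(replicate(30, stats::rbinom(m, 2, p)))
  storage.mode(d2) <- "integer"
  sol2 <- cluster_bic(gt_from_dosage(d2), K_max = 5, seed = 2)
  expect_equal(sol2$chosen_K, 1)
  expect_error(cluster_bic(gt_from_dosage(d2), K_max = 40), "K_max")
})

test_that("PCoA recovers planar configurations up to rotation", {
  set.seed(4)
  X <- cbind(stats::rnorm(4), stats::rnorm(4))
  res <- pcoa(as.matrix(stats::dist(X)), k = 2)
  # Procrustes: optimal rotation of recovered onto original
  A <- scale(res$coords, scale = FALSE)
  B <- scale(X, scale = FALSE)
  sv <- svd(crossprod(B, A))
  rot <- A %*% sv$v %*% t(sv$u)
  expect_lt(sqrt(mean((rot - B)^2)), 1e-8)
  expect_true(all(diff(res$eigenvalues) <= 1e-9))

  expect_equal(pcoa(matrix(0, 3, 3))$coords,
               matrix(0, 3, 2, dimnames = list(NULL, NULL)),
               ignore_attr = TRUE)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
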