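#' Configuration for the metapopulation simulator
#'
#' Defines the sampling design and genetic architecture emulated by
#' [simulate_metapopulation()]: a set of populations sampled along an
#' urbanisation gradient (impervious surface cover), neutral background
#' variation with weak differentiation, clinal loci whose allele frequencies
#' track the gradient, and sweep loci whose derived-allele carriers share an
#' extended haplotype.
#'
#' Defaults mirror the sampling design the package targets: 10 populations of
#' 7 diploid females, low background differentiation, impervious cover
#' spanning 5-70%, mean genotype depth 15x.
#'
#' @param n_pops number of populations.
#' @param n_dip_per_pop diploid individuals sampled per population.
#' @param n_contigs number of contigs.
#' @param snps_per_contig SNPs drawn per contig (duplicated positions are
#'   dropped, so the realised count can be slightly lower).
#' @param contig_length_bp contig length in base pairs.
#' @param env_range numeric length-2: range of impervious surface cover (%).
#' @param n_gea_loci number of planted environment-associated (clinal) loci.
#' @param gea_effect slope of population allele frequency per unit of the
#'   standardised environmental value.
#' @param n_sweep_loci number of planted sweep focal loci.
#' @param sweep_freq derived allele frequency at each sweep focal locus.
#' @param sweep_halo_bp length (bp) of the homogenised haplotype around each
#'   sweep focal site.
#' @param depth_mean mean per-genotype read depth (Poisson).
#' @param missing_rate probability that a genotype is missing.
#' @param fst background differentiation among populations for neutral loci
#'   (beta model concentration), matching the weak structure of the target
#'   system.
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#'
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pops = 10, n_dip_per_pop = 7, n_contigs = 4,
                       snps_per_contig = 500, contig_length_bp = 1e6,
                       env_range = c(5, 70), n_gea_loci = 20,
                       gea_effect = 0.4, n_sweep_loci = 2, sweep_freq = 0.4,
                       sweep_halo_bp = 1e5, depth_mean = 15,
                       missing_rate = 0.02, fst = 0.02, seed = 1L) {
  cfg <- list(n_pops = n_pops, n_dip_per_pop = n_dip_per_pop,
              n_contigs = n_contigs, snps_per_contig = snps_per_contig,
              contig_length_bp = contig_length_bp, env_range = env_range,
              n_gea_loci = n_gea_loci, gea_effect = gea_effect,
              n_sweep_loci = n_sweep_loci, sweep_freq = sweep_freq,
              sweep_halo_bp = sweep_halo_bp, depth_mean = depth_mean,
              missing_rate = missing_rate, fst = fst, seed = as.integer(seed))
  counts <- c("n_pops", "n_dip_per_pop", "n_contigs", "snps_per_contig",
              "contig_length_bp")
  if (any(unlist(cfg[counts]) <= 0)) stop("all counts must be > 0")
  if (length(env_range) != 2 || any(env_range < 0) || any(env_range > 100)) {
    stop("env_range must lie within [0, 100]")
  }
  if (sweep_freq <= 0 || sweep_freq >= 1) stop("sweep_freq must be in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a sampled metapopulation along an urbanisation gradient
#'
#' Generates phased diploid genotypes for `n_pops` populations. Neutral loci
#' draw a shared ancestral frequency from Beta(0.8, 0.8) truncated to
#' \[0.05, 0.95\] and per-population frequencies from the Balding-Nichols
#' beta model at the configured background `fst`. Planted clinal loci set the
#' population frequency to `clamp(p0 + gea_effect * z_k, 0.01, 0.99)`, where
#' `z_k` is the standardised impervious-cover value of population k. Planted
#' sweep loci assign the derived allele to haplotypes with probability
#' `sweep_freq` and copy a single donor haplotype onto all derived carriers
#' over `sweep_halo_bp` around the focal site, producing the extended shared
#' haplotypes a sweep scan detects. Per-genotype depth is Poisson, genotypes
#' go missing independently at `missing_rate`.
#'
#' Environmental values are evenly spaced across `env_range` and jittered,
#' guaranteeing gradient coverage; the environment table also carries
#' correlated urban-green / semi-natural / edge-density covariates.
#'
#' @param config a [sim_config()].
#' @return a list with elements `genotypes` (a [genotype_table()]), `pops`
#'   (data.frame: pop, individual, lat, lon), `env` (data.frame: pop,
#'   impervious, urban_green, seminatural, edge_density), and `truth` (list:
#'   `gea_locus_ids`, `sweep_locus_ids`, `gea_effects`, `n_callable` per
#'   population, `env_z`).
#' @export
simulate_metapopulation <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_pops <- config$n_pops
  n_ind <- n_pops * config$n_dip_per_pop
  n_hap <- 2L * n_ind
  pop_of_ind <- rep(seq_len(n_pops), each = config$n_dip_per_pop)
  pop_of_hap <- rep(pop_of_ind, each = 2L)

  # environment: even spacing + jitter, then correlated covariates
  spacing <- diff(config$env_range) / max(1, n_pops - 1)
  imperv <- seq(config$env_range[1], config$env_range[2], length.out = n_pops)
  imperv <- imperv + stats::runif(n_pops, -0.25, 0.25) * spacing
  imperv <- pmin(100, pmax(0, imperv))
  z <- as.numeric(scale(imperv))
  env <- data.frame(
    pop = paste0("P", seq_len(n_pops)),
    impervious = imperv,
    urban_green = pmin(100, pmax(0, 25 + 0.2 * imperv + stats::rnorm(n_pops, 0, 6))),
    seminatural = pmin(100, pmax(0, 60 - 0.5 * imperv + stats::rnorm(n_pops, 0, 8))),
    edge_density = pmax(0, 0.02 + 0.0005 * imperv + stats::rnorm(n_pops, 0, 0.004))
  )
  # site coordinates around a city centre (~52.27N, 10.52E), >= ~1 km apart
  pops <- data.frame(
    pop = rep(env$pop, each = config$n_dip_per_pop),
    individual = paste0("ind", formatC(seq_len(n_ind), width = 3, flag = "0")),
    lat = rep(52.27 + stats::runif(n_pops, -0.08, 0.08), each = config$n_dip_per_pop),
    lon = rep(10.52 + stats::runif(n_pops, -0.12, 0.12), each = config$n_dip_per_pop)
  )

  contigs <- character(0); positions <- integer(0)
  for (c_i in seq_len(config$n_contigs)) {
    p <- sort(unique(sample.int(config$contig_length_bp,
                                config$snps_per_contig, replace = TRUE)))
    contigs <- c(contigs, rep(sprintf("contig_%02d", c_i), length(p)))
    positions <- c(positions, p)
  }
  m <- length(positions)

  # locus classes: disjoint neutral / clinal / sweep sets
  if (config$n_gea_loci + config$n_sweep_loci > m) {
    stop("configuration error: more planted loci than simulated SNPs")
  }
  gea_idx <- sample.int(m, config$n_gea_loci)
  # sweep focal sites must fit their halo inside the contig: a clipped halo
  # leaves tracts truncated at the contig end and is undetectable by design
  half <- config$sweep_halo_bp / 2
  eligible <- setdiff(
    which(positions >= half & positions <= config$contig_length_bp - half),
    gea_idx)
  if (length(eligible) < config$n_sweep_loci) {
    stop("configuration error: contigs too short for the sweep halo")
  }
  sweep_idx <- sample(eligible, config$n_sweep_loci)

  # per-population allele frequencies
  p0 <- pmin(0.95, pmax(0.05, stats::rbeta(m, 0.8, 0.8)))
  fst <- config$fst
  theta <- (1 - fst) / fst
  pk <- matrix(stats::rbeta(n_pops * m,
                            rep(p0, each = n_pops) * theta,
                            rep(1 - p0, each = n_pops) * theta),
               nrow = n_pops)
  if (length(gea_idx)) {
    p0g <- stats::runif(length(gea_idx), 0.3, 0.7)
    pk[, gea_idx] <- pmin(0.99, pmax(0.01,
      matrix(rep(p0g, each = n_pops), nrow = n_pops) +
        config$gea_effect * matrix(rep(z, length(gea_idx)), nrow = n_pops)))
  }

  hap <- matrix(0L, n_hap, m)
  u <- matrix(stats::runif(n_hap * m), n_hap, m)
  hap[u < pk[pop_of_hap, , drop = FALSE]] <- 1L

  # plant sweeps: shared donor haplotype over the halo around each focal SNP
  for (s in sweep_idx) {
    carriers <- which(stats::runif(n_hap) < config$sweep_freq)
    if (length(carriers) < 2L) carriers <- sample.int(n_hap, 2L)
    hap[, s] <- 0L
    hap[carriers, s] <- 1L
    halo <- which(contigs == contigs[s] &
                    abs(positions - positions[s]) <= config$sweep_halo_bp / 2)
    donor <- hap[carriers[1L], halo]
    hap[carriers, halo] <- rep(donor, each = length(carriers))
    hap[carriers, s] <- 1L
  }

  dp <- matrix(stats::rpois(n_ind * m, config$depth_mean), n_ind, m)
  gq <- matrix(pmin(99L, stats::rpois(n_ind * m, 45L)), n_ind, m)
  qual <- round(30 + stats::rexp(m, 1 / 40), 2)
  miss <- matrix(stats::runif(n_ind * m) < config$missing_rate, n_ind, m)
  if (any(miss)) {
    idx <- which(miss)
    r <- ((idx - 1L) %% n_ind) + 1L
    cc <- ((idx - 1L) %/% n_ind) + 1L
    hap[cbind(2L * r - 1L, cc)] <- NA_integer_
    hap[cbind(2L * r, cc)] <- NA_integer_
    dp[miss] <- 0L
    gq[miss] <- 0L
  }

  ids <- paste0(contigs, ":", positions)
  gt <- genotype_table(
    contig = contigs, pos = positions,
    ref = sample(c("A", "C", "G", "T"), m, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), m, replace = TRUE),
    qual = qual, hap = hap, dp = dp, gq = gq,
    samples = pops$individual
  )
  truth <- list(
    gea_locus_ids = ids[sort(gea_idx)],
    sweep_locus_ids = ids[sort(sweep_idx)],
    gea_effects = stats::setNames(rep(config$gea_effect, length(gea_idx)),
                                  ids[gea_idx])[order(gea_idx)],
    n_callable = stats::setNames(
      rep(round(0.9 * config$n_contigs * config$contig_length_bp), n_pops),
      env$pop),
    env_z = stats::setNames(z, env$pop)
  )
  list(genotypes = gt, pops = pops, env = env, truth = truth)
}
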