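#' Per-population expected heterozygosity, adjusted for callable sites
#'
#' Per site and population, `He = 1 - sum(p_a^2)` over the two allele
#' frequencies computed from that population's non-missing genotypes.
#' `H_EXP` is the mean of `He` over the population's polymorphic sites, and
#' the adjusted value scales it by the fraction of callable sites that are
#' polymorphic: `adjH_EXP = H_EXP * n_polymorphic / n_callable`. This makes
#' diversity comparable across datasets with different numbers of monomorphic
#' callable positions.
#'
#' @param gt a [genotype_table()].
#' @param pops data.frame with columns `pop` and `individual` assigning each
#'   sample to a population.
#' @param n_callable named numeric vector of callable-site counts per
#'   population (from all-sites accounting, or simulation truth).
#' @return data.frame: pop, H_EXP, n_polymorphic, n_callable, adjH_EXP.
#' @export
expected_heterozygosity <- function(gt, pops, n_callable) {
  pop_ids <- unique(pops$pop)
  if (any(!(pop_ids %in% names(n_callable)))) {
    stop("n_callable must be named for every population")
  }
  if (any(n_callable[pop_ids] <= 0)) stop("n_callable must be positive")
  d <- dosage(gt)
  out <- lapply(pop_ids, function(pp) {
    rows <- match(pops$individual[pops$pop == pp], gt$samples)
    dp <- d[rows, , drop = FALSE]
    n_called <- colSums(!is.na(dp))
    p <- colSums(dp, na.rm = TRUE) / (2 * n_called)
    he <- 1 - p^2 - (1 - p)^2
    poly <- n_called > 0 & p > 0 & p < 1
    data.frame(pop = pp,
               H_EXP = if (any(poly)) mean(he[poly]) else 0,
               n_polymorphic = sum(poly),
               n_callable = unname(n_callable[pp]))
  })
  out <- do.call(rbind, out)
  out$adjH_EXP <- out$H_EXP * out$n_polymorphic / out$n_callable
  out
}

# Weir & Cockerham (1984) variance components a, b, c for one biallelic locus
# across r populations. n_i = called individuals, p_i = ALT frequency,
# h_i = observed heterozygote proportion.
wc_components <- function(n_i, p_i, h_i) {
  keep <- n_i > 0
  n_i <- n_i[keep]; p_i <- p_i[keep]; h_i <- h_i[keep]
  r <- length(n_i)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# per-locus WC components for one pair of populations
pairwise_wc_locus <- function(d1, d2) {
  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  p1 <- colSums(d1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(d2, na.rm = TRUE) / (2 * n2)
  h1 <- colMeans(d1 == 1L, na.rm = TRUE)
  h2 <- colMeans(d2 == 1L, na.rm = TRUE)
  t(vapply(seq_along(n1), function(j) {
    wc_components(c(n1[j], n2[j]), c(p1[j], p2[j]), c(h1[j], h2[j]))
  }, numeric(3)))
}

#' Pairwise Weir-Cockerham FST with locus bootstrap
#'
#' The multilocus estimator for each population pair is
#' `theta = sum(a) / sum(a + b + c)` over loci, from the Weir-Cockerham
#' (1984) variance components. Percentile 95% confidence intervals and a
#' one-sided bootstrap p-value `p(theta <= 0)` come from resampling loci with
#' replacement.
#'
#' @param gt a [genotype_table()].
#' @param pops data.frame with `pop` and `individual` columns.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return a `fst_matrix`: list with matrices `fst`, `ci_lower`, `ci_upper`,
#'   `p_value` (upper triangles filled, symmetric), `linearized`
#'   (`fst / (1 - fst)`), and `pop_ids`.
#' @export
pairwise_fst <- function(gt, pops, n_boot = 1000L, seed = 1L) {
  set.seed(seed)
  pop_ids <- unique(pops$pop)
  K <- length(pop_ids)
  if (K < 2) stop("need at least two populations")
  d <- dosage(gt)
  rows_of <- lapply(pop_ids, function(pp) {
    r <- match(pops$individual[pops$pop == pp], gt$samples)
    if (length(r) < 2) stop("need >= 2 individuals per population")
    r
  })
  fst <- ci_lo <- ci_hi <- pval <- matrix(0, K, K,
                                          dimnames = list(pop_ids, pop_ids))
  for (i in seq_len(K - 1)) {
    for (j in seq(i + 1, K)) {
      di <- d[rows_of[[i]], , drop = FALSE]
      dj <- d[rows_of[[j]], , drop = FALSE]
      if (all(colSums(!is.na(di)) == 0) || all(colSums(!is.na(dj)) == 0)) {
        stop("a population has no called genotypes")
      }
      comp <- pairwise_wc_locus(di, dj)
      ok <- stats::complete.cases(comp)
      comp <- comp[ok, , drop = FALSE]
      theta <- sum(comp[, "a"]) / sum(rowSums(comp))
      boots <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(comp), replace = TRUE)
        sum(comp[idx, "a"]) / sum(comp[idx, ])
      }, numeric(1))
      fst[i, j] <- fst[j, i] <- theta
      q <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
      ci_lo[i, j] <- ci_lo[j, i] <- q[1]
      ci_hi[i, j] <- ci_hi[j, i] <- q[2]
      pval[i, j] <- pval[j, i] <- (sum(boots <= 0, na.rm = TRUE) + 1) / (n_boot + 1)
    }
  }
  diag(pval) <- NA_real_
  structure(list(fst = fst, ci_lower = ci_lo, ci_upper = ci_hi,
                 p_value = pval, linearized = fst / (1 - fst),
                 pop_ids = pop_ids),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  ut <- x$fst[upper.tri(x$fst)]
  cat(sprintf("fst_matrix: %d populations, mean pairwise FST = %.4f\n",
              nrow(x$fst), mean(ut)))
  invisible(x)
}

#' Great-circle distance matrix (haversine, Earth radius 6371 km)
#'
#' @param coords data.frame with `lat` and `lon` columns (decimal degrees),
#'   one row per location.
#' @return symmetric matrix of distances in kilometres.
#' @export
greatcircle_km <- function(coords) {
  n <- nrow(coords)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    m[i, ] <- geosphere::distHaversine(
      c(coords$lon[i], coords$lat[i]),
      cbind(coords$lon, coords$lat), r = 6371000) / 1000
  }
  (m + t(m)) / 2
}

#' Mantel test of isolation by distance
#'
#' Correlates linearised genetic distance `FST / (1 - FST)` with
#' log-transformed great-circle distance. The Mantel r is the Pearson
#' correlation of the vectorised upper triangles; significance comes from
#' permuting rows/columns of one matrix, with
#' `p = (# permuted r >= observed + 1) / (n_perm + 1)`. With
#' `method = "exact"` all `n!` permutations are enumerated (n <= 8).
#'
#' @param gen_dist symmetric genetic distance matrix (e.g. the `linearized`
#'   element of [pairwise_fst()]).
#' @param geo_dist symmetric geographic distance matrix (km); log-transformed
#'   internally when `log_geo = TRUE`.
#' @param n_perm sampled permutations (default 9999).
#' @param seed RNG seed.
#' @param log_geo log-transform the geographic distances (default TRUE).
#' @param method `"sampled"` or `"exact"` permutation null.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_ibd <- function(gen_dist, geo_dist, n_perm = 9999L, seed = 1L,
                       log_geo = TRUE, method = c("sampled", "exact")) {
  method <- match.arg(method)
  stopifnot(isSymmetric(unname(gen_dist)), isSymmetric(unname(geo_dist)))
  g <- if (log_geo) log(geo_dist) else geo_dist
  n <- nrow(gen_dist)
  ut <- upper.tri(gen_dist)
  x <- gen_dist[ut]
  if (stats::sd(x) == 0 || stats::sd(g[ut]) == 0) {
    stop("constant distance matrix")
  }
  r_obs <- stats::cor(x, g[ut])
  perm_r <- function(ord) stats::cor(x, g[ord, ord][ut])
  if (method == "exact") {
    if (n > 8) stop("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    rs <- vapply(perms, perm_r, numeric(1))
    # identity permutation included in the reference set
    p <- mean(rs >= r_obs - 1e-12)
    return(list(r = r_obs, p = p, n_perm = length(perms)))
  }
  set.seed(seed)
  rs <- vapply(seq_len(n_perm), function(b) perm_r(sample.int(n)), numeric(1))
  p <- (sum(rs >= r_obs - 1e-12) + 1) / (n_perm + 1)
  list(r = r_obs, p = p, n_perm = n_perm)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) {
    for (i in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(s, n, after = i)
    }
  }
  out
}

#' Cluster search with k-means and BIC
#'
#' Genotypes are encoded as 0/1/2 dosages, mean-imputed, reduced to the
#' principal components retaining at least `var_retained` of the variance,
#' then k-means is run for K = 1..K_max (`nstart = 20`, seeded). The score is
#' `BIC(K) = n * log(WSS_K / n) + K * log(n)` and the chosen K minimises it.
#'
#' @param gt a [genotype_table()].
#' @param K_max largest number of clusters to try (must be < n individuals).
#' @param var_retained PC variance fraction retained (default 0.9).
#' @param seed RNG seed.
#' @return a `cluster_solution`: list with `K_grid`, `bic`, `chosen_K`,
#'   `assignments`, `scores` (PC coordinates used).
#' @export
cluster_bic <- function(gt, K_max = 10L, var_retained = 0.9, seed = 1L) {
  n <- n_individuals(gt)
  if (K_max >= n) stop("K_max must be smaller than the number of individuals")
  d <- dosage(gt)
  cm <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- cm[idx[, 2]]
  d <- d[, apply(d, 2, stats::sd) > 0, drop = FALSE]
  pc <- stats::prcomp(d, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k_pc <- max(1L, which(cum >= var_retained)[1])
  scores <- pc$x[, seq_len(k_pc), drop = FALSE]
  set.seed(seed)
  fits <- lapply(seq_len(K_max), function(K) {
    if (K == 1) {
      wss <- sum(scale(scores, scale = FALSE)^2)
      list(cluster = rep(1L, n), wss = wss)
    } else {
      km <- stats::kmeans(scores, centers = K, nstart = 20, iter.max = 50)
      list(cluster = km$cluster, wss = km$tot.withinss)
    }
  })
  bic <- vapply(seq_len(K_max), function(K) {
    n * log(fits[[K]]$wss / n) + K * log(n)
  }, numeric(1))
  chosen <- which.min(bic)
  structure(list(K_grid = seq_len(K_max), bic = bic, chosen_K = chosen,
                 assignments = fits[[chosen]]$cluster, scores = scores),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: chosen K = %d (grid 1..%d)\n",
              x$chosen_K, max(x$K_grid)))
  invisible(x)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres the squared distance matrix and eigendecomposes it;
#' coordinates are ordered by decreasing eigenvalue.
#'
#' @param dist_matrix symmetric distance matrix with zero diagonal.
#' @param k number of coordinate axes to return (default `n - 1`).
#' @return list with `coords` (n x k) and `eigenvalues` (length n - 1,
#'   non-increasing).
#' @export
pcoa <- function(dist_matrix, k = nrow(dist_matrix) - 1L) {
  dm <- as.matrix(dist_matrix)
  if (!isSymmetric(unname(dm))) stop("distance matrix must be symmetric")
  if (any(abs(diag(dm)) > 1e-12)) stop("distance matrix must have zero diagonal")
  n <- nrow(dm)
  B <- -0.5 * dm^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))  # second sweep also restores the grand mean
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values[seq_len(n - 1L)]
  k <- min(k, n - 1L)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  rownames(coords) <- rownames(dm)
  list(coords = coords, eigenvalues = ev)
}

#' Euclidean genotype distance between individuals
#'
#' Mean-imputed 0/1/2 dosages; the standard input for [pcoa()] on genotype
#' data (equivalent to genotype PCA up to scaling).
#'
#' @param gt a [genotype_table()].
#' @return symmetric distance matrix (individuals x individuals).
#' @export
genotype_distance <- function(gt) {
  d <- dosage(gt)
  cm <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- cm[idx[, 2]]
  as.matrix(stats::dist(d))
}
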