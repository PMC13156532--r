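#' Population allele-frequency matrix
#'
#' Missing genotypes are imputed with the most common (modal) genotype at
#' each SNP across all individuals, then per-population alternate-allele
#' frequencies are `alt count / (2 * n individuals)`.
#'
#' @param gt a [genotype_table()].
#' @param pops data.frame with `pop` and `individual` columns.
#' @return a `freq_matrix`: populations x SNPs numeric matrix with SNP ids as
#'   column names and attributes `contig`, `pos`, `n_ind` (per population).
#' @export
pop_allele_frequencies <- function(gt, pops) {
  d <- dosage(gt)
  # modal genotype per SNP (ties -> smaller dosage)
  modal <- apply(d, 2, function(col) {
    tab <- tabulate(col + 1L, nbins = 3L)
    which.max(tab) - 1L
  })
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- modal[idx[, 2]]
  pop_ids <- unique(pops$pop)
  freq <- matrix(NA_real_, length(pop_ids), n_sites(gt),
                 dimnames = list(pop_ids, site_ids(gt)))
  for (pp in pop_ids) {
    rows <- match(pops$individual[pops$pop == pp], gt$samples)
    if (!length(rows) || anyNA(rows)) stop("empty or unknown population: ", pp)
    freq[pp, ] <- colSums(d[rows, , drop = FALSE]) / (2 * length(rows))
  }
  structure(freq, contig = gt$contig, pos = gt$pos,
            n_ind = vapply(pop_ids, function(pp) sum(pops$pop == pp), 1L),
            class = c("freq_matrix", "matrix"))
}

# Ridge-penalised latent factor model fit plus per-SNP association tests.
# Y (n x M) response, x environmental vector (length n), K latent factors.
# Returns effects, z-scores, raw and GIF-calibrated p-values.
lfmm_fit_test <- function(Y, x, K, lambda = 1e-5) {
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  xc <- x - mean(x)
  U <- NULL
  if (K > 0) {
    sigma <- sqrt(sum(xc^2))
    Qc <- qr.Q(qr(matrix(xc, ncol = 1)), complete = TRUE)
    dvec <- c(sqrt(lambda / (lambda + sigma^2)), rep(1, n - 1))
    M1 <- dvec * crossprod(Qc, Yc)
    sv <- svd(M1, nu = K, nv = 0)
    U <- Qc %*% ((1 / dvec) * sv$u[, seq_len(K), drop = FALSE]) %*%
      diag(sv$d[seq_len(K)], K)
  }
  Z <- cbind(1, x, U)
  p_par <- ncol(Z)
  qrz <- qr(Z)
  coefs <- qr.coef(qrz, Y)
  res <- Y - Z %*% coefs
  rss <- colSums(res^2)
  xtxinv_22 <- chol2inv(qr.R(qrz))[2, 2]
  df <- n - p_par
  se <- sqrt(xtxinv_22 * rss / df)
  tstat <- coefs[2, ] / se
  tstat[!is.finite(tstat)] <- 0   # constant columns carry no association
  p_raw <- 2 * stats::pt(-abs(tstat), df)
  gif <- stats::median(tstat^2, na.rm = TRUE) / stats::qchisq(0.5, 1)
  p_cal <- stats::pchisq(tstat^2 / gif, df = 1, lower.tail = FALSE)
  list(effect = coefs[2, ], z = tstat, p_raw = p_raw, p_cal = p_cal,
       gif = gif, U = U)
}

#' Latent factor ridge regression for genotype-environment association
#'
#' Fits `Y = X B' + U V' + E` to population allele frequencies by
#' ridge-penalised least squares, solved through the SVD: with
#' `X = Q Sigma R'`, the latent part is the best rank-K approximation of
#' `D_lambda Q' Y`, where `D_lambda` shrinks the directions spanned by X.
#' Association tests then regress each SNP on the environment plus the
#' estimated factors; z-scores are calibrated with the genomic inflation
#' factor `median(z^2) / 0.456` (0.456 = median of chi-squared(1)) and
#' calibrated p-values are `pchisq(z^2 / gif, 1, lower = FALSE)`.
#'
#' With `K = 0` the procedure reduces to per-SNP simple linear regression.
#'
#' @param freq a [pop_allele_frequencies()] matrix (populations x SNPs).
#' @param env numeric environmental value per population (standardised
#'   internally).
#' @param K number of latent factors (`0 <= K < n_pops - 1`).
#' @param lambda ridge penalty (default 1e-5).
#' @return an `lfmm_result` data.frame: snp, contig, pos, effect, z, p_raw,
#'   p (calibrated); attribute `gif`.
#' @export
lfmm_ridge <- function(freq, env, K = 1L, lambda = 1e-5) {
  n <- nrow(freq)
  if (stats::sd(env) == 0) stop("constant environmental variable")
  if (K < 0 || K >= n - 1) stop("K must satisfy 0 <= K < n_pops - 1")
  x <- as.numeric(scale(env))
  ft <- lfmm_fit_test(unclass(freq), x, K, lambda)
  out <- data.frame(snp = colnames(freq),
                    contig = attr(freq, "contig"), pos = attr(freq, "pos"),
                    effect = ft$effect, z = ft$z, p_raw = ft$p_raw,
                    p = ft$p_cal, row.names = NULL)
  attr(out, "gif") <- ft$gif
  attr(out, "K") <- K
  class(out) <- c("lfmm_result", "data.frame")
  out
}

#' Empirical significance threshold from environment permutations
#'
#' Re-runs the full latent-factor fit (including factor re-estimation and
#' genomic-inflation calibration) on `n_perm` random reorderings of the
#' environmental variable, pools all null calibrated p-values, and takes
#' their 0.1st percentile (by default) as the significance threshold.
#' Observed SNPs with `p < threshold` are flagged as candidates.
#'
#' @param freq a [pop_allele_frequencies()] matrix.
#' @param env environmental vector.
#' @param K latent factors, as in [lfmm_ridge()].
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param quantile pooled-null quantile defining the threshold (default
#'   0.001, i.e. the 0.1st percentile).
#' @param seed RNG seed.
#' @param lambda ridge penalty.
#' @return list with `threshold`, `candidates` (SNP ids), `observed` (the
#'   [lfmm_ridge()] table with a `candidate` flag), `n_perm`.
#' @export
empirical_threshold <- function(freq, env, K = 1L, n_perm = 1000L,
                                quantile = 0.001, seed = 1L, lambda = 1e-5) {
  if (n_perm < 100) warning("fewer than 100 permutations; threshold unstable")
  obs <- lfmm_ridge(freq, env, K, lambda)
  x <- as.numeric(scale(env))
  Y <- unclass(freq)
  set.seed(seed)
  null_p <- vapply(seq_len(n_perm), function(b) {
    lfmm_fit_test(Y, sample(x), K, lambda)$p_cal
  }, numeric(ncol(Y)))
  thr <- stats::quantile(as.numeric(null_p), probs = quantile, names = FALSE)
  obs$candidate <- obs$p < thr
  list(threshold = thr, candidates = obs$snp[obs$candidate],
       observed = obs, n_perm = n_perm)
}

#' Per-SNP random-forest importance along the environmental gradient
#'
#' Regresses each SNP's population allele frequencies on the environmental
#' predictor with a 500-tree random forest. The reported importance is the
#' split (node-impurity) importance weighted by the out-of-bag R-squared,
#' with non-positive R-squared mapped to zero importance. Candidates are the
#' top `ceiling(0.01 * M)` SNPs by importance among SNPs with positive
#' importance; ties at the boundary break by SNP id order.
#'
#' @param freq a [pop_allele_frequencies()] matrix.
#' @param env environmental vector.
#' @param n_trees trees per forest (default 500).
#' @param top_fraction candidate fraction (default 0.01).
#' @param seed RNG seed.
#' @return a `forest_result` data.frame: snp, contig, pos, importance, r2,
#'   candidate.
#' @export
forest_importance <- function(freq, env, n_trees = 500L, top_fraction = 0.01,
                              seed = 1L) {
  M <- ncol(freq)
  if (M == 0) stop("no SNPs supplied")
  set.seed(seed)
  xm <- matrix(as.numeric(env), ncol = 1,
               dimnames = list(NULL, "env"))
  imp <- r2 <- numeric(M)
  for (j in seq_len(M)) {
    y <- freq[, j]
    if (stats::sd(y) == 0) { imp[j] <- 0; r2[j] <- 0; next }
    # regression on population-level frequencies is intended even when the
    # response has few unique values; silence that advisory warning
    rf <- suppressWarnings(
      randomForest::randomForest(x = xm, y = y, ntree = n_trees))
    r2_oob <- 1 - rf$mse[n_trees] / mean((y - mean(y))^2)
    r2[j] <- r2_oob
    imp[j] <- if (r2_oob > 0) rf$importance[1, 1] * r2_oob else 0
  }
  n_cand <- ceiling(top_fraction * M)
  pos_imp <- which(imp > 0)
  ord <- pos_imp[order(-imp[pos_imp], pos_imp)]
  cand_idx <- utils::head(ord, n_cand)
  out <- data.frame(snp = colnames(freq), contig = attr(freq, "contig"),
                    pos = attr(freq, "pos"), importance = imp, r2 = r2,
                    candidate = seq_len(M) %in% cand_idx, row.names = NULL)
  class(out) <- c("forest_result", "data.frame")
  out
}

#' Intersection of two candidate sets with a hypergeometric test
#'
#' `k = |a intersect b|`; the enrichment p-value is `P(X >= k)` with
#' `X ~ Hypergeometric(N = universe_size, K = |a|, n = |b|)`.
#'
#' @param a,b character vectors of SNP (or gene) identifiers drawn from a
#'   common universe.
#' @param universe_size size of that universe.
#' @return list with `intersection` (ids), `k`, `p`.
#' @export
intersect_candidates <- function(a, b, universe_size) {
  a <- unique(a); b <- unique(b)
  if (length(a) > universe_size || length(b) > universe_size) {
    stop("candidate set larger than the universe")
  }
  inter <- intersect(a, b)
  k <- length(inter)
  p <- stats::phyper(k - 1, length(a), universe_size - length(a), length(b),
                     lower.tail = FALSE)
  list(intersection = inter, k = k, p = p)
}
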