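# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive (loops, enumeration) and written from the
# defining formulas, independently of the package internals they check.

# build a genotype_table from a dosage matrix (individuals x sites);
# haplotypes are phased deterministically (dosage 1 -> 0|1)
gt_from_dosage <- function(d, contig = NULL, pos = NULL, qual = NULL,
                           dp = NULL, ref = NULL, alt = NULL,
                           is_indel = NULL) {
  n <- nrow(d); m <- ncol(d)
  if (is.null(contig)) contig <- rep("c1", m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(qual)) qual <- rep(50, m)
  if (is.null(dp)) dp <- matrix(10L, n, m)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("T", m)
  if (is.null(is_indel)) is_indel <- rep(FALSE, m)
  hap <- matrix(NA_integer_, 2L * n, m)
  for (i in seq_len(n)) {
    g <- d[i, ]
    hap[2L * i - 1L, ] <- ifelse(is.na(g), NA_integer_, as.integer(g >= 1L))
    hap[2L * i, ] <- ifelse(is.na(g), NA_integer_, as.integer(g == 2L))
    # dosage 1 phased as 1|0 for determinism
    one <- !is.na(g) & g == 1L
    hap[2L * i - 1L, one] <- 1L
    hap[2L * i, one] <- 0L
  }
  genotype_table(contig = contig, pos = pos, ref = ref, alt = alt,
                 qual = qual, hap = hap, dp = dp,
                 gq = matrix(60L, n, m), samples = paste0("s", seq_len(n)),
                 is_indel = is_indel)
}

# build a haplotype_matrix directly
hapmat <- function(h, pos = NULL, contig = NULL) {
  h <- as.matrix(h)
  if (is.null(pos)) pos <- seq_len(ncol(h)) * 1000L
  if (is.null(contig)) contig <- rep("c1", ncol(h))
  structure(h, contig = contig, pos = as.integer(pos),
            class = c("haplotype_matrix", "matrix"))
}

# --- brute-force nSL oracle: naive left/right scans over every pair -------
nsl_oracle <- function(hap, min_maf = 0.05, max_edge_frac = 0.05) {
  contig <- attr(hap, "contig"); pos <- attr(hap, "pos")
  h_all <- unclass(hap)
  rows <- list()
  for (ctg in unique(contig)) {
    cols <- which(contig == ctg)
    h <- h_all[, cols, drop = FALSE]
    S <- ncol(h); H <- nrow(h)
    for (s in seq_len(S)) {
      freq <- mean(h[, s])
      if (freq * H < 2 || (1 - freq) * H < 2) next
      if (min(freq, 1 - freq) < min_maf) next
      tr_a <- tr_d <- numeric(0)
      ed_a <- ed_d <- logical(0)
      for (i in seq_len(H - 1)) for (j in seq(i + 1, H)) {
        if (h[i, s] != h[j, s]) next
        l <- s; r <- s
        while (l > 1 && h[i, l - 1] == h[j, l - 1]) l <- l - 1
        while (r < S && h[i, r + 1] == h[j, r + 1]) r <- r + 1
        tract <- r - l + 1
        edge <- (l == 1) || (r == S)
        if (h[i, s] == 0) { tr_a <- c(tr_a, tract); ed_a <- c(ed_a, edge) }
        else { tr_d <- c(tr_d, tract); ed_d <- c(ed_d, edge) }
      }
      if (!length(tr_a) || !length(tr_d)) next
      if (mean(ed_a) > max_edge_frac || mean(ed_d) > max_edge_frac) next
      rows[[length(rows) + 1]] <- data.frame(
        contig = ctg, pos = pos[cols][s], freq = freq,
        sl_a = mean(tr_a), sl_d = mean(tr_d),
        nsl = log(mean(tr_a) / mean(tr_d)))
    }
  }
  if (!length(rows)) {
    return(data.frame(contig = character(0), pos = integer(0),
                      freq = numeric(0), sl_a = numeric(0), sl_d = numeric(0),
                      nsl = numeric(0)))
  }
  do.call(rbind, rows)
}

# --- Weir-Cockerham 1984 oracle: per-locus transcription ------------------
# independent transcription of the two-population variance components
wc84_theta_oracle <- function(d1, d2) {
  num <- den <- 0
  for (l in seq_len(ncol(d1))) {
    g1 <- d1[, l][!is.na(d1[, l])]
    g2 <- d2[, l][!is.na(d2[, l])]
    if (!length(g1) || !length(g2)) next
    n1 <- length(g1); n2 <- length(g2)
    p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
    h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    cterm <- hbar / 2
    if (is.finite(a + b + cterm)) { num <- num + a; den <- den + a + b + cterm }
  }
  num / den
}

# --- hypergeometric upper-tail by direct PMF summation --------------------
hyper_upper_oracle <- function(k, N, K, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# --- interval-union oracle for sweep region merging -----------------------
merge_oracle <- function(pos, gap) {
  pos <- sort(pos)
  starts <- ends <- integer(0)
  cur_s <- cur_e <- pos[1]
  for (p in pos[-1]) {
    if (p - cur_e <= gap) cur_e <- p
    else { starts <- c(starts, cur_s); ends <- c(ends, cur_e); cur_s <- cur_e <- p }
  }
  data.frame(start = c(starts, cur_s), end = c(ends, cur_e))
}

# --- memo-free recursive Wang similarity evaluator ------------------------
wang_oracle <- function(a, b, edges, weights = c(is_a = 0.8, part_of = 0.6)) {
  anc_closure <- function(t) {
    ps <- edges$parent[edges$child == t]
    unique(c(t, unlist(lapply(ps, anc_closure))))
  }
  svalue <- function(t, target) {
    # S_target(t): recursive, no memoisation
    if (t == target) return(1)
    kids <- edges[edges$parent == t, , drop = FALSE]
    best <- -Inf
    for (i in seq_len(nrow(kids))) {
      sv <- svalue(kids$child[i], target)
      if (is.finite(sv)) best <- max(best, weights[[kids$relation[i]]] * sv)
    }
    best
  }
  ta <- anc_closure(a); tb <- anc_closure(b)
  sa <- vapply(ta, svalue, numeric(1), target = a)
  sb <- vapply(tb, svalue, numeric(1), target = b)
  sa <- sa[is.finite(sa)]; sb <- sb[is.finite(sb)]
  common <- intersect(names(sa), names(sb))
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

# --- exhaustive permutation generator (for Mantel enumeration) ------------
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_oracle(n - 1L)) {
    for (pos in 0:(n - 1L)) out[[length(out) + 1]] <- append(p, n, after = pos)
  }
  out
}

# small toy GO edge set used in several tests:
#   root <- m1 <- c1 ; root <- m2 ; c1 part_of m2
toy_edges <- function() {
  data.frame(child = c("m1", "c1", "m2", "c1"),
             parent = c("root", "m1", "root", "m2"),
             relation = c("is_a", "is_a", "is_a", "part_of"))
}
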