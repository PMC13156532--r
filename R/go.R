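#' Build a GO universe from edge and annotation tables
#'
#' Validates that the typed term graph (edges child -> parent, relation
#' `is_a` or `part_of`) is acyclic, assigns every term to the ontology of
#' the root it reaches, and propagates gene annotations to all ancestors.
#'
#' @param edges data.frame: child, parent, relation.
#' @param annotations data.frame: gene, term.
#' @param term_names optional named character vector of term descriptions.
#' @return a `go_universe`: list with `terms`, `roots`, `ontology` (named by
#'   term), `parents`/`children` (adjacency lists with relations),
#'   `direct` (term -> genes), `genes_of` (term -> propagated genes),
#'   `genes` (all annotated genes), `ancestors` (term -> ancestor closure,
#'   self excluded).
#' @export
go_universe <- function(edges, annotations, term_names = NULL) {
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)),
            all(c("gene", "term") %in% names(annotations)))
  terms <- sort(unique(c(edges$child, edges$parent, annotations$term)))
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     vertices = terms)
  if (!igraph::is_dag(g)) stop("cycle detected in the term graph")
  roots <- setdiff(terms, unique(edges$child))
  topo <- names(igraph::topo_sort(g, mode = "out"))  # children before parents
  parents <- split(data.frame(parent = edges$parent,
                              relation = edges$relation,
                              stringsAsFactors = FALSE),
                   factor(edges$child, levels = terms))
  # ancestor closure and ontology assignment, children-to-parents order
  ancestors <- stats::setNames(vector("list", length(terms)), terms)
  ontology <- stats::setNames(rep(NA_character_, length(terms)), terms)
  onto_of_root <- stats::setNames(roots, roots)
  # parents must be resolved before their children: reverse topological order
  for (t in rev(topo)) {
    ps <- parents[[t]]$parent
    if (!length(ps)) {
      ancestors[[t]] <- character(0)
      ontology[t] <- onto_of_root[t]
    } else {
      anc <- unique(c(ps, unlist(ancestors[ps], use.names = FALSE)))
      ancestors[[t]] <- anc
      ont <- unique(stats::na.omit(ontology[ps]))
      if (length(ont) > 1) stop("term ", t, " reaches multiple roots")
      ontology[t] <- ont
    }
  }
  direct <- lapply(split(annotations$gene, factor(annotations$term,
                                                  levels = terms)), unique)
  genes_of <- direct
  for (t in terms) {
    gs <- direct[[t]]
    if (!length(gs)) next
    for (a in ancestors[[t]]) genes_of[[a]] <- union(genes_of[[a]], gs)
  }
  children <- split(data.frame(child = edges$child, relation = edges$relation,
                               stringsAsFactors = FALSE),
                    factor(edges$parent, levels = terms))
  structure(list(terms = terms, roots = roots, ontology = ontology,
                 parents = parents, children = children,
                 direct = direct, genes_of = genes_of,
                 genes = sort(unique(annotations$gene)),
                 ancestors = ancestors,
                 term_names = term_names, topo = topo),
            class = "go_universe")
}

#' @export
print.go_universe <- function(x, ...) {
  cat(sprintf("go_universe: %d terms (%d root(s)), %d genes\n",
              length(x$terms), length(x$roots), length(x$genes)))
  invisible(x)
}

#' Simulate a toy GO universe with annotations and an orthology table
#'
#' Builds one rooted DAG per ontology (BP/MF/CC): each non-root term attaches
#' to one or two earlier terms with `is_a` or `part_of` edges, every gene is
#' annotated to at least one term, and a random subset of species-A genes is
#' mapped one-to-one to species-B genes.
#'
#' @param n_terms terms per ontology (>= 3).
#' @param n_genes number of species-A genes.
#' @param seed RNG seed.
#' @param ortho_fraction fraction of genes with an orthologue (default 0.7).
#' @return list with `universe` (a [go_universe()]), `edges`, `annotations`,
#'   `orthology` (data.frame: gene_a, gene_b).
#' @export
simulate_go_universe <- function(n_terms = 15L, n_genes = 60L, seed = 1L,
                                 ortho_fraction = 0.7) {
  if (n_terms < 3) stop("need at least 3 terms per ontology")
  set.seed(seed)
  edges <- NULL
  for (ont in c("BP", "MF", "CC")) {
    ids <- sprintf("%s:%03d", ont, seq_len(n_terms))
    for (i in 2:n_terms) {
      n_par <- if (i > 2 && stats::runif(1) < 0.3) 2L else 1L
      ps <- sample(ids[seq_len(i - 1)], min(n_par, i - 1))
      edges <- rbind(edges, data.frame(
        child = ids[i], parent = ps,
        relation = sample(c("is_a", "part_of"), length(ps),
                          replace = TRUE, prob = c(0.8, 0.2))))
    }
  }
  genes <- sprintf("geneA_%03d", seq_len(n_genes))
  all_terms <- unique(c(edges$child, edges$parent))
  annotations <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene = g,
               term = sample(all_terms, 1 + stats::rpois(1, 1.2)))
  }))
  annotations <- unique(annotations)
  n_ortho <- round(ortho_fraction * n_genes)
  orthology <- data.frame(gene_a = sample(genes, n_ortho),
                          gene_b = sprintf("geneB_%03d", seq_len(n_ortho)))
  list(universe = go_universe(edges, annotations),
       edges = edges, annotations = annotations, orthology = orthology)
}

#' Map candidate SNPs to genes within a padding distance
#'
#' A gene is reported when its interval intersects
#' `[pos - pad_bp, pos + pad_bp]` of any candidate SNP. Gene intervals are
#' 0-based half-open (BED convention); SNP positions are 1-based.
#'
#' @param candidates data.frame with `contig`, `pos` (1-based SNPs).
#' @param genes data.frame with `contig`, `start`, `end` (0-based half-open)
#'   and `gene`.
#' @param pad_bp padding around each SNP (default 10000).
#' @return character vector of unique gene identifiers.
#' @export
map_snps_to_genes <- function(candidates, genes, pad_bp = 10000L) {
  hits <- character(0)
  for (ctg in unique(candidates$contig)) {
    gsub <- genes[genes$contig == ctg, , drop = FALSE]
    if (!nrow(gsub)) next
    g_start1 <- gsub$start + 1L   # 1-based inclusive
    g_end1 <- gsub$end            # half-open end == 1-based inclusive end
    for (p in candidates$pos[candidates$contig == ctg]) {
      ov <- g_start1 <= p + pad_bp & g_end1 >= p - pad_bp
      hits <- c(hits, gsub$gene[ov])
    }
  }
  unique(hits)
}

#' GO enrichment with the elim algorithm
#'
#' Terms are processed from the leaves toward the roots (topological order).
#' Each term is tested with a one-sided Fisher exact test on the 2x2 table of
#' study vs background and annotated vs not, using propagated annotations
#' minus the genes already eliminated at that term. When a term's p-value
#' falls below `elim_cutoff`, its (current) genes are removed from all of its
#' ancestors' gene sets before those are tested — decorrelating the DAG and
#' reducing false positives at ancestor terms. Terms with fewer than
#' `min_node` propagated background genes are skipped.
#'
#' @param study_genes character vector; must be a subset of the universe's
#'   annotated genes.
#' @param universe a [go_universe()].
#' @param min_node minimum annotated background genes per tested term
#'   (default 5).
#' @param elim_cutoff p-value below which a term's genes are eliminated from
#'   its ancestors (default 0.01; 0 disables elimination, giving the classic
#'   term-by-term Fisher test).
#' @return data.frame: term, name, ontology, annotated, significant,
#'   expected, p — all tested terms, sorted by p (filter at 0.05 for
#'   reporting).
#' @export
go_enrichment_elim <- function(study_genes, universe, min_node = 5L,
                               elim_cutoff = 0.01) {
  study_genes <- unique(study_genes)
  if (!all(study_genes %in% universe$genes)) {
    stop("study genes absent from the annotated background")
  }
  N <- length(universe$genes)
  n_study <- length(study_genes)
  eliminated <- stats::setNames(vector("list", length(universe$terms)),
                                universe$terms)
  rows <- list()
  for (t in universe$topo) {     # children before parents
    anno_full <- universe$genes_of[[t]]
    if (length(anno_full) < min_node) next
    anno <- setdiff(anno_full, eliminated[[t]])
    k <- sum(study_genes %in% anno)
    K <- length(anno)
    p <- stats::phyper(k - 1, K, N - K, n_study, lower.tail = FALSE)
    rows[[t]] <- data.frame(
      term = t,
      name = if (!is.null(universe$term_names)) universe$term_names[t] else t,
      ontology = unname(universe$ontology[t]),
      annotated = K, significant = k,
      expected = K * n_study / N, p = p)
    if (elim_cutoff > 0 && p < elim_cutoff) {
      for (a in universe$ancestors[[t]]) {
        eliminated[[a]] <- union(eliminated[[a]], anno)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), name = character(0),
                      ontology = character(0), annotated = integer(0),
                      significant = integer(0), expected = numeric(0),
                      p = numeric(0)))
  }
  rownames(out) <- NULL
  out[order(out$p), ]
}

#' Cross-species orthologue overlap with a hypergeometric test
#'
#' The universe is the set of orthologous gene pairs present in both species'
#' analysed backgrounds. k counts pairs whose species-A member is a candidate
#' in A and whose species-B member is a candidate in B;
#' `p = P(X >= k)` with `X ~ Hypergeometric(N = #pairs, K, n)` where K and n
#' are the candidate counts restricted to the universe.
#'
#' @param cand_a,cand_b character vectors of candidate gene ids per species.
#' @param orthology data.frame with `gene_a`, `gene_b` (one-to-one pairs);
#'   this is the universe.
#' @return list with `k`, `K`, `n`, `N`, `p`, `shared_pairs`.
#' @export
orthologue_overlap <- function(cand_a, cand_b, orthology) {
  N <- nrow(orthology)
  if (N == 0) stop("empty orthology universe")
  in_a <- orthology$gene_a %in% cand_a
  in_b <- orthology$gene_b %in% cand_b
  k <- sum(in_a & in_b)
  K <- sum(in_a); n <- sum(in_b)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p = p,
       shared_pairs = orthology[in_a & in_b, , drop = FALSE])
}

# Wang S-values: contribution of every ancestor (and the term itself) to the
# semantics of `term`, S(term) = 1, S(t) = max over child edges on paths to
# `term` of w_edge * S(child).
wang_svalues <- function(term, universe, weights) {
  sub <- c(term, universe$ancestors[[term]])
  s <- stats::setNames(rep(-Inf, length(sub)), sub)
  s[term] <- 1
  ord <- universe$topo[universe$topo %in% sub]   # children before parents
  for (t in ord) {
    if (t == term) next
    ch <- universe$children[[t]]
    ch <- ch[ch$child %in% sub, , drop = FALSE]
    if (!nrow(ch)) next
    w <- unname(weights[ch$relation])
    s[t] <- max(w * s[ch$child])
  }
  s[is.finite(s)]
}

#' Wang semantic similarity between two GO terms
#'
#' Edge-based similarity: each term's ancestors receive S-values decaying by
#' the edge weights (`is_a` 0.8, `part_of` 0.6 by default); the similarity is
#' the summed S-values over shared ancestors divided by the two terms' total
#' semantic values.
#'
#' @param term_a,term_b term identifiers from the same ontology.
#' @param universe a [go_universe()].
#' @param weights named edge weights (default `c(is_a = 0.8, part_of = 0.6)`).
#' @return similarity in \[0, 1\].
#' @export
wang_similarity <- function(term_a, term_b, universe,
                            weights = c(is_a = 0.8, part_of = 0.6)) {
  if (universe$ontology[term_a] != universe$ontology[term_b]) {
    stop("terms belong to different ontologies")
  }
  sa <- wang_svalues(term_a, universe, weights)
  sb <- wang_svalues(term_b, universe, weights)
  common <- intersect(names(sa), names(sb))
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

# Best-match average over a precomputed pairwise similarity matrix
bma_from_matrix <- function(sim_ab) {
  (sum(apply(sim_ab, 1, max)) + sum(apply(sim_ab, 2, max))) /
    (nrow(sim_ab) + ncol(sim_ab))
}

#' Best-match-average similarity between two GO term sets
#'
#' Per ontology, `BMA = (sum_i max_j sim(a_i, b_j) + sum_j max_i sim(a_i,
#' b_j)) / (|A| + |B|)`; the combined value is the mean over ontologies
#' represented in both sets.
#'
#' @param terms_a,terms_b character vectors of term ids.
#' @param universe a [go_universe()].
#' @param weights Wang edge weights.
#' @return list with `per_ontology` (named numeric) and `combined`.
#' @export
bma_similarity <- function(terms_a, terms_b, universe,
                           weights = c(is_a = 0.8, part_of = 0.6)) {
  onts <- intersect(unique(universe$ontology[terms_a]),
                    unique(universe$ontology[terms_b]))
  per <- vapply(onts, function(o) {
    a <- terms_a[universe$ontology[terms_a] == o]
    b <- terms_b[universe$ontology[terms_b] == o]
    m <- outer(a, b, Vectorize(function(x, y) {
      wang_similarity(x, y, universe, weights)
    }))
    bma_from_matrix(matrix(m, length(a), length(b)))
  }, numeric(1))
  list(per_ontology = per,
       combined = if (length(per)) mean(per) else NA_real_)
}

#' Permutation test of cross-species functional convergence
#'
#' The observed statistic is the combined BMA similarity between the two
#' species' term sets. Under the null, term sets of the same per-ontology
#' sizes are drawn uniformly without replacement from the shared universe and
#' the combined BMA recomputed; `p = (#{null >= observed} + 1) / (n_perm + 1)`.
#' Pairwise Wang similarities over the shared universe are precomputed once,
#' so permutations are lookups.
#'
#' @param terms_a,terms_b observed term sets (subsets of `shared_universe`).
#' @param universe a [go_universe()].
#' @param shared_universe character vector of candidate terms both species
#'   could draw from.
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @param weights Wang edge weights.
#' @return a `similarity_result`: list with `observed` (combined BMA),
#'   `per_ontology`, `p`, `null` (numeric vector).
#' @export
convergence_test <- function(terms_a, terms_b, universe, shared_universe,
                             n_perm = 10000L, seed = 1L,
                             weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(all(terms_a %in% shared_universe),
            all(terms_b %in% shared_universe))
  su_ont <- universe$ontology[shared_universe]
  obs <- bma_similarity(terms_a, terms_b, universe, weights)
  # full pairwise similarity cache over the shared universe, per ontology
  sims <- list()
  for (o in unique(su_ont)) {
    tt <- shared_universe[su_ont == o]
    m <- matrix(1, length(tt), length(tt), dimnames = list(tt, tt))
    if (length(tt) > 1) {
      for (i in seq_len(length(tt) - 1)) {
        for (j in seq(i + 1, length(tt))) {
          m[i, j] <- m[j, i] <- wang_similarity(tt[i], tt[j], universe, weights)
        }
      }
    }
    sims[[o]] <- m
  }
  na_ont <- table(universe$ontology[terms_a])
  nb_ont <- table(universe$ontology[terms_b])
  onts <- intersect(names(na_ont), names(nb_ont))
  if (any(vapply(onts, function(o) {
    sum(su_ont == o) < max(na_ont[[o]], nb_ont[[o]])
  }, logical(1)))) {
    stop("shared universe smaller than an observed term set")
  }
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b) {
    vals <- vapply(onts, function(o) {
      pool <- shared_universe[su_ont == o]
      a <- sample(pool, na_ont[[o]])
      bb <- sample(pool, nb_ont[[o]])
      bma_from_matrix(sims[[o]][a, bb, drop = FALSE])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  p <- (sum(null >= obs$combined - 1e-12) + 1) / (n_perm + 1)
  structure(list(observed = obs$combined, per_ontology = obs$per_ontology,
                 p = p, null = null, n_perm = n_perm),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("similarity_result: combined BMA = %.3f, p = %.4g (%d perms)\n",
              x$observed, x$p, x$n_perm))
  invisible(x)
}
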