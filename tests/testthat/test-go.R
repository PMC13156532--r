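test_that("SNP-to-gene mapping respects the 10 kb padding boundary", {
  genes <- data.frame(contig = "c1", start = c(58000L, 60000L),
                      end = c(60000L, 61000L), gene = c("g1", "g2"))
  # SNP at 50,000: gene [58,000, 60,000) starts 8 kb away -> mapped
  expect_true("g1" %in% map_snps_to_genes(
    data.frame(contig = "c1", pos = 50000L), genes))
  # gene starting exactly at pos + 10,001 (1-based) is not mapped
  g3 <- data.frame(contig = "c1", start = 60000L, end = 70000L, gene = "g3")
  expect_length(map_snps_to_genes(
    data.frame(contig = "c1", pos = 50000L), g3), 0)  # 1-based start 60001
  expect_equal(map_snps_to_genes(
    data.frame(contig = "c1", pos = 50001L), g3), "g3")
})

test_that("random gene mapping equals the all-pairs interval oracle", {
  set.seed(7)
  for (rep in 1:20) {
    genes <- data.frame(contig = sample(c("c1", "c2"), 30, TRUE),
                        start = sample.int(2e5, 30))
    genes$end <- genes$start + sample.int(5000, 30)
    genes$gene <- paste0("g", 1:30)
    cand <- data.frame(contig = sample(c("c1", "c2"), 10, TRUE),
                       pos = sample.int(2e5, 10))
    got <- sort(map_snps_to_genes(cand, genes, pad_bp = 10000L))
    want <- character(0)
    for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(cand))) {
      if (genes$contig[i] != cand$contig[j]) next
      lo <- cand$pos[j] - 10000L; hi <- cand$pos[j] + 10000L
      if (genes$start[i] + 1L <= hi && genes$end[i] >= lo) {
        want <- c(want, genes$gene[i])
      }
    }
    expect_equal(got, sort(unique(want)))
  }
})

test_that("elim reduces to the classic Fisher test when it cannot eliminate", {
  # one-term 'DAG' plus its root: no elimination possible below the cutoff
  edges <- data.frame(child = "t1", parent = "root", relation = "is_a")
  ann <- data.frame(gene = paste0("g", 1:20),
                    term = rep(c("t1", "root"), c(8, 12)))
  u <- go_universe(edges, ann)
  study <- c(paste0("g", 1:5), "g10")
  res <- go_enrichment_elim(study, u, min_node = 1, elim_cutoff = 0)
  t1 <- res[res$term == "t1", ]
  ft <- stats::fisher.test(matrix(c(5, 8 - 5, 1, 12 - 0 - 1 + 0), 2,
                                  byrow = TRUE,
                                  dimnames = NULL),
                           alternative = "greater")
  # classic hypergeometric tail for the same 2x2 table
  expect_equal(t1$p, hyper_upper_oracle(5, 20, 8, 6), tolerance = 1e-12)
  expect_equal(t1$annotated, 8)
  expect_equal(t1$significant, 5)
  expect_equal(t1$expected, 8 * 6 / 20)

  # study == background makes every term's p exactly 1
  res_all <- go_enrichment_elim(paste0("g", 1:20), u, min_node = 1)
  expect_true(all(res_all$p == 1))
  expect_error(go_enrichment_elim("nope", u), "absent")
})

test_that("elim raises an absorbed parent's p above its classic value", {
  # two-level toy: child c1 under parent m1 under root; the child holds all
  # study genes, so elim strips them from the parent
  edges <- data.frame(child = c("m1", "c1"), parent = c("root", "m1"),
                      relation = "is_a")
  ann <- data.frame(
    gene = c(paste0("s", 1:6), paste0("p", 1:4), paste0("o", 1:10)),
    term = c(rep("c1", 6), rep("m1", 4), rep("root", 10)))
  u <- go_universe(edges, ann)
  study <- paste0("s", 1:6)
  classic <- go_enrichment_elim(study, u, min_node = 1, elim_cutoff = 0)
  elim <- go_enrichment_elim(study, u, min_node = 1, elim_cutoff = 0.05)
  p_parent_classic <- classic$p[classic$term == "m1"]
  p_parent_elim <- elim$p[elim$term == "m1"]
  # hand-computed tables: classic parent 10/20 annotated, 6/6 study hits
  expect_equal(p_parent_classic, hyper_upper_oracle(6, 20, 10, 6),
               tolerance = 1e-12)
  # after eliminating the child's 6 genes: 4 annotated, 0 study hits
  expect_equal(p_parent_elim, hyper_upper_oracle(0, 20, 4, 6),
               tolerance = 1e-12)
  expect_gt(p_parent_elim, p_parent_classic)
  # the child itself is unaffected
  expect_equal(elim$p[elim$term == "c1"], classic$p[classic$term == "c1"])
})

test_that("elim with elimination disabled equals classic Fisher on simulated universes", {
  for (s in 1:3) {
    gou <- simulate_go_universe(n_terms = 10, n_genes = 40, seed = 400 + s)
    u <- gou$universe
    set.seed(s)
    study <- sample(u$genes, 12)
    res0 <- go_enrichment_elim(study, u, min_node = 5, elim_cutoff = 0)
    N <- length(u$genes)
    for (i in seq_len(nrow(res0))) {
      K <- res0$annotated[i]
      expect_equal(res0$p[i],
                   hyper_upper_oracle(res0$significant[i], N, K, 12),
                   tolerance = 1e-12)
    }
  }
})

test_that("orthologue overlap matches exact enumeration and behaves under the null", {
  orth <- data.frame(gene_a = paste0("a", 1:100), gene_b = paste0("b", 1:100))
  # k = 0 -> p = 1
  expect_equal(orthologue_overlap("a101", "b101", orth)$p, 1)
  # N=100, K=10, n=10, k=5
  res <- orthologue_overlap(paste0("a", 1:10),
                            paste0("b", c(1:5, 50:54)), orth)
  expect_equal(res$k, 5)
  expect_equal(res$p, hyper_upper_oracle(5, 100, 10, 10), tolerance = 1e-12)
  expect_error(orthologue_overlap("a1", "b1", orth[0, ]), "empty")

  # disjoint-by-construction candidates are never significant
  ps <- vapply(1:10, function(s) {
    set.seed(s)
    ca <- sample(orth$gene_a[1:50], 8)
    cb <- sample(orth$gene_b[51:100], 8)
    orthologue_overlap(ca, cb, orth)$p
  }, numeric(1))
  expect_true(all(ps > 0.5))
})

test_that("Wang similarity: identity, two-node value, and symmetry", {
  u <- go_universe(toy_edges(),
                   data.frame(gene = "g1", term = "c1"))
  expect_equal(wang_similarity("c1", "c1", u), 1)
  # single is_a child-parent pair: (0.8 + 1) / (1.8 + 1)
  edges2 <- data.frame(child = "A", parent = "P", relation = "is_a")
  u2 <- go_universe(edges2, data.frame(gene = "g", term = "A"))
  expect_equal(wang_similarity("A", "P", u2), 1.8 / 2.8, tolerance = 1e-12)
  expect_equal(round(wang_similarity("A", "P", u2), 4), 0.6429)
  expect_equal(wang_similarity("A", "P", u2), wang_similarity("P", "A", u2))
})

test_that("Wang similarity equals the memo-free recursive evaluator on random DAGs", {
  for (s in 1:5) {
    gou <- simulate_go_universe(n_terms = 10, n_genes = 10, seed = 500 + s)
    u <- gou$universe
    bp <- u$terms[startsWith(u$ontology, "BP")]
    set.seed(s)
    pairs <- replicate(6, sample(bp, 2), simplify = FALSE)
    for (pr in pairs) {
      expect_equal(wang_similarity(pr[1], pr[2], u),
                   wang_oracle(pr[1], pr[2], gou$edges),
                   tolerance = 1e-12)
      expect_equal(wang_similarity(pr[1], pr[2], u),
                   wang_similarity(pr[2], pr[1], u), tolerance = 1e-12)
    }
  }
})

test_that("BMA similarity: self-match, degeneracy, order invariance, bounds", {
  gou <- simulate_go_universe(n_terms = 8, n_genes = 10, seed = 61)
  u <- gou$universe
  bp <- u$terms[startsWith(u$ontology, "BP")]
  set.seed(62)
  a <- sample(bp, 3); b <- sample(bp, 4)
  # identical sets match perfectly
  expect_equal(bma_similarity(a, a, u)$combined, 1)
  # single-term sets reduce to the pairwise similarity
  expect_equal(bma_similarity(a[1], b[1], u)$combined,
               wang_similarity(a[1], b[1], u))
  # order invariance and bounds
  s1 <- bma_similarity(a, b, u)$combined
  s2 <- bma_similarity(rev(a), sample(b), u)$combined
  expect_equal(s1, s2)
  expect_gte(s1, 0); expect_lte(s1, 1)
})

test_that("terms from different ontologies cannot be compared", {
  gou <- simulate_go_universe(n_terms = 5, n_genes = 10, seed = 63)
  u <- gou$universe
  bp <- u$terms[startsWith(u$ontology, "BP")][1]
  mf <- u$terms[startsWith(u$ontology, "MF")][1]
  expect_error(wang_similarity(bp, mf, u), "different ontologies")
})

test_that("a cycle in the edge table is rejected", {
  edges <- data.frame(child = c("a", "b", "c"), parent = c("b", "c", "a"),
                      relation = "is_a")
  expect_error(go_universe(edges, data.frame(gene = "g", term = "a")),
               "cycle")
})

test_that("convergence permutation test is calibrated under its own null", {
  gou <- simulate_go_universe(n_terms = 12, n_genes = 20, seed = 71)
  u <- gou$universe
  shared <- u$terms
  ps <- vapply(1:20, function(s) {
    set.seed(700 + s)
    a <- unlist(lapply(c("BP", "MF"), function(o) {
      sample(shared[startsWith(u$ontology[shared], o)], 3)
    }))
    b <- unlist(lapply(c("BP", "MF"), function(o) {
      sample(shared[startsWith(u$ontology[shared], o)], 3)
    }))
    convergence_test(a, b, u, shared, n_perm = 200, seed = s)$p
  }, numeric(1))
  # null p-values should not pile up at either extreme
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
  expect_gt(min(ps), 1 / 201 - 1e-12)

  # identical observed sets give BMA 1 and a small p on this universe
  a1 <- shared[startsWith(u$ontology[shared], "BP")][1:3]
  res <- convergence_test(a1, a1, u, shared, n_perm = 200, seed = 1)
  expect_equal(res$observed, 1)
})
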