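#' Pipeline run configuration
#'
#' @param out_dir output directory for stage tables and the manifest.
#' @param sim a [sim_config()] used when no VCF is supplied.
#' @param vcf optional path to a phased multi-sample VCF (overrides `sim`).
#' @param pops_file,env_file optional TSVs (pop/individual/lat/lon and
#'   pop + covariates) accompanying a user VCF.
#' @param preset_assoc filter preset for the association/sweep arm
#'   (default "relaxed").
#' @param preset_diversity filter preset for the diversity arm
#'   (default "strict").
#' @param K latent factors for the association model.
#' @param n_perm_gea,n_perm_overlap,n_boot_fst permutation/bootstrap sizes.
#' @param stages named logical vector toggling `popgen`, `landscape`, `gea`,
#'   `sweep`, `converge`.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("beescape_run_"),
                       sim = sim_config(), vcf = NULL, pops_file = NULL,
                       env_file = NULL, preset_assoc = "relaxed",
                       preset_diversity = "strict", K = 1L,
                       n_perm_gea = 200L, n_perm_overlap = 500L,
                       n_boot_fst = 200L,
                       stages = c(popgen = TRUE, landscape = TRUE, gea = TRUE,
                                  sweep = TRUE, converge = TRUE),
                       seed = 1L) {
  structure(list(out_dir = out_dir, sim = sim, vcf = vcf,
                 pops_file = pops_file, env_file = env_file,
                 preset_assoc = preset_assoc,
                 preset_diversity = preset_diversity, K = K,
                 n_perm_gea = n_perm_gea, n_perm_overlap = n_perm_overlap,
                 n_boot_fst = n_boot_fst, stages = stages,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full comparative landscape-genomics pipeline
#'
#' Executes the stages in dependency order — data (simulated or loaded),
#' variant QC (both presets), diversity/differentiation/structure, landscape
#' models, genotype-environment association, sweep scan with overlap
#' testing, and functional convergence on a simulated GO universe — writing
#' one TSV per product plus a JSON manifest recording seeds, thresholds and
#' per-stage record counts. Re-running the same configuration reproduces
#' identical outputs.
#'
#' @param config a [run_config()].
#' @return the manifest (list), invisibly; outputs are under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest <- list(package_version = as.character(utils::packageVersion("beescape")),
                   seed = seed, stages = as.list(config$stages))

  # --- data
  if (is.null(config$vcf)) {
    sim <- simulate_metapopulation(config$sim)
    gt_raw <- sim$genotypes; pops <- sim$pops; env <- sim$env
    truth <- sim$truth
    write_vcf(gt_raw, file.path(config$out_dir, "simulated.vcf"))
  } else {
    gt_raw <- read_vcf(config$vcf)
    pops <- utils::read.delim(config$pops_file)
    env <- utils::read.delim(config$env_file)
    truth <- NULL
  }
  write_tsv(pops, file.path(config$out_dir, "populations.tsv"))
  write_tsv(env, file.path(config$out_dir, "environment.tsv"))
  manifest$n_sites_raw <- n_sites(gt_raw)
  manifest$n_individuals_raw <- n_individuals(gt_raw)

  # --- qc, both arms
  qc_arm <- function(preset_name) {
    fr <- apply_site_filters(gt_raw, filter_preset(preset_name))
    gt <- drop_high_missing_individuals(fr$genotypes)
    if (identical(preset_name, "strict")) gt <- ld_prune(gt)
    list(gt = gt, report = fr$report)
  }
  strict <- qc_arm(config$preset_diversity)
  relaxed <- qc_arm(config$preset_assoc)
  pops_s <- pops[pops$individual %in% strict$gt$samples, ]
  pops_r <- pops[pops$individual %in% relaxed$gt$samples, ]
  write_tsv(strict$report, file.path(config$out_dir, "qc_report_strict.tsv"))
  write_tsv(relaxed$report, file.path(config$out_dir, "qc_report_relaxed.tsv"))
  kin <- king_kinship(strict$gt)
  write_tsv(kin$flagged, file.path(config$out_dir, "kinship_flagged.tsv"))
  manifest$qc <- list(n_sites_strict = n_sites(strict$gt),
                      n_sites_relaxed = n_sites(relaxed$gt),
                      n_flagged_related = nrow(kin$flagged))

  env_by_pop <- env[match(unique(pops_s$pop), env$pop), ]
  coords <- unique(pops_s[, c("pop", "lat", "lon")])

  # --- popgen
  if (isTRUE(config$stages[["popgen"]])) {
    n_callable <- if (!is.null(truth)) truth$n_callable else {
      stats::setNames(rep(n_sites(gt_raw) * 50, length(unique(pops_s$pop))),
                      unique(pops_s$pop))
    }
    he <- expected_heterozygosity(strict$gt, pops_s, n_callable)
    write_tsv(he, file.path(config$out_dir, "diversity.tsv"))
    fst <- pairwise_fst(strict$gt, pops_s, n_boot = config$n_boot_fst,
                        seed = seed + 1L)
    fst_tab <- as.data.frame(fst$fst)
    fst_tab <- cbind(pop = rownames(fst$fst), fst_tab)
    write_tsv(fst_tab, file.path(config$out_dir, "fst_matrix.tsv"))
    geo <- greatcircle_km(coords)
    ibd <- mantel_ibd(fst$linearized, geo, n_perm = 999L, seed = seed + 2L)
    cl <- cluster_bic(strict$gt, K_max = min(8L, length(unique(pops_s$pop))),
                      seed = seed + 3L)
    pc <- pcoa(genotype_distance(strict$gt), k = 2L)
    write_tsv(data.frame(individual = strict$gt$samples, pc$coords),
              file.path(config$out_dir, "pcoa_coords.tsv"))
    manifest$popgen <- list(mean_fst = mean(fst$fst[upper.tri(fst$fst)]),
                            mantel_r = ibd$r, mantel_p = ibd$p,
                            chosen_K = cl$chosen_K,
                            mean_adj_he = mean(he$adjH_EXP))
  }

  # --- landscape
  if (isTRUE(config$stages[["landscape"]]) &&
      isTRUE(config$stages[["popgen"]])) {
    he <- utils::read.delim(file.path(config$out_dir, "diversity.tsv"))
    dat <- merge(he, env_by_pop, by = "pop")
    covars <- intersect(c("impervious", "urban_green", "seminatural",
                          "edge_density"), names(dat))
    vt <- vif(dat, covars)
    mi <- morans_i(dat$adjH_EXP, coords[match(dat$pop, coords$pop), ])
    avg <- dredge_average(dat, "adjH_EXP", covars)
    write_tsv(avg$models, file.path(config$out_dir, "model_selection.tsv"))
    write_tsv(avg$average, file.path(config$out_dir, "model_average.tsv"))
    write_tsv(vt, file.path(config$out_dir, "vif.tsv"))
    manifest$landscape <- list(moran_i = mi$I, moran_p = mi$p,
                               n_models = nrow(avg$models),
                               max_vif = max(vt$vif))
  }

  # --- gea
  cand_both <- NULL
  if (isTRUE(config$stages[["gea"]])) {
    freq <- pop_allele_frequencies(relaxed$gt, pops_r)
    env_v <- env_by_pop$impervious[match(rownames(freq), env_by_pop$pop)]
    thr <- empirical_threshold(freq, env_v, K = config$K,
                               n_perm = config$n_perm_gea, seed = seed + 4L)
    gf <- forest_importance(freq, env_v, seed = seed + 5L)
    inter <- intersect_candidates(thr$candidates,
                                  gf$snp[gf$candidate], ncol(freq))
    cand_both <- inter$intersection
    obs <- thr$observed
    obs$gf_importance <- gf$importance
    obs$gf_candidate <- gf$candidate
    obs$robust <- obs$snp %in% cand_both
    write_tsv(obs, file.path(config$out_dir, "gea_results.tsv"))
    manifest$gea <- list(threshold = thr$threshold,
                         n_lfmm = length(thr$candidates),
                         n_gf = sum(gf$candidate),
                         n_both = inter$k, overlap_p = inter$p)
  }

  # --- sweep
  if (isTRUE(config$stages[["sweep"]])) {
    hap <- impute_haplotypes(haplotypes(relaxed$gt))
    scan <- normalize_nsl(nsl_scan(hap))
    regions <- merge_outlier_regions(scan)
    write_tsv(scan, file.path(config$out_dir, "nsl_scan.tsv"))
    write_tsv(regions, file.path(config$out_dir, "sweep_regions.tsv"))
    manifest$sweep <- list(n_scanned = nrow(scan),
                           n_outliers = sum(scan$outlier),
                           n_regions = nrow(regions))
    if (!is.null(cand_both) && length(cand_both) && nrow(regions)) {
      cand_df <- data.frame(
        contig = sub(":.*", "", cand_both),
        pos = as.integer(sub(".*:", "", cand_both)))
      all_snps <- data.frame(contig = relaxed$gt$contig,
                             pos = relaxed$gt$pos)
      ov <- overlap_permutation_test(cand_df, regions, all_snps,
                                     n_perm = config$n_perm_overlap,
                                     seed = seed + 6L)
      manifest$sweep$overlap_k <- ov$k
      manifest$sweep$overlap_p <- ov$p
    } else {
      manifest$sweep$overlap_k <- NA
      manifest$sweep$overlap_p <- NA
      manifest$sweep$note <- "overlap test skipped (no GEA candidates or regions)"
    }
  } else {
    manifest$sweep <- list(note = "sweep stage disabled; overlap testing skipped")
  }

  # --- convergence demo on a simulated GO universe
  if (isTRUE(config$stages[["converge"]])) {
    gou <- simulate_go_universe(seed = seed + 7L)
    genes <- data.frame(
      contig = sample(unique(gt_raw$contig), length(gou$universe$genes),
                      replace = TRUE),
      start = sample.int(900000L, length(gou$universe$genes)),
      gene = gou$universe$genes)
    genes$end <- genes$start + 2000L
    cand_df <- if (!is.null(cand_both) && length(cand_both)) {
      data.frame(contig = sub(":.*", "", cand_both),
                 pos = as.integer(sub(".*:", "", cand_both)))
    } else {
      data.frame(contig = gt_raw$contig[1], pos = gt_raw$pos[1])
    }
    study <- map_snps_to_genes(cand_df, genes)
    if (length(study) >= 2) {
      enr <- go_enrichment_elim(study, gou$universe)
      write_tsv(enr, file.path(config$out_dir, "go_enrichment.tsv"))
      ortho <- orthologue_overlap(study,
                                  gou$orthology$gene_b[seq_len(min(10, nrow(gou$orthology)))],
                                  gou$orthology)
      terms_a <- utils::head(enr$term, 5)
      terms_b <- utils::head(rev(enr$term), 5)
      conv <- convergence_test(terms_a, terms_b, gou$universe,
                               shared_universe = gou$universe$terms,
                               n_perm = 1000L, seed = seed + 8L)
      manifest$converge <- list(n_study_genes = length(study),
                                ortho_k = ortho$k, ortho_p = ortho$p,
                                bma = conv$observed, bma_p = conv$p)
    } else {
      manifest$converge <- list(note = "too few mapped genes for enrichment")
    }
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
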