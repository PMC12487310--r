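#' End-to-end pipeline configuration
#'
#' One declarative list holding every stage's parameter block plus the root
#' seed. Inputs are either a simulation config (the default: everything is
#' generated) or paths to existing VCF/TSV files.
#'
#' @param sim a [sim_config()] used when no input paths are given
#' @param vcf,traits_tsv optional input paths overriding simulation
#' @param filter a [filter_params()] block
#' @param impute an [ld_knni_params()] block
#' @param structure admixture-replicate block: `k_range`, `n_replicates`,
#'   EM `max_iter`/`tol`, and `max_markers` (the admixture stage thins the
#'   panel deterministically to at most this many markers; ancestry
#'   inference saturates well below the full panel size)
#' @param gwas an [mlm_spec()] block
#' @param probe_gc list(min, max) probe GC acceptance band
#' @param seed root seed; all stage randomness derives from it
#' @return a named list of class `run_config`
#' @export
pipeline_config <- function(sim = sim_config(), vcf = NULL,
                            traits_tsv = NULL,
                            filter = filter_params(),
                            impute = ld_knni_params(),
                            structure = list(k_range = 1:5,
                                             n_replicates = 10,
                                             max_iter = 150, tol = 0.5,
                                             max_markers = 1000),
                            gwas = mlm_spec(),
                            probe_gc = list(min = 0.30, max = 0.70),
                            seed = 1) {
  cfg <- as.list(environment())
  cfg$sim$rng_seed <- seed
  class(cfg) <- "run_config"
  cfg
}

#' Run the whole panel analysis pipeline
#'
#' simulate (or load) -> panel-design screens -> filter cascade -> LD-kNNi
#' imputation -> translocation scan -> population structure (kinship, PCA,
#' NJ tree, admixture replicates, delta-K) -> BLUEs and MLM GWAS with
#' SimpleM-Bonferroni correction -> per-category MTA enrichment. All stage
#' outputs are written as TSV (plus VCF and Newick) under `out_dir`, with a
#' plain-text run report. Re-running with the same config reproduces the
#' outputs byte for byte.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with every stage's in-memory result
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message(sprintf("[panelgwas] %s", sprintf(...)))
  tsv <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)

  if (!is.null(config$vcf)) {
    if (!file.exists(config$vcf)) stop("genotype VCF not found: ", config$vcf)
    inp <- read_genotype_vcf(config$vcf)
    gm <- inp$genotypes; markers <- inp$markers
    truth <- NULL; reference <- NULL
    traits <- if (!is.null(config$traits_tsv)) {
      if (!file.exists(config$traits_tsv))
        stop("traits file not found: ", config$traits_tsv)
      df <- utils::read.delim(config$traits_tsv, stringsAsFactors = FALSE)
      trait_table(df$accession_id, df$trait, df$year, df$value)
    } else NULL
    log_msg("loaded %d markers x %d accessions from %s",
            n_markers(gm), n_accessions(gm), config$vcf)
  } else {
    log_msg("simulating panel (seed %d)", config$seed)
    simres <- simulate_panel(config$sim)
    gm <- simres$genotypes; markers <- simres$markers
    traits <- simres$traits; truth <- simres$truth
    reference <- simres$reference
    write_genotype_vcf(gm, markers, file.path(out_dir, "genotypes.vcf"))
    tsv(data.frame(accession_id = truth$accession_ids,
                   subpop = truth$subpop,
                   carrier = truth$accession_ids %in% truth$carriers),
        "truth.tsv")
  }

  # panel design screens (toy reference, when available)
  panel <- NULL
  if (!is.null(reference)) {
    fr <- flank_report(markers, reference)
    feas <- probe_feasibility(fr, gc_min = config$probe_gc$min,
                              gc_max = config$probe_gc$max)
    panel <- merge(fr, feas, by = "marker_id")
    tsv(panel, "panel_design.tsv")
    log_msg("panel design: %d/%d flanks feasible",
            sum(panel$feasible), nrow(panel))
  }

  st <- apply_filter_cascade(gm, markers, config$filter)
  log_msg("filter cascade: %d -> %d markers",
          n_markers(gm), n_markers(st$genotypes))
  funnel_flags <- list(call_rate = st$stats$pass_call_rate,
                       het = st$stats$pass_het, maf = st$stats$pass_maf)
  if (!is.null(panel)) {
    feas_flag <- markers$id %in% panel$marker_id[panel$feasible]
    funnel_flags <- c(list(probe = feas_flag), funnel_flags)
  }
  funnel <- panel_funnel_report(markers$category, funnel_flags)
  tsv(funnel, "funnel.tsv")

  # translocation scan runs on the *unfiltered* matrix: the missingness
  # signal lives in markers the call-rate filter removes
  trw <- config$sim$translocation
  carriers <- NULL
  if (!is.null(trw)) {
    carriers <- classify_carriers(gm, markers, trw$chrom, trw$start, trw$end)
    tsv(carriers, "carrier_calls.tsv")
    log_msg("translocation scan: %d carriers / %d non-carriers / %d intermediate",
            sum(carriers$class == "carrier"),
            sum(carriers$class == "non_carrier"),
            sum(carriers$class == "intermediate"))
  }
  profile <- missingness_profile(gm, markers)
  tsv(profile, "missingness_profile.tsv")

  gm_f <- st$genotypes; markers_f <- st$markers
  imp <- impute_ld_knni(gm_f, markers_f, config$impute)
  gm_i <- imp$genotypes
  log_msg("imputation: %d missing filled (%d by fallback)",
          sum(is.na(gm_f$calls)), imp$n_fallback)
  write_genotype_vcf(gm_i, markers_f, file.path(out_dir, "imputed.vcf"))

  kin <- centered_ibs_kinship(gm_i)
  pca <- pca_genotypes(gm_i, config$gwas$n_pcs)
  tsv(data.frame(accession_id = rownames(pca$scores), pca$scores),
      "pca_scores.tsv")
  dm <- ibs_distance(gm_i)
  tree <- neighbor_joining(dm)
  writeLines(write_tree_newick(tree), file.path(out_dir, "nj_tree.nwk"))

  max_mk <- config$structure$max_markers %||% Inf
  gm_s <- if (n_markers(gm_i) > max_mk) {
    thin <- unique(round(seq(1, n_markers(gm_i), length.out = max_mk)))
    subset_genotypes(gm_i, markers = thin)
  } else gm_i
  reps <- admixture_replicates(gm_s, k_range = config$structure$k_range,
                               n_replicates = config$structure$n_replicates,
                               seed = child_seed(config$seed, 6),
                               max_iter = config$structure$max_iter %||% 500,
                               tol = config$structure$tol %||% 1e-4)
  evanno <- evanno_delta_k(reps)
  tsv(evanno, "evanno.tsv")
  k_best <- best_k(evanno)
  log_msg("delta-K selects K = %d", k_best)
  q_best <- Filter(function(r) r$K == k_best, reps)
  q_best <- q_best[[which.max(vapply(q_best, `[[`, numeric(1), "loglik"))]]$Q
  tsv(data.frame(accession_id = gm_i$accession_ids, q_best), "q_matrix.tsv")

  assoc_all <- NULL; meff <- NA; alpha_c <- NA; enrich <- NULL
  if (!is.null(traits)) {
    blues <- compute_blues(traits)
    tsv(blues, "blues.tsv")
    meff <- simplem_meff(gm_i, markers_f)
    alpha_c <- bonferroni_threshold(meff, config$gwas$alpha)
    log_msg("SimpleM: Meff = %d of %d markers, corrected alpha = %.3g",
            as.integer(meff), n_markers(gm_i), alpha_c)
    assoc_all <- list()
    for (tr in unique(blues$trait)) {
      b <- blues[blues$trait == tr, ]
      y <- stats::setNames(b$blue, b$accession_id)
      a <- mlm_association(gm_i, markers_f, y, kinship = kin,
                           spec = config$gwas)
      a$trait <- tr
      a$significant <- a$p_value < alpha_c
      assoc_all[[tr]] <- a
      utils::write.table(qq_table(a$p_value),
                         file.path(out_dir, paste0("qq_", tr, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    assoc_all <- do.call(rbind, assoc_all)
    rownames(assoc_all) <- NULL
    tsv(assoc_all, "associations.tsv")
    sig_any <- tapply(assoc_all$significant, assoc_all$marker_id, any)
    enrich <- mta_category_enrichment(
      markers_f$id, markers_f$category,
      as.logical(sig_any[markers_f$id]))
    tsv(enrich$table, "mta_enrichment.tsv")
    log_msg("GWAS: %d significant MTAs over %d traits",
            sum(assoc_all$significant), length(unique(blues$trait)))
  }

  report <- c(
    sprintf("panelgwas run report (%s)", format(Sys.time(), "%Y-%m-%d")),
    sprintf("seed: %d", config$seed),
    sprintf("markers: %d input, %d after filter cascade",
            n_markers(gm), n_markers(gm_f)),
    sprintf("accessions: %d", n_accessions(gm)),
    if (!is.null(carriers)) sprintf(
      "carriers: %d / non-carriers: %d / intermediate: %d",
      sum(carriers$class == "carrier"),
      sum(carriers$class == "non_carrier"),
      sum(carriers$class == "intermediate")),
    sprintf("delta-K best K: %d", k_best),
    if (!is.na(meff)) sprintf("Meff: %d, corrected alpha: %.4g",
                              as.integer(meff), alpha_c),
    if (!is.null(assoc_all)) sprintf("significant MTAs: %d",
                                     sum(assoc_all$significant))
  )
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(list(genotypes = gm, markers = markers, filtered = st,
                 imputed = gm_i, markers_filtered = markers_f,
                 funnel = funnel, carriers = carriers, panel = panel,
                 kinship = kin, pca = pca, tree = tree, evanno = evanno,
                 best_k = k_best, associations = assoc_all, meff = meff,
                 alpha_corrected = alpha_c, enrichment = enrich,
                 truth = truth, traits = traits))
}
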