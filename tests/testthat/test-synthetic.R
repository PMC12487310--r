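test_that("generators are seed-deterministic end to end", {
  cfg <- small_sim(seed = 5, traits = one_locus_trait())
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$markers, b$markers)
  expect_identical(a$traits, b$traits)
  expect_identical(a$reference, b$reference)
  expect_identical(a$truth$carriers, b$truth$carriers)
})

test_that("flank duplication count is deterministic and zero means unique", {
  cfg0 <- small_sim(seed = 2, duplicate_fraction = 0)
  r0 <- simulate_reference(cfg0)
  fr0 <- flank_report(r0$markers, r0$reference)
  expect_true(all(fr0$n_exact_hits == 1L))

  cfg1 <- small_sim(seed = 2, duplicate_fraction = 0.1)
  r1 <- simulate_reference(cfg1)
  expect_length(r1$duplicated_ids, round(0.1 * cfg1$n_markers))
  fr1 <- flank_report(r1$markers, r1$reference)
  dup <- fr1$marker_id %in% r1$duplicated_ids
  expect_true(all(fr1$n_exact_hits[dup] >= 2L))
})

test_that("zero base missingness leaves no missing calls outside the block", {
  cfg <- small_sim(seed = 3, base_missing = 0, n_carriers = 10)
  sim <- simulate_panel(cfg, reference = FALSE)
  win <- sim$markers$chrom == "1B" & sim$markers$pos <= cfg$chrom_length_bp / 4
  expect_identical(sum(is.na(sim$genotypes$calls[!win, ])), 0L)
  outside_carriers <- setdiff(sim$genotypes$accession_ids, sim$truth$carriers)
  expect_identical(sum(is.na(sim$genotypes$calls[, outside_carriers])), 0L)
})

test_that("realized missing and het rates match the config within 3 MC SEs", {
  cfg <- sim_config(n_accessions = 80, n_markers = 1000,
                    chromosomes = c("1A", "1B"), chrom_length_bp = 1e7,
                    un_fraction = 0, het_rate = 0.05,
                    base_missing_rate = 0.03, translocation = NULL,
                    traits = list(), rng_seed = 17)
  sim <- simulate_population(cfg)
  calls <- sim$genotypes$calls
  n_cells <- length(calls)
  miss <- mean(is.na(calls))
  se_miss <- sqrt(0.03 * 0.97 / n_cells)
  expect_lt(abs(miss - 0.03), 3 * se_miss)
  het <- mean(calls == 1L, na.rm = TRUE)
  se_het <- sqrt(0.05 * 0.95 / sum(!is.na(calls)))
  expect_lt(abs(het - 0.05), 3 * se_het)
  # realized allele frequencies track the generating mixture frequencies
  f_exp <- (sim$truth$P %*% t(sim$truth$Q))
  expect_lt(abs(mean(calls, na.rm = TRUE) / 2 - mean(f_exp)), 0.02)
})

test_that("translocation injection hits carriers at the configured rate", {
  gm <- random_gm(50, 200, missing_rate = 0, seed = 8)
  mk <- markers_for(gm, chrom = "1B")
  spec <- list(chrom = "1B", start = 1, end = 50 * 1000, n_carriers = 200,
               carrier_missing_rate = 0.8)
  truth <- list(carriers = character(0))
  out <- inject_translocation_missingness(gm, mk, spec, truth, seed = 21)
  counts <- colSums(is.na(out$genotypes$calls))
  se <- sqrt(50 * 0.8 * 0.2 / 200)
  expect_lt(abs(mean(counts) - 40), 3 * se)

  # rate 1: every windowed call missing for carriers
  spec1 <- list(chrom = "1B", start = 1, end = 5e4, n_carriers = 30,
                carrier_missing_rate = 1)
  out1 <- inject_translocation_missingness(gm, mk, spec1, truth, seed = 3)
  expect_true(all(is.na(out1$genotypes$calls[, out1$truth$carriers])))

  # no carriers: identity; empty window: warning no-op
  spec0 <- list(chrom = "1B", start = 1, end = 5e4, n_carriers = 0,
                carrier_missing_rate = 1)
  expect_identical(
    inject_translocation_missingness(gm, mk, spec0, truth, 3)$genotypes$calls,
    gm$calls)
  spec_empty <- list(chrom = "7D", start = 1, end = 10, n_carriers = 5,
                     carrier_missing_rate = 1)
  expect_warning(
    same <- inject_translocation_missingness(gm, mk, spec_empty, truth, 3),
    "no markers")
  expect_identical(same$genotypes$calls, gm$calls)
})

test_that("an undivided population shows no cluster separation", {
  cfg <- small_sim(seed = 31, n_acc = 60, n_markers = 200, n_carriers = -1,
                   base_missing = 0, K_true = 1, divergence = 0, ld_rho = 0)
  sim <- simulate_population(cfg)
  X <- t(sim$genotypes$calls)
  km <- kmeans(X, 2, nstart = 5)
  sil <- cluster::silhouette(km$cluster, dist(X))
  expect_lt(mean(sil[, 3]), 0.2)
  # no dominant axis of variation either
  pca <- pca_genotypes(sim$genotypes, 2)
  expect_lt(pca$all_variance[1], 3 * mean(pca$all_variance[2:6]))
})

test_that("two diverged subpopulations are recoverable from genotypes", {
  cfg <- small_sim(seed = 32, n_acc = 60, n_markers = 250, n_carriers = -1,
                   base_missing = 0, divergence = 0.25,
                   admixture_fraction = 0)
  sim <- simulate_population(cfg)
  fit <- admixture_fit(sim$genotypes, K = 2, seeds = 100)[[1]]
  Q <- align_q_to_labels(fit$Q, sim$truth$subpop)
  assigned <- max.col(Q)
  expect_gte(mean(assigned == sim$truth$subpop), 0.95)
})

test_that("trait generation respects causal structure and heritability", {
  cfg <- small_sim(seed = 33, base_missing = 0, n_carriers = -1,
                   traits = one_locus_trait(effect = 2, h2 = 0.9))
  sim <- simulate_panel(cfg, reference = FALSE)
  tr <- sim$traits
  expect_s3_class(tr, "trait_table")
  expect_identical(nrow(tr), 3L * 60L)
  causal <- sim$truth$causal$trait1$ids
  blues <- compute_blues(tr)
  y <- setNames(blues$blue, blues$accession_id)[sim$genotypes$accession_ids]
  x <- sim$genotypes$calls[causal, ]
  expect_gt(summary(lm(y ~ x))$r.squared, 0.3)

  # a causal marker with zero calls is rejected
  gm_bad <- sim$genotypes
  gm_bad$calls[causal, ] <- NA_integer_
  expect_error(
    simulate_traits(gm_bad, sim$markers, sim$truth,
                    one_locus_trait(causal = causal), seed = 1),
    "entirely missing")
})
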