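test_that("BLUEs reduce to means on balanced data and pass through single years", {
  acc <- rep(paste0("S", 1:4), each = 3)
  yr <- rep(2019:2021, 4)
  set.seed(5)
  val <- rnorm(12) + rep(c(0, 3, 6), 4)
  tt <- trait_table(acc, "t", yr, val)
  bl <- compute_blues(tt)
  expect_equal(bl$blue, as.numeric(tapply(val, acc, mean)[paste0("S", 1:4)]),
               tolerance = 1e-10)

  t1 <- trait_table(paste0("S", 1:3), "t", 2020, c(5, 6, 7))
  expect_equal(compute_blues(t1)$blue, c(5, 6, 7))
})

test_that("unbalanced BLUEs match the normal-equations oracle", {
  acc <- c("a", "a", "a", "b", "b", "c")
  yr <- c("1", "2", "3", "1", "3", "2")
  val <- c(10, 12, 11, 8, 9, 15)
  tt <- trait_table(acc, "t", yr, val)
  bl <- compute_blues(tt)
  # oracle: direct least squares on [accession indicators, sum-coded years]
  A <- model.matrix(~ 0 + factor(acc))
  Yr <- model.matrix(~ factor(yr), contrasts.arg =
                       list(`factor(yr)` = contr.sum))[, -1, drop = FALSE]
  X <- cbind(A, Yr)
  beta <- solve(crossprod(X), crossprod(X, val))
  expect_equal(bl$blue, as.numeric(beta[1:3]), tolerance = 1e-10)
})

test_that("MLM with zero kinship and no PCs equals the OLS F-test", {
  gm <- random_gm(30, 40, missing_rate = 0, seed = 7)
  mk <- markers_for(gm)
  set.seed(8)
  y <- setNames(rnorm(40) + 0.8 * gm$calls[5, ], gm$accession_ids)
  K0 <- matrix(0, 40, 40)
  a <- mlm_association(gm, mk, y, kinship = K0, spec = mlm_spec(n_pcs = 0))
  for (i in c(1, 5, 12)) {
    id <- gm$marker_ids[i]
    ols <- summary(lm(y ~ gm$calls[i, ]))
    expect_equal(a$p_value[a$marker_id == id],
                 ols$coefficients[2, 4], tolerance = 1e-8)
    expect_equal(a$effect[a$marker_id == id],
                 unname(ols$coefficients[2, 1]), tolerance = 1e-8)
  }
})

test_that("degenerate markers are flagged with p = 1", {
  m <- rbind(rep(1L, 20), sample(0:2, 20, TRUE))
  gm <- gm_from(m)
  set.seed(1)
  y <- setNames(rnorm(20), gm$accession_ids)
  a <- mlm_association(gm, markers_for(gm), y,
                       kinship = matrix(0, 20, 20), spec = mlm_spec(n_pcs = 0))
  expect_true(a$flagged[a$marker_id == "M1"])
  expect_equal(a$p_value[a$marker_id == "M1"], 1)
})

test_that("conditioning on the causal dosage kills its own association", {
  gm <- random_gm(20, 50, missing_rate = 0, seed = 9)
  mk <- markers_for(gm)
  causal <- gm$calls[3, ]
  set.seed(10)
  y <- setNames(rnorm(50) + causal, gm$accession_ids)
  K <- centered_ibs_kinship(gm)
  spec <- mlm_spec(n_pcs = 0)
  a_plain <- mlm_association(gm, mk, y, kinship = K, spec = spec)
  expect_equal(a_plain$marker_id[which.min(a_plain$p_value)], "M3")
  a_cond <- mlm_association(gm, mk, y, kinship = K, spec = spec,
                            covariates = cbind(causal))
  expect_true(a_cond$flagged[a_cond$marker_id == "M3"])
  expect_equal(a_cond$p_value[a_cond$marker_id == "M3"], 1)
})

test_that("MLM finds a strong simulated locus under structure", {
  cfg <- small_sim(seed = 23, n_acc = 80, n_markers = 200, n_carriers = -1,
                   base_missing = 0,
                   traits = one_locus_trait(effect = 1.5, h2 = 0.8))
  sim <- simulate_panel(cfg, reference = FALSE)
  bl <- compute_blues(sim$traits)
  y <- setNames(bl$blue, bl$accession_id)
  a <- mlm_association(sim$genotypes, sim$markers, y, spec = mlm_spec(n_pcs = 3))
  expect_identical(a$marker_id[which.min(a$p_value)],
                   sim$truth$causal$trait1$ids)
})

test_that("SimpleM Meff matches the analytic eigen spectra", {
  # orthogonal (Walsh-pattern) markers: Meff = M
  walsh <- rbind(rep(c(0L, 2L), 8),
                 rep(c(0L, 0L, 2L, 2L), 4),
                 rep(c(rep(0L, 4), rep(2L, 4)), 2),
                 c(rep(0L, 8), rep(2L, 8)))
  gm <- gm_from(walsh)
  expect_identical(as.integer(simplem_meff(gm, markers_for(gm))), 4L)

  # one duplicated marker among M: Meff = M - 1
  m10 <- random_gm(10, 40, seed = 3)$calls
  m10[10, ] <- m10[1, ]
  gm10 <- gm_from(m10)
  expect_identical(as.integer(simplem_meff(gm10, markers_for(gm10))), 9L)

  # perfect-LD block of size b: Meff = M - b + 1
  m <- random_gm(12, 40, seed = 4)$calls
  for (i in 2:5) m[i, ] <- m[1, ]          # block of b = 5
  gmb <- gm_from(m)
  expect_identical(as.integer(simplem_meff(gmb, markers_for(gmb))), 8L)

  # chromosome-blockwise sum and zero-variance dropping
  mz <- rbind(m, rep(1L, 40))
  gmz <- gm_from(mz)
  mkz <- marker_table(gmz$marker_ids, rep(c("1A", "2A"), c(6, 7)),
                      seq_len(13) * 1000)
  expect_message(meff_z <- simplem_meff(gmz, mkz), "zero-variance")
  expect_identical(as.integer(meff_z), 2L + 6L)

  expect_true(1 <= as.integer(simplem_meff(gmb, markers_for(gmb))) &&
                as.integer(simplem_meff(gmb, markers_for(gmb))) <= 12)
})

test_that("Bonferroni thresholds are plain division", {
  expect_equal(bonferroni_threshold(100), 5e-4)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(3456), 0.05 / 3456, tolerance = 1e-12)
  expect_error(bonferroni_threshold(0.5), "meff")
})

test_that("category enrichment matches hypergeometric enumeration", {
  # identical proportions, equal sizes -> p = 1
  out <- mta_category_enrichment(
    paste0("m", 1:20), rep(c("A", "B"), each = 10),
    rep(c(TRUE, FALSE), 10))
  expect_equal(out$pairwise$p_value, 1)

  # (8,2; 1,9): enumeration oracle for the two-sided Fisher p
  enum_fisher <- function(a, b, c, d) {
    n1 <- a + b; n2 <- c + d; k <- a + c
    support <- max(0, k - n2):min(k, n1)
    probs <- dhyper(support, n1, n2, k)
    p_obs <- dhyper(a, n1, n2, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  out2 <- mta_category_enrichment(
    paste0("m", 1:20), rep(c("A", "B"), each = 10),
    c(rep(TRUE, 8), rep(FALSE, 2), TRUE, rep(FALSE, 9)))
  expect_equal(out2$pairwise$p_value, enum_fisher(8, 2, 1, 9),
               tolerance = 1e-12)

  # 0/10 vs 10/10 significant
  out3 <- mta_category_enrichment(
    paste0("m", 1:20), rep(c("A", "B"), each = 10),
    c(rep(FALSE, 10), rep(TRUE, 10)))
  expect_lt(out3$pairwise$p_value, 0.001)
  expect_equal(out3$pairwise$p_value, enum_fisher(0, 10, 10, 0),
               tolerance = 1e-12)
  # distinguishable proportions get different group letters
  expect_false(out3$table$group[1] == out3$table$group[2])
})

test_that("QQ tables pair sorted p-values with uniform quantiles", {
  qq1 <- qq_table(0.5)
  expect_equal(qq1$expected, -log10(0.5), tolerance = 1e-6)
  expect_equal(qq1$observed, -log10(0.5), tolerance = 1e-6)
  grid <- (seq_len(100) - 0.5) / 100
  qq <- qq_table(grid)
  expect_equal(qq$expected, qq$observed, tolerance = 1e-12)
})
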