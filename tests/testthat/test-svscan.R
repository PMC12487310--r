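test_that("missingness profile reports per-marker no-call fractions", {
  gm <- random_gm(20, 200, missing_rate = 0, seed = 2)
  prof <- missingness_profile(gm, markers_for(gm))
  expect_true(all(prof$missing_fraction == 0))
  m <- gm$calls
  m[1, 1:10] <- NA_integer_
  prof2 <- missingness_profile(genotype_matrix(m), markers_for(gm))
  expect_equal(prof2$missing_fraction[prof2$marker_id == "M1"], 0.05)
  expect_false(is.unsorted(prof2$pos))
})

test_that("gap thresholds split a clearly bimodal count distribution", {
  counts <- c(0, 0, 1, 48, 49, 50)
  th <- auto_thresholds(counts)
  cls <- ifelse(counts > th$t_high, "carrier",
                ifelse(counts < th$t_low, "non_carrier", "intermediate"))
  expect_identical(cls, c(rep("non_carrier", 3), rep("carrier", 3)))
  # degenerate: everyone equal -> all non-carrier
  th0 <- auto_thresholds(rep(7, 5))
  expect_true(all(rep(7, 5) < th0$t_low))
})

test_that("two comparable gaps leave the middle cluster intermediate", {
  counts <- c(0, 1, 20, 21, 48, 50)
  th <- auto_thresholds(counts)
  cls <- ifelse(counts > th$t_high, "carrier",
                ifelse(counts < th$t_low, "non_carrier", "intermediate"))
  expect_identical(cls, c("non_carrier", "non_carrier", "intermediate",
                          "intermediate", "carrier", "carrier"))
})

test_that("carrier classification works with manual and auto thresholds", {
  gm <- random_gm(40, 30, missing_rate = 0, seed = 5)
  mk <- markers_for(gm, chrom = "1B")
  m <- gm$calls
  m[1:30, 1:6] <- NA_integer_    # 6 clear carriers over 30 window markers
  gm2 <- genotype_matrix(m)
  cc <- classify_carriers(gm2, mk, "1B", 1, 30 * 1000)
  expect_identical(sum(cc$class == "carrier"), 6L)
  expect_identical(sum(cc$class == "non_carrier"), 24L)
  # window bounds by marker id, manual thresholds
  cc2 <- classify_carriers(gm2, mk, "1B", "M1", "M30",
                           t_low = 5, t_high = 20)
  expect_identical(cc2$class, cc$class)
  expect_error(classify_carriers(gm2, mk, "7D", 1, 10), "no markers")
  # zero missing in window -> everyone non-carrier
  cc0 <- classify_carriers(gm, mk, "1B", 1, 30 * 1000)
  expect_true(all(cc0$class == "non_carrier"))
})

test_that("classification ignores marker order inside the window", {
  sim <- simulate_panel(small_sim(seed = 13), reference = FALSE)
  win_end <- sim$markers$pos[1]  # any bounds: use full window
  cc1 <- classify_carriers(sim$genotypes, sim$markers, "1B", 1, 1e6)
  perm <- sample(n_markers(sim$genotypes))
  cc2 <- classify_carriers(subset_genotypes(sim$genotypes, markers = perm),
                           sim$markers[perm, ], "1B", 1, 1e6)
  expect_identical(cc1$class, cc2$class)
})

test_that("concordance builds the 2x2 table and excludes intermediates", {
  calls <- data.frame(
    accession_id = paste0("S", 1:8),
    missing_count = c(40, 41, 0, 1, 0, 2, 20, 39),
    class = c("carrier", "carrier", "non_carrier", "non_carrier",
              "non_carrier", "non_carrier", "intermediate", "carrier"))
  labels <- data.frame(accession_id = paste0("S", 1:8),
                       carrier = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE,
                                   TRUE, TRUE))
  out <- concordance(calls, labels)
  expect_equal(out$agreement, 6 / 7)
  expect_identical(out$n_intermediate, 1L)
  expect_identical(as.integer(out$table), c(3L, 1L, 0L, 3L))
  # arithmetic identity on a constructed (19,169,1,1) table
  tab <- matrix(c(19, 1, 1, 169), 2, 2)
  expect_equal((tab[1, 1] + tab[2, 2]) / sum(tab), 188 / 190)
  expect_error(concordance(calls,
                           data.frame(accession_id = "X1", carrier = TRUE)),
               "no shared")
})

test_that("the genome scan flags only the injected chromosome arm", {
  cfg <- small_sim(seed = 19, n_acc = 80, n_markers = 320, n_carriers = 16,
                   carrier_rate = 0.95, base_missing = 0.01)
  sim <- simulate_panel(cfg, reference = FALSE)
  sc <- scan_missingness_windows(sim$genotypes, sim$markers,
                                 window_size = 20, min_fraction = 0.5,
                                 min_accessions = 8)
  flagged <- sc[sc$flagged, ]
  expect_gt(nrow(flagged), 0)
  expect_true(all(flagged$chrom == "1B"))
  expect_true(all(flagged$start <= cfg$translocation$end))
})
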