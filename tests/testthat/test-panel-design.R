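test_that("GC content follows the N-excluded definition", {
  expect_equal(flank_gc_content("ACGT"), 0.50)
  expect_equal(flank_gc_content("GGCC"), 1.00)
  expect_equal(flank_gc_content("ANGT"), 1 / 3)
  expect_true(is.na(flank_gc_content("NNN")))
  expect_equal(flank_gc_content(c("acgt", "AAAA")), c(0.5, 0))
  expect_error(flank_gc_content("ACGU"), "alphabet")
  expect_error(flank_gc_content(""), "length")
})

test_that("GC content is strand-invariant", {
  set.seed(14)
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 31, replace = TRUE),
               collapse = "")
    expect_equal(flank_gc_content(s), flank_gc_content(revcomp(s)))
  }
})

test_that("exact-match counting handles overlaps and both strands", {
  expect_equal(count_exact_matches("ACGT", c(x = "ACGTACGT")), 2L)
  expect_equal(count_exact_matches("ACGTT", c(x = "GGGGGG")), 0L)
  expect_equal(count_exact_matches("AAAA", c(x = "AAAAAA")), 3L)
  # reverse-complement hit on the other strand
  expect_equal(count_exact_matches("AAGG", c(x = "TTTTCCTTTT")), 1L)
})

test_that("exact-match counting equals a naive sliding-window oracle", {
  set.seed(7)
  for (i in 1:25) {
    ref <- vapply(1:2, function(j)
      paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE,
                   prob = c(0.4, 0.1, 0.1, 0.4)), collapse = ""),
      character(1))
    names(ref) <- c("c1", "c2")
    frag <- paste(sample(c("A", "C", "G", "T"), sample(2:4, 1),
                         replace = TRUE, prob = c(0.4, 0.1, 0.1, 0.4)),
                  collapse = "")
    expect_equal(count_exact_matches(frag, ref), naive_count(frag, ref),
                 info = paste("fragment", frag))
  }
})

test_that("probe feasibility rejects multilocus flanks and off-band GC", {
  flanks <- data.frame(marker_id = c("a", "b", "c"),
                       gc_fraction = c(0.50, 0.55, 0.20),
                       n_exact_hits = c(1L, 2L, 1L),
                       unique = c(TRUE, FALSE, TRUE))
  out <- probe_feasibility(flanks, gc_min = 0.30, gc_max = 0.70)
  expect_identical(out$feasible, c(TRUE, FALSE, FALSE))
  expect_identical(out$reason, c("", "multilocus", "gc"))
  # one passing probe out of two is enough
  probes <- data.frame(marker_id = c("a", "a", "c", "c"),
                       gc_fraction = c(0.10, 0.50, 0.15, 0.20))
  out2 <- probe_feasibility(flanks, probes)
  expect_true(out2$feasible[out2$marker_id == "a"])
  expect_identical(out2$reason[out2$marker_id == "c"], "gc")
})

test_that("the survival funnel matches a brute-force recount", {
  set.seed(41)
  cats <- sample(c("A", "B", "C", "D", "G"), 100, replace = TRUE)
  flags <- list(s1 = runif(100) < 0.8, s2 = runif(100) < 0.7,
                s3 = runif(100) < 0.9)
  fun <- panel_funnel_report(cats, flags)
  for (cc in unique(cats)) {
    alive <- rep(TRUE, 100)
    for (s in names(flags)) {
      alive <- alive & flags[[s]]
      expect_equal(fun[[s]][fun$category == cc], sum(alive & cats == cc))
    }
  }
  # counts non-increasing across stages for every category
  stage_cols <- c("initial", names(flags))
  for (r in seq_len(nrow(fun)))
    expect_true(all(diff(as.numeric(fun[r, stage_cols])) <= 0))
})

test_that("funnel edge cases: all-pass identity, empty input, bad category", {
  cats <- rep(c("A", "D"), 5)
  all_pass <- list(s1 = rep(TRUE, 10))
  fun <- panel_funnel_report(cats, all_pass)
  expect_identical(fun$s1, fun$initial)
  expect_true(all(fun$final_pct == 100))
  empty <- panel_funnel_report(character(0), list(s1 = logical(0)))
  expect_identical(empty$initial, 0L)
  expect_error(panel_funnel_report("Z", list(s1 = TRUE)), "category")
})
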