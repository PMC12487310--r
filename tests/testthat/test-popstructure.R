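test_that("centered-IBS kinship matches hand multiplication", {
  # 2 accessions x 2 markers, dosages [[0,2],[2,0]]:
  # p = (0.5, 0.5); c = 2*0.25 + 2*0.25 = 1; W rows (-1,1),(1,-1)
  gm <- gm_from(rbind(c(0L, 2L), c(2L, 0L)))
  K <- centered_ibs_kinship(gm)
  expect_equal(unname(K), matrix(c(2, -2, -2, 2), 2, 2))

  # identical accessions: equal rows, K[1,1] == K[1,2]
  gm2 <- gm_from(cbind(c(0L, 2L, 1L), c(0L, 2L, 1L), c(2L, 0L, 1L)))
  K2 <- centered_ibs_kinship(gm2)
  expect_equal(K2[1, ], K2[2, ])
  expect_equal(K2[1, 1], K2[1, 2])
  expect_error(centered_ibs_kinship(gm_from(matrix(c(0L, NA), 1, 2))),
               "impute")
})

test_that("kinship is PSD on simulated panels", {
  for (seed in c(3, 4)) {
    gm <- random_gm(80, 30, missing_rate = 0, seed = seed)
    K <- centered_ibs_kinship(gm)
    expect_equal(K, t(K))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("IBS distance follows the shared-allele score", {
  gm <- gm_from(cbind(a = c(0L, 0L, 0L), b = c(0L, 0L, 0L),
                      c = c(2L, 2L, 2L), d = c(1L, 1L, 1L)))
  dm <- ibs_distance(gm)
  expect_equal(dm[1, 2], 0)
  expect_equal(dm[1, 3], 1)
  expect_equal(dm[1, 4], 0.5)
  expect_equal(diag(dm), setNames(rep(0, 4), gm$accession_ids))
  expect_equal(dm, t(dm))
  # missing pairs drop out of numerator and denominator
  gm2 <- gm_from(rbind(c(0L, 2L), c(0L, NA), c(2L, 2L)))
  expect_equal(ibs_distance(gm2)[1, 2], (1 + 0) / 2 / 1 * 1)  # mean(|d|)/2 over 2 markers
  expect_equal(ibs_distance(gm2)[1, 2], (2 + 0) / (2 * 2))
  # zero overlap is undefined
  gm3 <- gm_from(rbind(c(0L, NA), c(NA, 2L)))
  expect_true(is.na(ibs_distance(gm3)[1, 2]))
})

test_that("PCA equals a dense eigensolver oracle up to sign", {
  set.seed(21)
  m <- matrix(sample(0:2, 12, TRUE), 4, 3)  # 4 markers x 3 accessions
  gm <- gm_from(m)
  pca <- suppressMessages(pca_genotypes(gm, 3))
  X <- scale(t(m), center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(X) / (nrow(X) - 1), symmetric = TRUE)
  scores_oracle <- X %*% ev$vectors
  for (k in seq_len(ncol(pca$scores))) {
    if (pca$variance_fraction[k] < 1e-12) next
    expect_equal(abs(unname(pca$scores[, k])), abs(scores_oracle[, k]),
                 tolerance = 1e-8)
  }
  expect_equal(sum(pca$all_variance), 1)

  # rank-1 matrix loads everything on PC1
  r1 <- gm_from(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  expect_equal(suppressMessages(pca_genotypes(r1, 1))$variance_fraction[1], 1)
})

test_that("component count is clipped with a notice", {
  gm <- random_gm(10, 4, seed = 3)
  expect_message(pca <- pca_genotypes(gm, 10), "clipped")
  expect_identical(ncol(pca$scores), 4L)
})

test_that("NJ recovers additive trees exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  dm <- ape::cophenetic.phylo(tr)
  nj <- neighbor_joining(dm, midpoint = FALSE)
  expect_equal(ape::cophenetic.phylo(nj)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-10)
  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nj3 <- neighbor_joining(d3, midpoint = FALSE)
  len <- setNames(nj3$edge.length[match(1:3, nj3$edge[, 2])],
                  nj3$tip.label)
  expect_equal(len[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
})

test_that("midpoint-rooted NJ keeps ultrametric clusters monophyletic", {
  tr <- ape::read.tree(
    text = "(((a:1,b:1):1,c:2):3,((d:1,e:1):1,f:2):3);")
  nj <- neighbor_joining(ape::cophenetic.phylo(tr))
  expect_true(ape::is.monophyletic(nj, c("a", "b", "c")))
  expect_true(ape::is.monophyletic(nj, c("d", "e", "f")))
})

test_that("negative NJ branches are clamped without breaking path lengths much", {
  set.seed(8)
  n <- 6
  noise <- matrix(rnorm(n * n, 0, 0.3), n, n)
  noise <- (noise + t(noise)) / 2; diag(noise) <- 0
  dm <- as.matrix(dist(matrix(rnorm(n * 3), n))) + abs(noise)
  dimnames(dm) <- list(letters[1:n], letters[1:n])
  nj <- neighbor_joining(dm, midpoint = FALSE)
  expect_true(all(nj$edge.length >= 0))
  expect_error(neighbor_joining(matrix(c(0, NA, NA, 0), 2, 2)), "3 taxa")
})
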