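# Centered-IBS kinship from a complete dosage matrix (markers x accessions).
centered_ibs_kinship_dosage <- function(d) {
  p <- rowMeans(d) / 2
  W <- d - rowMeans(d)
  c0 <- sum(2 * p * (1 - p))
  if (c0 <= 0) stop("no polymorphic markers: kinship scale is zero")
  crossprod(W) / c0
}

#' Centered-IBS kinship matrix
#'
#' Genomic relationship matrix `K = W'W / c` where `W` is the dosage matrix
#' with per-marker means subtracted and `c = sum_m 2 p_m (1 - p_m)` is the
#' total expected heterozygosity. Symmetric and positive semi-definite by
#' construction. Requires a complete matrix — impute first.
#'
#' @param gm a [genotype_matrix()] without missing calls
#' @return accession x accession numeric matrix
#' @export
centered_ibs_kinship <- function(gm) {
  if (anyNA(gm$calls))
    stop("genotypes contain missing calls; impute before computing kinship")
  centered_ibs_kinship_dosage(dosages(gm))
}

#' Identity-by-state distance matrix
#'
#' `d(i, j) = 1 - mean(shared-allele score)` over markers called in both
#' accessions, with score 1 for identical genotypes, 0.5 when one allele is
#' shared (dosages differing by 1) and 0 otherwise. Pairs with no
#' overlapping calls get `NA`.
#'
#' @param gm a [genotype_matrix()] with at least two accessions
#' @return symmetric accession x accession matrix with zero diagonal
#' @export
ibs_distance <- function(gm) {
  if (n_accessions(gm) < 2L) stop("need at least two accessions")
  d <- dosages(gm)
  valid <- !is.na(d)
  I <- lapply(0:2, function(g) { m <- (d == g) & valid; m[is.na(m)] <- FALSE
                                 storage.mode(m) <- "double"; m })
  sum_absdiff <- crossprod(I[[1]], I[[2]]) + crossprod(I[[2]], I[[1]]) +
    crossprod(I[[2]], I[[3]]) + crossprod(I[[3]], I[[2]]) +
    2 * (crossprod(I[[1]], I[[3]]) + crossprod(I[[3]], I[[1]]))
  storage.mode(valid) <- "double"
  overlap <- crossprod(valid)
  dm <- sum_absdiff / (2 * overlap)
  dm[overlap == 0] <- NA_real_
  diag(dm) <- 0
  dimnames(dm) <- list(gm$accession_ids, gm$accession_ids)
  dm
}

#' Principal components of the genotype matrix
#'
#' Eigen-decomposition of the covariance of the column-centred (not
#' variance-scaled) dosage matrix. The sign of each component is fixed by
#' forcing its largest-magnitude marker loading positive, so scores are
#' reproducible across platforms.
#'
#' @param gm a [genotype_matrix()] without missing calls
#' @param n_components number of components to return (clipped to
#'   `min(n, M)` with a message)
#' @return list with `scores` (accessions x components),
#'   `variance_fraction` (per returned component), and `all_variance`
#'   (full eigenvalue-share vector; sums to 1)
#' @export
pca_genotypes <- function(gm, n_components = 10) {
  if (anyNA(gm$calls)) stop("genotypes contain missing calls; impute first")
  X <- t(dosages(gm))                      # accessions x markers
  max_comp <- min(dim(X))
  if (n_components > max_comp) {
    message(sprintf("n_components clipped from %d to %d",
                    n_components, max_comp))
    n_components <- max_comp
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  sco <- pc$x[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    top <- which.max(abs(rot[, k]))
    if (rot[top, k] < 0) { rot[, k] <- -rot[, k]; sco[, k] <- -sco[, k] }
  }
  rownames(sco) <- gm$accession_ids
  list(scores = sco, variance_fraction = frac[seq_len(n_components)],
       all_variance = frac)
}

#' Neighbor-joining tree from an IBS distance matrix
#'
#' Saitou-Nei agglomeration (via `ape::nj`), followed by clamping any
#' negative branch length to zero with the deficit moved onto the sister
#' edge(s) so path lengths through the node are preserved, and optional
#' midpoint rooting (the default).
#'
#' @param dm symmetric distance matrix with defined entries, >= 3 taxa
#' @param midpoint root the tree at its midpoint (default TRUE)
#' @return an `ape::phylo` tree
#' @export
neighbor_joining <- function(dm, midpoint = TRUE) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("need at least 3 taxa")
  if (anyNA(dm)) stop("distance matrix contains undefined entries")
  tree <- ape::nj(dm)
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    sisters <- setdiff(which(tree$edge[, 1] == tree$edge[e, 1]), e)
    tree$edge.length[sisters] <- tree$edge.length[sisters] + deficit
  }
  if (midpoint) tree <- phangorn::midpoint(tree)
  tree
}
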