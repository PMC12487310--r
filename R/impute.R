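#' Squared LD correlation between two dosage vectors
#'
#' Squared Pearson correlation over pairwise-complete accessions. Defined
#' as 0 when either site has zero variance over the shared calls or fewer
#' than two shared calls exist.
#'
#' @param a,b numeric dosage vectors (NA = missing), equal length
#' @return r-squared in `[0, 1]`
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(0)
  x <- a[ok]; y <- b[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' LD-kNNi parameters
#'
#' Defaults are the published panel's settings: 30 high-LD sites, 10
#' nearest neighbours, and a 1 Mb window for finding LD partners.
#'
#' @param l number of high-LD sites used to measure accession distance
#' @param k number of nearest neighbour accessions
#' @param max_distance_bp window (same chromosome) for LD partner sites
#' @param fallback what to do when no LD sites or no scored neighbour
#'   exists: `"mode"` (most frequent called genotype at the site) or
#'   `"leave_missing"`
#' @param eps floor on the neighbour distance before 1/d^2 weighting
#' @return a named list
#' @export
ld_knni_params <- function(l = 30, k = 10, max_distance_bp = 1e6,
                           fallback = c("mode", "leave_missing"),
                           eps = 1e-8) {
  stopifnot(l >= 1, k >= 1, max_distance_bp >= 0)
  list(l = l, k = k, max_distance_bp = max_distance_bp,
       fallback = match.arg(fallback), eps = eps)
}

# Most frequent called genotype at a site (ties toward lower dosage).
site_mode <- function(x) {
  tab <- tabulate(x + 1L, nbins = 3L)
  if (sum(tab) == 0L) return(NA_integer_)
  as.integer(which.max(tab) - 1L)
}

#' Impute missing genotypes by LD-kNNi
#'
#' For each missing call at site s of accession i: the `l` sites in highest
#' LD (r-squared) with s among same-chromosome sites within the window are
#' selected; the distance from i to every other accession called at s is
#' the mean squared dosage difference over the shared-called subset of
#' those sites (accessions sharing no called site are skipped); the `k`
#' nearest accessions vote for their genotype at s with weight `1/d^2`
#' (d floored at `eps`), and the genotype with the largest total weight is
#' imputed. Ties go to the more frequent genotype at s, then to the lower
#' dosage. Observed calls are never altered. Unplaced ("Un") markers have
#' no positional window and always use the fallback.
#'
#' @param gm a [genotype_matrix()]
#' @param markers the matching [marker_table()] (chromosome and position)
#' @param params an [ld_knni_params()] list
#' @return list with `genotypes` (imputed [genotype_matrix()]) and
#'   `n_fallback` (count of cells imputed by the fallback rule)
#' @export
impute_ld_knni <- function(gm, markers, params = ld_knni_params()) {
  stopifnot(identical(markers$id, gm$marker_ids))
  d <- dosages(gm)
  out <- gm$calls
  miss_sites <- which(rowSums(is.na(d)) > 0L)
  n_fallback <- 0L
  for (s in miss_sites) {
    miss_acc <- which(is.na(d[s, ]))
    cand <- which(markers$chrom == markers$chrom[s] &
                    markers$chrom != "Un" &
                    abs(markers$pos - markers$pos[s]) <= params$max_distance_bp)
    cand <- setdiff(cand, s)
    ld_sites <- integer(0)
    if (length(cand) > 0 && markers$chrom[s] != "Un") {
      r2 <- apply(d[cand, , drop = FALSE], 1L, ld_r2, b = d[s, ])
      keep <- order(r2, decreasing = TRUE)[seq_len(min(params$l, length(cand)))]
      ld_sites <- cand[keep[r2[keep] > 0]]
    }
    mode_s <- site_mode(out[s, ])
    for (i in miss_acc) {
      g <- impute_one(d, s, i, ld_sites, params)
      if (is.na(g)) {
        n_fallback <- n_fallback + 1L
        g <- if (params$fallback == "mode") mode_s else NA_integer_
      }
      out[s, i] <- g
    }
  }
  list(genotypes = genotype_matrix(out), n_fallback = n_fallback)
}

# kNN vote for one missing cell; NA when no usable LD sites or neighbours.
impute_one <- function(d, s, i, ld_sites, params) {
  if (length(ld_sites) == 0L) return(NA_integer_)
  called_at_s <- which(!is.na(d[s, ]) & seq_len(ncol(d)) != i)
  if (length(called_at_s) == 0L) return(NA_integer_)
  block <- d[ld_sites, , drop = FALSE]
  xi <- block[, i]
  if (all(is.na(xi))) return(NA_integer_)
  diff2 <- (block[, called_at_s, drop = FALSE] - xi)^2
  overlap <- colSums(!is.na(diff2))
  dist <- colMeans(diff2, na.rm = TRUE)
  usable <- overlap > 0L
  if (!any(usable)) return(NA_integer_)
  j <- called_at_s[usable]
  dist <- pmax(dist[usable], params$eps)
  nn <- order(dist)[seq_len(min(params$k, length(dist)))]
  w <- 1 / dist[nn]^2
  geno <- d[s, j[nn]]
  votes <- vapply(0:2, function(g) sum(w[geno == g]), numeric(1))
  top <- which(votes == max(votes)) - 1L
  if (length(top) == 1L) return(as.integer(top))
  # tie: more frequent genotype at the site, then lower dosage
  freq <- tabulate(d[s, ] + 1L, nbins = 3L)[top + 1L]
  as.integer(top[order(-freq, top)][1L])
}

#' Site-mode imputation baseline
#'
#' Replaces every missing call with the most frequent called genotype at
#' its site — the naive baseline LD-kNNi is compared against.
#'
#' @param gm a [genotype_matrix()]
#' @return an imputed [genotype_matrix()]
#' @export
impute_mode <- function(gm) {
  out <- gm$calls
  for (s in which(rowSums(is.na(out)) > 0L)) {
    out[s, is.na(out[s, ])] <- site_mode(out[s, ])
  }
  genotype_matrix(out)
}
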