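#' Maximum-likelihood admixture model fit (EM)
#'
#' Fits the binomial admixture model: accession i's dosage at marker m is
#' Binomial(2, f_im) with `f_im = sum_k q_ik p_mk`, `Q` the accession
#' ancestry fractions (rows sum to 1) and `P` the subpopulation allele
#' frequencies. The log-likelihood `sum x log f + (2 - x) log(1 - f)`
#' (combinatorial constant dropped) is maximised by EM from a random
#' Dirichlet start per replicate seed; EM makes it non-decreasing every
#' iteration. Replicate fits from different seeds play the role of the
#' replicate runs consumed by the Evanno delta-K statistic.
#'
#' For `K = 1` the analytic optimum (observed allele frequencies) is
#' returned directly.
#'
#' @param gm a [genotype_matrix()] without missing calls
#' @param K number of subpopulations (1 <= K <= accessions)
#' @param seeds integer vector: one replicate per seed
#' @param max_iter,tol EM stopping rule (`delta log-lik < tol`)
#' @return list of replicates, each
#'   `list(K, replicate, seed, loglik, Q, P, loglik_trace, converged)`
#' @export
admixture_fit <- function(gm, K, seeds = 1, max_iter = 500, tol = 1e-4) {
  if (anyNA(gm$calls)) stop("genotypes contain missing calls; impute first")
  n <- n_accessions(gm)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K cannot exceed the number of accessions")
  X <- t(dosages(gm))                          # n x M
  M <- ncol(X)
  X2 <- 2 - X
  clamp <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  loglik <- function(Fm) sum(X * log(Fm)) + sum(X2 * log1p(-Fm))
  lapply(seq_along(seeds), function(r) {
    if (K == 1) {
      p <- clamp(colMeans(X) / 2)
      Fm <- matrix(p, n, M, byrow = TRUE)
      return(list(K = 1L, replicate = r, seed = seeds[r],
                  loglik = loglik(Fm),
                  Q = matrix(1, n, 1), P = matrix(p, M, 1),
                  loglik_trace = loglik(Fm), converged = TRUE))
    }
    with_seed(seeds[r], {
      Q <- matrix(stats::rgamma(n * K, 1), n, K)
      Q <- Q / rowSums(Q)
      P <- matrix(stats::runif(M * K, 0.05, 0.95), M, K)
      trace <- numeric(0)
      prev <- -Inf
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        Fm <- clamp(tcrossprod(Q, P))          # n x M
        ll <- loglik(Fm)
        trace <- c(trace, ll)
        if (is.finite(prev) && ll - prev < tol) { converged <- TRUE; break }
        prev <- ll
        A <- X / Fm                            # alt-allele responsibility base
        B <- X2 / (1 - Fm)
        # expected allele counts per component, via the separable identity
        # colSums(A * (q x p)) = p * (A' q), rowSums(A * (q x p)) = q * (A p)
        num_p <- P * crossprod(A, Q)           # M x K, E[# alt from k]
        den_p <- num_p + (1 - P) * crossprod(B, Q)
        Q <- Q * (A %*% P + B %*% (1 - P)) / (2 * M)
        Q <- Q / rowSums(Q)
        P <- clamp(num_p / pmax(den_p, 1e-12))
      }
      if (!converged) {                        # score the final update
        ll <- loglik(clamp(tcrossprod(Q, P)))
        trace <- c(trace, ll)
      }
      list(K = as.integer(K), replicate = r, seed = seeds[r],
           loglik = trace[length(trace)], Q = Q, P = P,
           loglik_trace = trace, converged = converged)
    })
  })
}

#' Fit admixture replicates over a range of K
#'
#' Runs [admixture_fit()] for each K in `k_range` with `n_replicates`
#' seeded restarts, returning the flat replicate list [evanno_delta_k()]
#' consumes.
#'
#' @param gm a [genotype_matrix()] without missing calls
#' @param k_range contiguous integer range of K values (e.g. `1:10`)
#' @param n_replicates replicates per K (default 10)
#' @param seed root seed (replicate seeds are child streams)
#' @param ... passed to [admixture_fit()]
#' @return list of replicate fits
#' @export
admixture_replicates <- function(gm, k_range = 1:10, n_replicates = 10,
                                 seed = 1, ...) {
  out <- list()
  for (K in k_range) {
    seeds <- vapply(seq_len(n_replicates),
                    function(r) child_seed(seed, 100L * K + r), integer(1))
    out <- c(out, admixture_fit(gm, K, seeds = seeds, ...))
  }
  out
}

#' Evanno delta-K model-selection table
#'
#' From replicate log-likelihoods L(K): `deltaK(K) = mean_r |L_r(K+1) -
#' 2 L_r(K) + L_r(K-1)| / sd_r(L_r(K))`, the mean absolute second
#' difference of the likelihood across replicate runs (paired by replicate
#' index) over the between-replicate standard deviation at K. Defined for
#' interior K only; `sd = 0` leaves delta-K undefined (`NA`).
#'
#' @param replicates list of fits from [admixture_replicates()] (each needs
#'   `K`, `replicate`, `loglik`); every K must carry the same number of
#'   replicates and the K range must be contiguous
#' @return data.frame per K: `K`, `mean_loglik`, `sd_loglik`,
#'   `mean_abs_l2` (mean |second difference|), `delta_k`
#' @export
evanno_delta_k <- function(replicates) {
  K <- vapply(replicates, `[[`, integer(1), "K")
  L <- vapply(replicates, `[[`, numeric(1), "loglik")
  rep_i <- vapply(replicates, `[[`, numeric(1), "replicate")
  ks <- sort(unique(K))
  if (length(ks) < 2L) stop("need replicates for at least two values of K")
  if (!all(diff(ks) == 1L)) stop("K range must be contiguous")
  n_rep <- length(unique(rep_i))
  if (any(table(K) < 2L)) stop("need >= 2 replicates per K")
  Lmat <- matrix(NA_real_, n_rep, length(ks),
                 dimnames = list(NULL, ks))       # replicate x K
  for (i in seq_along(K))
    Lmat[rep_i[i], match(K[i], ks)] <- L[i]
  sdL <- apply(Lmat, 2, stats::sd)
  out <- data.frame(K = ks, mean_loglik = colMeans(Lmat), sd_loglik = sdL,
                    mean_abs_l2 = NA_real_, delta_k = NA_real_)
  for (j in seq_along(ks)) {
    if (j == 1L || j == length(ks)) next
    l2 <- abs(Lmat[, j + 1] - 2 * Lmat[, j] + Lmat[, j - 1])
    out$mean_abs_l2[j] <- mean(l2)
    out$delta_k[j] <- if (sdL[j] > 0) mean(l2) / sdL[j] else NA_real_
  }
  rownames(out) <- NULL
  out
}

#' Best-supported K from an Evanno table
#'
#' @param evanno output of [evanno_delta_k()]
#' @return the K maximising delta-K (interior K only)
#' @export
best_k <- function(evanno) {
  ok <- !is.na(evanno$delta_k)
  if (!any(ok)) stop("delta-K undefined for every interior K")
  evanno$K[ok][which.max(evanno$delta_k[ok])]
}

#' Align ancestry matrices to a reference labelling
#'
#' Greedy column matching of a Q matrix to reference labels (or a reference
#' Q) so subpopulation indices are comparable across runs — the label-swap
#' invariance of mixture models otherwise confounds comparisons.
#'
#' @param Q accession x K ancestry matrix
#' @param reference integer labels in `1..K` (length = accessions)
#' @return Q with columns permuted to best match the reference
#' @export
align_q_to_labels <- function(Q, reference) {
  K <- ncol(Q)
  perm <- integer(K)
  used <- logical(K)
  for (k in seq_len(K)) {
    mean_in <- vapply(seq_len(K), function(j) {
      if (used[j]) -Inf else mean(Q[reference == k, j])
    }, numeric(1))
    perm[k] <- which.max(mean_in)
    used[perm[k]] <- TRUE
  }
  Q[, perm, drop = FALSE]
}
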