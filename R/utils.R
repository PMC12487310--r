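#' Derive a child RNG seed from a root seed
#'
#' All generators take one root seed; each stage draws from its own child
#' stream so stages can be re-run independently without disturbing each
#' other. Child seeds are a fixed affine map of the root modulo a Mersenne
#' prime, kept within 32-bit integer range.
#'
#' @param root integer root seed
#' @param stream small integer stream index (one per operation)
#' @return an integer seed
#' @export
child_seed <- function(root, stream) {
  as.integer((as.numeric(root) %% 2147483647 * 48271 + stream) %% 2147483647)
}

# Run code under a seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Dosage matrix (markers x accessions, NA for missing) from a genotype_matrix.
dosages <- function(gm) {
  d <- gm$calls
  storage.mode(d) <- "double"
  d
}

# Mean-impute missing dosages per marker (used only where a complete matrix
# is a computational requirement, never as a genotype call).
mean_impute <- function(d) {
  mu <- rowMeans(d, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 1]]
  d
}
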