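# Shared fixture builders. Everything is generated in code; no files.

# Genotype matrix from a plain integer matrix (NA = missing).
gm_from <- function(m, marker_prefix = "M", acc_prefix = "S") {
  rownames(m) <- paste0(marker_prefix, seq_len(nrow(m)))
  colnames(m) <- paste0(acc_prefix, seq_len(ncol(m)))
  genotype_matrix(m)
}

# Matching one-chromosome marker table at 1 kb spacing.
markers_for <- function(gm, chrom = "1A", spacing = 1000L,
                        category = "G") {
  marker_table(gm$marker_ids, chrom,
               seq_len(n_markers(gm)) * spacing,
               category = rep_len(category, n_markers(gm)))
}

# Random small genotype fixture with controlled missingness.
random_gm <- function(n_markers, n_acc, missing_rate = 0, seed = 1,
                      het_rate = 0.1) {
  set.seed(seed)
  p <- runif(n_markers, 0.1, 0.9)
  m <- matrix(rbinom(n_markers * n_acc, 2, rep(p, n_acc)),
              nrow = n_markers)
  het <- m == 1L & runif(length(m)) > het_rate
  m[het] <- 2L * rbinom(sum(het), 1, 0.5)
  if (missing_rate > 0) m[runif(length(m)) < missing_rate] <- NA_integer_
  gm_from(m)
}

# Small, fast simulation config (dense markers so the 1 Mb LD window has
# partners; translocation on 1B's proximal quarter).
small_sim <- function(seed = 1, n_acc = 60, n_markers = 240,
                      n_carriers = 12, carrier_rate = 0.9,
                      base_missing = 0.02, ld_rho = 0.9,
                      chromosomes = c("1A", "1B", "2A", "2B"),
                      chrom_length = 4e6, traits = NULL, ...) {
  sim_config(
    n_accessions = n_acc, n_markers = n_markers,
    chromosomes = chromosomes, chrom_length_bp = chrom_length,
    un_fraction = 0, ld_rho = ld_rho,
    base_missing_rate = base_missing,
    translocation = if (n_carriers >= 0) list(
      chrom = "1B", start = 1, end = chrom_length / 4,
      n_carriers = n_carriers, carrier_missing_rate = carrier_rate) else NULL,
    traits = traits %||% list(),
    rng_seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One quantitative trait spec with a single causal locus.
one_locus_trait <- function(effect = 1, h2 = 0.5, n_years = 3,
                            causal = "auto") {
  list(list(name = "trait1", type = "quantitative", causal = causal,
            n_causal = 1, effects = effect, h2 = h2, n_years = n_years,
            year_effects = seq_len(n_years) - 1))
}

# Naive O(n*m) substring occurrence counter (overlaps allowed).
naive_count <- function(fragment, sequences) {
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  count_in <- function(pat, s) {
    n <- nchar(s) - nchar(pat) + 1L
    if (n < 1L) return(0L)
    sum(vapply(seq_len(n), function(i)
      substr(s, i, i + nchar(pat) - 1L) == pat, logical(1)))
  }
  rc <- revcomp(fragment)
  tot <- sum(vapply(sequences, count_in, integer(1), pat = fragment))
  if (rc != fragment)
    tot <- tot + sum(vapply(sequences, count_in, integer(1), pat = rc))
  tot
}
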