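#' Per-marker call statistics
#'
#' Call rate (fraction of accessions genotyped), heterozygote rate among
#' called genotypes, and minor allele frequency among called genotypes
#' (`p = (2 * n_alt_hom + n_het) / (2 * n_called)`, `maf = min(p, 1 - p)`).
#' Markers with zero calls get call rate 0 and `NA` het/MAF.
#'
#' @param gm a [genotype_matrix()] with at least one accession
#' @return data.frame with `marker_id`, `call_rate`, `het_rate`, `maf`
#' @export
site_stats <- function(gm) {
  if (n_accessions(gm) < 1L) stop("need at least one accession")
  calls <- gm$calls
  n <- ncol(calls)
  called <- rowSums(!is.na(calls))
  n_het <- rowSums(calls == 1L, na.rm = TRUE)
  n_alt <- rowSums(calls == 2L, na.rm = TRUE)
  p <- (2 * n_alt + n_het) / (2 * called)
  data.frame(marker_id = gm$marker_ids,
             call_rate = called / n,
             het_rate = ifelse(called > 0, n_het / called, NA_real_),
             maf = ifelse(called > 0, pmin(p, 1 - p), NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Marker filter parameters
#'
#' Defaults follow the panel's published screening rules: a marker must be
#' genotyped in at least 90% of accessions (inclusive), be heterozygous in
#' no more than 10% of called accessions (inclusive; high apparent
#' heterozygosity in a selfing crop flags multi-locus read capture), and
#' have minor allele frequency strictly greater than 0.05.
#'
#' @param min_call_rate inclusive lower bound on call rate
#' @param max_het_rate inclusive upper bound on het rate
#' @param min_maf exclusive lower bound on MAF
#' @return a named list
#' @export
filter_params <- function(min_call_rate = 0.90, max_het_rate = 0.10,
                          min_maf = 0.05) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            max_het_rate >= 0, max_het_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  list(min_call_rate = min_call_rate, max_het_rate = max_het_rate,
       min_maf = min_maf)
}

#' Apply the three-stage marker filter cascade
#'
#' Stages are applied in order: call rate, then heterozygosity, then MAF.
#' Markers failing an earlier stage never reach a later one, so the
#' per-stage survivor counts form the panel's filtering funnel. Marker
#' order is preserved in the surviving matrix. Filtering precedes
#' imputation.
#'
#' @param gm a [genotype_matrix()]
#' @param markers the matching [marker_table()] (categories feed the funnel)
#' @param params a [filter_params()] list
#' @return list with `genotypes` (filtered), `markers` (filtered),
#'   `funnel` (per-category survival table from [panel_funnel_report()]),
#'   and `stats` (the [site_stats()] table with per-stage pass flags)
#' @export
apply_filter_cascade <- function(gm, markers, params = filter_params()) {
  stopifnot(identical(markers$id, gm$marker_ids))
  st <- site_stats(gm)
  pass_cr <- st$call_rate >= params$min_call_rate
  pass_het <- !is.na(st$het_rate) & st$het_rate <= params$max_het_rate
  pass_maf <- !is.na(st$maf) & st$maf > params$min_maf
  funnel <- panel_funnel_report(
    markers$category,
    list(call_rate = pass_cr, het = pass_het, maf = pass_maf))
  keep <- pass_cr & pass_het & pass_maf
  st$pass_call_rate <- pass_cr
  st$pass_het <- pass_cr & pass_het
  st$pass_maf <- keep
  list(genotypes = subset_genotypes(gm, markers = which(keep)),
       markers = markers[keep, , drop = FALSE],
       funnel = funnel, stats = st)
}
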