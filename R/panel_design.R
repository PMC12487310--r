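#' GC fraction of a nucleotide sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` bases are excluded from the
#' denominator. An all-N (or empty-after-N) sequence has no defined GC
#' content and returns `NA`.
#'
#' @param seq character vector of sequences over `{A,C,G,T,N}`
#'   (case-insensitive)
#' @return numeric vector of GC fractions in `[0, 1]` (`NA` where undefined)
#' @export
flank_gc_content <- function(seq) {
  if (any(nchar(seq) < 1L)) stop("sequences must have length >= 1")
  up <- toupper(seq)
  if (any(grepl("[^ACGTN]", up))) stop("alphabet must be {A,C,G,T,N}")
  counts <- function(ch) nchar(up) - nchar(gsub(ch, "", up, fixed = TRUE))
  gc <- counts("G") + counts("C")
  acgt <- gc + counts("A") + counts("T")
  ifelse(acgt == 0L, NA_real_, gc / acgt)
}

#' Count exact occurrences of a fragment in a reference
#'
#' Occurrences of the fragment and of its reverse complement across all
#' reference sequences, overlapping matches counted. At positions where the
#' forward and reverse-complement matches coincide (palindromic fragments)
#' the hit is counted once.
#'
#' @param fragment a single non-empty nucleotide string
#' @param reference a FASTA path, named character vector, or `DNAStringSet`
#' @return integer hit count
#' @export
count_exact_matches <- function(fragment, reference) {
  stopifnot(length(fragment) == 1L, nchar(fragment) >= 1L)
  ref <- as_reference(reference)
  pat <- Biostrings::DNAString(toupper(fragment))
  rc <- Biostrings::reverseComplement(pat)
  fwd <- sum(Biostrings::vcountPattern(pat, ref))
  if (as.character(rc) == as.character(pat)) return(fwd)
  fwd + sum(Biostrings::vcountPattern(rc, ref))
}

#' Flank uniqueness and GC report
#'
#' For each marker with a flank, counts exact matches of the full flank in
#' the reference (both strands) and records its GC content. A marker is
#' "unique" exactly when its flank occurs once — the requirement for a
#' locus-specific enrichment probe in a polyploid genome, where homoeologous
#' copies otherwise capture reads from several loci.
#'
#' @param markers a [marker_table()] with flanks
#' @param reference reference sequences (path, character vector or
#'   `DNAStringSet`)
#' @return data.frame with `marker_id`, `gc_fraction`, `n_exact_hits`,
#'   `unique`
#' @export
flank_report <- function(markers, reference) {
  has <- !is.na(markers$flank)
  ref <- as_reference(reference)
  hits <- vapply(markers$flank[has], count_exact_matches, integer(1),
                 reference = ref)
  data.frame(marker_id = markers$id[has],
             gc_fraction = flank_gc_content(markers$flank[has]),
             n_exact_hits = as.integer(hits),
             unique = hits == 1L,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Probe feasibility screen
#'
#' A marker is targetable when its flank is locus-specific (exactly one
#' exact match in the reference) and at least one of its probes has GC
#' content inside the acceptance band. Enrichment probes outside roughly
#' 30-70% GC hybridise poorly; multi-locus flanks cannot be targeted
#' specifically at all.
#'
#' @param flanks output of [flank_report()]
#' @param probes data.frame with `marker_id` and `gc_fraction` (one or two
#'   probes per marker); if `NULL`, the flank GC is used as the probe proxy
#' @param gc_min,gc_max GC acceptance band (defaults 0.30 and 0.70)
#' @return data.frame with `marker_id`, `feasible`, `reason`
#'   (`""`, `"multilocus"` or `"gc"`)
#' @export
probe_feasibility <- function(flanks, probes = NULL,
                              gc_min = 0.30, gc_max = 0.70) {
  stopifnot(gc_min >= 0, gc_max <= 1, gc_min < gc_max)
  if (is.null(probes))
    probes <- data.frame(marker_id = flanks$marker_id,
                         gc_fraction = flanks$gc_fraction)
  gc_ok <- vapply(flanks$marker_id, function(id) {
    g <- probes$gc_fraction[probes$marker_id == id]
    any(!is.na(g) & g >= gc_min & g <= gc_max)
  }, logical(1))
  reason <- ifelse(!flanks$unique, "multilocus", ifelse(!gc_ok, "gc", ""))
  data.frame(marker_id = flanks$marker_id,
             feasible = reason == "",
             reason = reason, row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-category survival funnel
#'
#' Tabulates how many markers of each panel selection category survive each
#' sequential screening stage, mirroring the design-to-final-panel funnel:
#' counts are cumulative (a marker counts at stage s only if it passed all
#' stages up to s), hence non-increasing left to right, with the percentage
#' of the initial panel retained at the last stage.
#'
#' @param categories character vector of categories (A-G), one per marker
#' @param stage_flags named list of logical pass vectors, one per stage, in
#'   filtering order
#' @return data.frame: one row per category plus a `Total` row; columns
#'   `initial`, one per stage, and `final_pct`
#' @export
panel_funnel_report <- function(categories, stage_flags) {
  if (!all(categories %in% c("A", "B", "C", "D", "G")))
    stop("unknown selection category")
  cats <- intersect(c("A", "B", "C", "D", "G"), unique(categories))
  n <- length(categories)
  stopifnot(all(vapply(stage_flags, length, 1L) == n))
  alive <- rep(TRUE, n)
  cols <- list(initial = rep(TRUE, n))
  for (s in names(stage_flags)) {
    alive <- alive & stage_flags[[s]]
    cols[[s]] <- alive
  }
  tab <- vapply(cols, function(flag) {
    c(vapply(cats, function(cc) sum(flag & categories == cc), integer(1)),
      Total = sum(flag))
  }, integer(length(cats) + 1L))
  if (!is.matrix(tab)) tab <- t(tab)     # single (Total-only) row
  out <- as.data.frame(tab)
  out <- cbind(category = c(cats, "Total"), out)
  out$final_pct <- ifelse(out$initial > 0,
                          100 * out[[ncol(out)]] / out$initial, 0)
  rownames(out) <- NULL
  out
}
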