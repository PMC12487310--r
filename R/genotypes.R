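#' Genotype matrix container
#'
#' A `genotype_matrix` stores biallelic dosage calls for a panel of markers
#' (rows) scored on a set of accessions (columns). Calls are coded
#' 0 = homozygous reference, 1 = heterozygous (for pooled inbred accessions:
#' within-accession heterogeneity), 2 = homozygous alternate, and `NA` for a
#' missing (no-call) genotype. No phasing is represented.
#'
#' @param calls integer (or coercible) matrix of dosages in `{0, 1, 2, NA}`,
#'   markers in rows and accessions in columns, with unique row and column
#'   names giving marker and accession identifiers.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls` (integer matrix), `marker_ids` and `accession_ids`.
#' @export
genotype_matrix <- function(calls) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  storage.mode(calls) <- "integer"
  ok <- is.na(calls) | calls %in% 0:2
  if (!all(ok)) stop("genotype calls must be 0, 1, 2 or NA")
  marker_ids <- rownames(calls)
  accession_ids <- colnames(calls)
  if (is.null(marker_ids)) {
    if (nrow(calls) > 0) stop("`calls` must carry marker row names")
    marker_ids <- character(0)
  }
  if (is.null(accession_ids)) {
    if (ncol(calls) > 0) stop("`calls` must carry accession column names")
    accession_ids <- character(0)
  }
  if (anyDuplicated(marker_ids)) stop("duplicate marker ids")
  if (anyDuplicated(accession_ids)) stop("duplicate accession ids")
  structure(
    list(calls = calls,
         marker_ids = marker_ids,
         accession_ids = accession_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d accessions (%.2f%% missing)\n",
              n_markers(x), n_accessions(x),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Number of markers in a genotype matrix
#' @param gm a [genotype_matrix()]
#' @return integer count
#' @export
n_markers <- function(gm) nrow(gm$calls)

#' Number of accessions in a genotype matrix
#' @param gm a [genotype_matrix()]
#' @return integer count
#' @export
n_accessions <- function(gm) ncol(gm$calls)

#' Subset a genotype matrix by markers and/or accessions
#'
#' @param gm a [genotype_matrix()]
#' @param markers marker ids or row indices (default: all)
#' @param accessions accession ids or column indices (default: all)
#' @return a [genotype_matrix()]
#' @export
subset_genotypes <- function(gm, markers = NULL, accessions = NULL) {
  calls <- gm$calls
  if (!is.null(markers)) calls <- calls[markers, , drop = FALSE]
  if (!is.null(accessions)) calls <- calls[, accessions, drop = FALSE]
  genotype_matrix(calls)
}

#' Marker metadata table
#'
#' Validates a marker record table: one row per marker with identifier,
#' chromosome, 1-based position, panel selection category, alleles and an
#' optional flanking sequence with the SNP base at its centre.
#'
#' Selection categories follow the panel-design tiers: A = derived from
#' marker-assisted-selection (KASP) assays, B = from prior array GWAS hits,
#' C = polymorphisms in GenBank-deposited genes, D = protein-changing
#' mutations, G = gap-filling high-polymorphism markers.
#'
#' @param id character marker ids (unique)
#' @param chrom chromosome names (free strings; "Un" = unplaced)
#' @param pos 1-based positions in bp
#' @param category selection category, one of `"A","B","C","D","G"`
#' @param ref,alt single-base alleles, `ref != alt`
#' @param flank optional odd-length flank sequence centred on the SNP
#'   (centre base must equal `ref`); `NA` where absent
#' @return a `data.frame` of class `marker_table`
#' @export
marker_table <- function(id, chrom, pos, category = "G",
                         ref = "A", alt = "G", flank = NA_character_) {
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   pos = as.integer(pos),
                   category = as.character(category),
                   ref = as.character(ref), alt = as.character(alt),
                   flank = as.character(flank),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate marker ids")
  if (any(df$pos < 1L)) stop("positions must be >= 1 (1-based)")
  if (!all(df$category %in% c("A", "B", "C", "D", "G")))
    stop("unknown selection category (expect A, B, C, D or G)")
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
  has_flank <- !is.na(df$flank)
  if (any(has_flank)) {
    fl <- df$flank[has_flank]
    if (any(nchar(fl) %% 2L == 0L)) stop("flanks must have odd length")
    centre <- substr(fl, (nchar(fl) + 1L) %/% 2L, (nchar(fl) + 1L) %/% 2L)
    if (any(centre != df$ref[has_flank]))
      stop("flank centre base must equal the reference allele")
  }
  class(df) <- c("marker_table", "data.frame")
  df
}

#' Phenotype observation table
#'
#' Long-format multi-year trait observations: one row per
#' (accession, trait, year).
#'
#' @param accession_id accession identifiers
#' @param trait trait names
#' @param year observation year (integer or label)
#' @param value numeric trait value (quantitative, ordinal score or 0/1)
#' @return a `data.frame` of class `trait_table`
#' @export
trait_table <- function(accession_id, trait, year, value) {
  df <- data.frame(accession_id = as.character(accession_id),
                   trait = as.character(trait),
                   year = as.character(year),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("accession_id", "trait", "year")]))
    stop("duplicate (accession, trait, year) observation")
  if (any(!is.finite(df$value))) stop("trait values must be finite")
  class(df) <- c("trait_table", "data.frame")
  df
}
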