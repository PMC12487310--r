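#' Read a genotype matrix from VCF
#'
#' Reads a VCF v4.x file of biallelic SNPs into the internal dosage coding:
#' `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`, `./. -> NA`. Phased
#' separators (`|`) are accepted and treated like unphased calls.
#' Multi-allelic records are dropped with a warning giving their count.
#' A `CAT=` INFO key, when present, is taken as the panel selection category.
#'
#' @param path path to a VCF file
#' @return a list with `genotypes` (a [genotype_matrix()]) and `markers`
#'   (a [marker_table()]); marker order is preserved from the file.
#' @export
read_genotype_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    samples <- colnames(vcf@gt)[-1]
    if (is.null(samples)) samples <- character(0)
    calls <- matrix(integer(0), nrow = 0, ncol = length(samples),
                    dimnames = list(character(0), samples))
    return(list(genotypes = structure(list(calls = calls,
                                           marker_ids = character(0),
                                           accession_ids = samples),
                                      class = "genotype_matrix"),
                markers = marker_table(character(0), character(0), integer(0),
                                       character(0), character(0),
                                       character(0), character(0))))
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE) |
    nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  if (any(multi)) {
    warning(sprintf("dropped %d multi-allelic/non-SNP record(s)", sum(multi)))
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  ids <- fix$ID
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix$CHROM[noid], "_", fix$POS[noid])
  if (anyDuplicated(ids)) stop("duplicate marker id in VCF")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  calls <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                  dimnames = list(ids, colnames(gt)))
  calls[gt %in% "0/0"] <- 0L
  calls[gt %in% c("0/1", "1/0")] <- 1L
  calls[gt %in% "1/1"] <- 2L
  bad <- !is.na(gt) & !gt %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
  if (any(bad))
    stop(sprintf("unparseable GT field(s), e.g. '%s' at marker %s",
                 gt[bad][1], ids[which(rowSums(bad) > 0)[1]]))
  cat_info <- sub(".*CAT=([A-G]).*", "\\1", fix$INFO)
  cat_info[!grepl("CAT=", fix$INFO)] <- "G"
  cat_info[is.na(cat_info)] <- "G"
  list(genotypes = genotype_matrix(calls),
       markers = marker_table(ids, fix$CHROM, as.integer(fix$POS),
                              cat_info, fix$REF, fix$ALT))
}

#' Write a genotype matrix to VCF v4.2
#'
#' Emits a plain-text VCF v4.2 file with one biallelic SNP record per marker.
#' Missing calls are written `./.`; records are sorted by chromosome and
#' position (with a message when the input order had to change). The panel
#' selection category is stored under the `CAT` INFO key so a write/read
#' cycle preserves it.
#'
#' @param gm a [genotype_matrix()] with at least one accession
#' @param markers a [marker_table()] covering exactly the markers of `gm`
#' @param path output file path
#' @return the path, invisibly
#' @export
write_genotype_vcf <- function(gm, markers, path) {
  if (n_accessions(gm) == 0L) stop("cannot write a VCF with 0 accessions")
  if (!setequal(markers$id, gm$marker_ids) ||
      length(markers$id) != length(gm$marker_ids))
    stop("marker table and genotype matrix ids do not match")
  markers <- markers[match(gm$marker_ids, markers$id), , drop = FALSE]
  ord <- order(markers$chrom, markers$pos)
  if (is.unsorted(ord)) message("records re-sorted by chromosome and position")
  markers <- markers[ord, , drop = FALSE]
  calls <- gm$calls[ord, , drop = FALSE]
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_code[calls + 1L], nrow = nrow(calls))
  gt[is.na(calls)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=panelgwas",
    "##INFO=<ID=CAT,Number=1,Type=String,Description=\"Panel selection category (A-G)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$accession_ids), collapse = "\t")
  )
  body <- paste(markers$chrom, markers$pos, markers$id, markers$ref,
                markers$alt, ".", "PASS", paste0("CAT=", markers$category),
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  if (nrow(markers) == 0L) body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write the simple genotype TSV dialect
#'
#' A fixture-friendly tab-separated layout: markers as rows, accessions as
#' columns, first column `marker_id`, cells in `{0, 1, 2, NA}`. VCF remains
#' the canonical interchange format.
#'
#' @param path file path
#' @return for the reader, a [genotype_matrix()]
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  genotype_matrix(m)
}

#' @rdname read_genotype_tsv
#' @param gm a [genotype_matrix()]
#' @export
write_genotype_tsv <- function(gm, path) {
  df <- data.frame(marker_id = gm$marker_ids, gm$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise a phylogenetic tree to Newick
#'
#' Writes an `ape::phylo` tree (with branch lengths) to a Newick string.
#' Tip labels containing whitespace are single-quoted so the output stays
#' parseable by standard readers.
#'
#' @param tree an `ape::phylo` object; branch lengths must be non-negative
#' @param digits significant digits for branch lengths
#' @return a single Newick string (terminated by `;`)
#' @export
write_tree_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths")
  lab <- tree$tip.label
  needs_quote <- grepl("\\s", lab)
  lab[needs_quote] <- paste0("'", lab[needs_quote], "'")
  ntip <- length(lab)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_len <- function(e) {
    if (is.null(tree$edge.length)) "" else
      paste0(":", format(tree$edge.length[e], digits = digits,
                         scientific = FALSE, trim = TRUE))
  }
  recurse <- function(node) {
    kid_edges <- children[[as.character(node)]]
    parts <- vapply(kid_edges, function(e) {
      child <- tree$edge[e, 2]
      sub <- if (child <= ntip) lab[child] else recurse(child)
      paste0(sub, fmt_len(e))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- ntip + 1L
  paste0(recurse(root), ";")
}

#' Read a reference as a DNAStringSet
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] so the panel-design
#' screens take either a path or an in-memory sequence set.
#'
#' @param x a FASTA path, a named character vector of sequences, or a
#'   `DNAStringSet`
#' @return a `Biostrings::DNAStringSet`
#' @export
as_reference <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  Biostrings::DNAStringSet(x)
}
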