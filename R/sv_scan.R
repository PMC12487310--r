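#' Per-marker missingness profile
#'
#' Fraction of accessions with a missing call at each marker, ordered by
#' chromosome and position. A contiguous run of elevated missingness on one
#' chromosome arm is the panel's footprint of a deletion or alien
#' translocation (the probes have no target to enrich in carriers).
#'
#' @param gm a [genotype_matrix()]
#' @param markers the matching [marker_table()]
#' @return data.frame `marker_id`, `chrom`, `pos`, `missing_fraction`,
#'   sorted by (chrom, pos)
#' @export
missingness_profile <- function(gm, markers) {
  stopifnot(identical(markers$id, gm$marker_ids))
  frac <- rowMeans(is.na(gm$calls))
  out <- data.frame(marker_id = markers$id, chrom = markers$chrom,
                    pos = markers$pos, missing_fraction = frac,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

# Markers inside an inclusive window; bounds may be marker ids or bp.
window_markers <- function(markers, chrom, start, end) {
  to_bp <- function(x) {
    if (is.character(x) && x %in% markers$id) markers$pos[markers$id == x]
    else as.numeric(x)
  }
  lo <- to_bp(start); hi <- to_bp(end)
  if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
  which(markers$chrom == chrom & markers$pos >= lo & markers$pos <= hi)
}

#' Automatic carrier/non-carrier thresholds from window missing counts
#'
#' Finds the two largest gaps in the sorted per-accession missing-count
#' distribution — the automatic analogue of reading the trimodal histogram
#' by eye. The widest gap separates non-carriers from the rest; when a
#' second distinctly wide gap exists above it, the counts between the two
#' gaps are left as "intermediate". A distribution without any clear gap
#' (all counts within 1 of each other) classifies everyone as non-carrier.
#'
#' Returned thresholds are used as: count < `t_low` -> non-carrier,
#' count > `t_high` -> carrier, otherwise intermediate.
#'
#' @param counts integer vector of per-accession missing counts in a window
#' @param min_gap smallest count gap treated as a mode separation (default 2)
#' @return list(t_low, t_high)
#' @export
auto_thresholds <- function(counts, min_gap = 2) {
  stopifnot(length(counts) >= 2)
  u <- sort(unique(counts))
  if (length(u) == 1L) return(list(t_low = u + 1, t_high = u))
  gaps <- diff(u)
  if (max(gaps) < min_gap) {
    m <- max(counts)
    return(list(t_low = m + 1, t_high = m))   # unimodal: all non-carrier
  }
  ord <- order(gaps, decreasing = TRUE)
  g1 <- ord[1]
  # a second gap counts only if comparably wide (>= half the largest)
  g2 <- if (length(ord) > 1 && gaps[ord[2]] >= min_gap &&
            gaps[ord[2]] >= gaps[g1] / 2) ord[2] else NA
  if (is.na(g2)) {
    list(t_low = u[g1] + 1, t_high = u[g1 + 1] - 1)
  } else {
    lo <- min(g1, g2); hi <- max(g1, g2)
    list(t_low = u[lo] + 1, t_high = u[hi + 1] - 1)
  }
}

#' Classify accessions as translocation carriers from window missingness
#'
#' Counts missing calls per accession over the markers inside an inclusive
#' window (given by marker ids or bp bounds) and classifies: count >
#' `t_high` -> carrier, count < `t_low` -> non-carrier, otherwise
#' intermediate. Thresholds may be supplied (to reproduce a published
#' split) or derived by [auto_thresholds()].
#'
#' @param gm a [genotype_matrix()]
#' @param markers the matching [marker_table()]
#' @param chrom window chromosome
#' @param start,end window bounds: marker ids or bp positions (inclusive)
#' @param t_low,t_high optional manual thresholds (`t_low <= t_high + 1`)
#' @return data.frame `accession_id`, `missing_count`, `class`, plus
#'   attributes `t_low`, `t_high`, `n_window_markers`
#' @export
classify_carriers <- function(gm, markers, chrom, start, end,
                              t_low = NULL, t_high = NULL) {
  idx <- window_markers(markers, chrom, start, end)
  if (length(idx) == 0L) stop("window contains no markers")
  counts <- colSums(is.na(gm$calls[idx, , drop = FALSE]))
  if (is.null(t_low) || is.null(t_high)) {
    th <- auto_thresholds(counts)
    t_low <- th$t_low; t_high <- th$t_high
  }
  if (t_low > t_high + 1) stop("t_low must be <= t_high + 1")
  cls <- ifelse(counts > t_high, "carrier",
                ifelse(counts < t_low, "non_carrier", "intermediate"))
  out <- data.frame(accession_id = gm$accession_ids,
                    missing_count = as.integer(counts),
                    class = cls, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "t_low") <- t_low
  attr(out, "t_high") <- t_high
  attr(out, "n_window_markers") <- length(idx)
  out
}

#' Agreement between carrier calls and validation labels
#'
#' Compares carrier/non-carrier calls against external validation labels
#' (e.g. a diagnostic PCR marker), excluding intermediates. Reports the 2x2
#' confusion table and simple agreement.
#'
#' @param calls output of [classify_carriers()]
#' @param labels data.frame with `accession_id` and `carrier` (logical or
#'   "carrier"/"non_carrier")
#' @return list(`table` 2x2 matrix, `agreement`, `n_intermediate`)
#' @export
concordance <- function(calls, labels) {
  if (is.character(labels$carrier))
    labels$carrier <- labels$carrier == "carrier"
  m <- merge(calls, labels, by = "accession_id")
  if (nrow(m) == 0L) stop("no shared accession ids between calls and labels")
  n_int <- sum(m$class == "intermediate")
  m <- m[m$class != "intermediate", , drop = FALSE]
  if (nrow(m) == 0L) stop("no non-intermediate overlapping accessions")
  pred <- m$class == "carrier"
  tab <- matrix(c(sum(pred & m$carrier), sum(pred & !m$carrier),
                  sum(!pred & m$carrier), sum(!pred & !m$carrier)),
                nrow = 2, byrow = TRUE,
                dimnames = list(predicted = c("carrier", "non_carrier"),
                                validated = c("carrier", "non_carrier")))
  list(table = tab,
       agreement = (tab[1, 1] + tab[2, 2]) / sum(tab),
       n_intermediate = n_int)
}

#' Genome-wide missingness window scan
#'
#' Slides over each chromosome's markers in fixed-size marker windows and
#' reports, per window, how many accessions exceed a carrier-like
#' missingness level, flagging candidate deletion/translocation regions.
#'
#' @param gm a [genotype_matrix()]
#' @param markers the matching [marker_table()]
#' @param window_size markers per window (default 20)
#' @param min_fraction per-accession fraction of the window that must be
#'   missing to count as carrier-like (default 0.5)
#' @param min_accessions accessions over `min_fraction` needed to flag a
#'   window (default 5)
#' @return data.frame of windows: `chrom`, `start`, `end`, `n_markers`,
#'   `n_flagged_accessions`, `flagged`
#' @export
scan_missingness_windows <- function(gm, markers, window_size = 20,
                                     min_fraction = 0.5, min_accessions = 5) {
  stopifnot(identical(markers$id, gm$marker_ids))
  res <- list()
  for (ch in setdiff(unique(markers$chrom), "Un")) {
    idx <- which(markers$chrom == ch)
    idx <- idx[order(markers$pos[idx])]
    starts <- seq(1L, length(idx), by = window_size)
    for (st in starts) {
      w <- idx[st:min(st + window_size - 1L, length(idx))]
      miss <- colMeans(is.na(gm$calls[w, , drop = FALSE]))
      n_flag <- sum(miss >= min_fraction)
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, start = min(markers$pos[w]), end = max(markers$pos[w]),
        n_markers = length(w), n_flagged_accessions = n_flag,
        flagged = n_flag >= min_accessions, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
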