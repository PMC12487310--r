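#' Multi-year BLUEs per accession and trait
#'
#' Two-way fixed-effects adjustment `value ~ accession + year` with
#' sum-to-zero year coding; the BLUE of an accession is its fixed-effect
#' estimate (intercept plus accession effect), i.e. its value adjusted to
#' the average year. Balanced data reduce to the per-accession mean across
#' years; single-year traits pass through unchanged. Accessions with no
#' observations for a trait are absent from its output.
#'
#' @param traits a [trait_table()]
#' @return data.frame `accession_id`, `trait`, `blue`
#' @export
compute_blues <- function(traits) {
  out <- lapply(split(traits, traits$trait), function(df) {
    acc <- factor(df$accession_id)
    if (length(unique(df$year)) == 1L) {
      blue <- tapply(df$value, acc, mean)
    } else {
      yr <- factor(df$year)
      fit <- stats::lm(value ~ 0 + acc + yr, data = df,
                       contrasts = list(yr = stats::contr.sum))
      blue <- stats::coef(fit)[paste0("acc", levels(acc))]
    }
    data.frame(accession_id = levels(acc), trait = df$trait[1],
               blue = as.numeric(blue), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mixed-model specification for association mapping
#'
#' @param n_pcs number of genotype principal components used as fixed
#'   covariates (default 10)
#' @param mode `"P3D"` (variance components estimated once under the null
#'   model and reused per marker; the common fast configuration) or
#'   `"per_marker"` (re-estimated for every marker)
#' @param alpha nominal significance level before multiple-test correction
#' @return a named list
#' @export
mlm_spec <- function(n_pcs = 10, mode = c("P3D", "per_marker"),
                     alpha = 0.05) {
  stopifnot(n_pcs >= 0)
  list(n_pcs = n_pcs, mode = match.arg(mode), alpha = alpha)
}

# REML profile criterion for lambda = s2_g / s2_e on the rotated model.
# yr, Xr: eigen-rotated response/design; d: kinship eigenvalues.
reml_neg2ll <- function(log_lambda, yr, Xr, d) {
  lambda <- exp(log_lambda)
  v <- lambda * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xr, Xr * w)
  beta <- solve(XtWX, crossprod(Xr, yr * w))
  r <- yr - Xr %*% beta
  rss <- sum(w * r^2)
  n <- length(yr); p <- ncol(Xr)
  (n - p) * log(rss) + sum(log(v)) + determinant(XtWX)$modulus[1]
}

#' Mixed-linear-model marker-trait association scan
#'
#' Fits `y = mu + PCs g + marker b + u + e` with `u ~ N(0, s2_g K)` for the
#' centered-IBS kinship `K` and `e ~ N(0, s2_e I)`. Variance components are
#' estimated by REML on the spectral decomposition of `K` (so each
#' candidate ratio costs only a reweighted least squares); in P3D mode they
#' are estimated once under the null and reused for every marker. Each
#' marker is tested with an F-test on its effect (`df = n - rank(design)`).
#' Markers collinear with the covariates (including constant markers) are
#' flagged and given `p = 1`. Records are sorted by chromosome and
#' position.
#'
#' @param gm a [genotype_matrix()] without missing calls
#' @param markers the matching [marker_table()]
#' @param y named numeric vector of phenotypes (BLUEs), names = accession
#'   ids; must cover the accessions of `gm`
#' @param kinship accession x accession kinship (default: centered IBS of
#'   `gm`); a zero matrix reduces the model to ordinary least squares
#' @param spec an [mlm_spec()]
#' @param covariates optional extra fixed covariates (n x q matrix, rows in
#'   accession order), e.g. a candidate locus dosage for conditional
#'   analysis
#' @return data.frame of class `association_table`: `marker_id`, `chrom`,
#'   `pos`, `effect`, `f_stat`, `p_value`, `neg_log10_p`, `flagged`; the
#'   fitted null-model `lambda` is attached as an attribute
#' @export
mlm_association <- function(gm, markers, y, kinship = NULL,
                            spec = mlm_spec(), covariates = NULL) {
  if (anyNA(gm$calls)) stop("genotypes contain missing calls; impute first")
  stopifnot(identical(markers$id, gm$marker_ids))
  acc <- gm$accession_ids
  if (!all(acc %in% names(y))) stop("phenotype missing for some accessions")
  y <- as.numeric(y[acc])
  n <- length(acc)
  if (is.null(kinship)) kinship <- centered_ibs_kinship(gm)
  X0 <- matrix(1, n, 1)
  if (spec$n_pcs > 0) {
    pcs <- pca_genotypes(gm, spec$n_pcs)$scores
    X0 <- cbind(X0, pcs)
  }
  if (!is.null(covariates)) X0 <- cbind(X0, covariates)
  eig <- eigen(kinship, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yr <- crossprod(U, y)
  X0r <- crossprod(U, X0)
  G <- dosages(gm)
  Gr <- crossprod(U, t(G))               # n x M rotated marker dosages
  fit_lambda <- function(Xr) {
    if (sum(d) < 1e-12) return(0)     # zero kinship: pure OLS
    opt <- stats::optimize(reml_neg2ll, interval = c(-10, 10),
                           yr = yr, Xr = Xr, d = d)
    exp(opt$minimum)
  }
  lambda0 <- fit_lambda(X0r)
  p0 <- ncol(X0)
  M <- n_markers(gm)
  eff <- fst <- pv <- rep(NA_real_, M)
  flagged <- rep(FALSE, M)
  for (m in seq_len(M)) {
    Xr <- cbind(X0r, Gr[, m])
    qrX <- qr(cbind(X0, G[m, ]))
    if (qrX$rank <= p0) {             # marker collinear with covariates
      flagged[m] <- TRUE; pv[m] <- 1; eff[m] <- 0; fst[m] <- 0
      next
    }
    lambda <- if (spec$mode == "P3D") lambda0 else fit_lambda(Xr)
    w <- 1 / (lambda * d + 1)
    XtWX <- crossprod(Xr, Xr * w)
    XtWy <- crossprod(Xr, yr * w)
    beta <- solve(XtWX, XtWy)
    r <- yr - Xr %*% beta
    df <- n - qrX$rank
    s2 <- sum(w * r^2) / df
    se2 <- s2 * solve(XtWX)[p0 + 1, p0 + 1]
    eff[m] <- beta[p0 + 1]
    fst[m] <- beta[p0 + 1]^2 / se2
    pv[m] <- stats::pf(fst[m], 1, df, lower.tail = FALSE)
  }
  out <- data.frame(marker_id = markers$id, chrom = markers$chrom,
                    pos = markers$pos, effect = eff, f_stat = fst,
                    p_value = pv, neg_log10_p = -log10(pv),
                    flagged = flagged, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lambda") <- lambda0
  class(out) <- c("association_table", "data.frame")
  out
}

#' SimpleM effective number of independent tests
#'
#' Per chromosome, the marker-marker dosage correlation matrix is
#' eigen-decomposed and the chromosome's effective test count is the
#' smallest number of leading eigenvalues whose sum reaches the cutoff
#' fraction (default 99.5%) of the eigenvalue total; the genome-wide Meff
#' is the sum over chromosomes. Zero-variance markers are dropped with a
#' message before the correlation.
#'
#' @param gm a [genotype_matrix()] without missing calls
#' @param markers the matching [marker_table()] (chromosome blocks)
#' @param cutoff eigenvalue-sum fraction (default 0.995)
#' @return integer Meff with per-chromosome counts as an attribute
#' @export
simplem_meff <- function(gm, markers, cutoff = 0.995) {
  if (anyNA(gm$calls)) stop("genotypes contain missing calls; impute first")
  stopifnot(identical(markers$id, gm$marker_ids))
  d <- dosages(gm)
  varz <- apply(d, 1, stats::var)
  if (any(varz == 0)) {
    message(sprintf("dropped %d zero-variance marker(s)", sum(varz == 0)))
    d <- d[varz > 0, , drop = FALSE]
    markers <- markers[varz > 0, , drop = FALSE]
  }
  if (nrow(d) < 2) stop("need at least two polymorphic markers")
  per_chrom <- vapply(unique(markers$chrom), function(ch) {
    block <- d[markers$chrom == ch, , drop = FALSE]
    if (nrow(block) == 1L) return(1L)
    ev <- eigen(stats::cor(t(block)), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    as.integer(which(cumsum(ev) / sum(ev) >= cutoff)[1])
  }, integer(1))
  structure(sum(per_chrom), per_chrom = per_chrom)
}

#' Bonferroni threshold from an effective test count
#'
#' @param meff effective number of independent tests (>= 1)
#' @param alpha_nominal nominal level (default 0.05)
#' @return corrected per-test alpha
#' @export
bonferroni_threshold <- function(meff, alpha_nominal = 0.05) {
  stopifnot(meff >= 1)
  alpha_nominal / as.numeric(meff)
}

#' Per-category MTA enrichment with pairwise Fisher tests
#'
#' For each panel selection category: marker count, number of markers with
#' at least one significant marker-trait association, and the proportion;
#' then all pairwise two-sided Fisher exact tests on the 2x2
#' significant-vs-not tables, with compact homogeneous-group letters at the
#' given level. Empty categories are excluded with a message.
#'
#' @param marker_ids marker identifiers
#' @param categories selection category per marker
#' @param significant logical: does the marker have >= 1 significant MTA
#' @param alpha level for the group letters (default 0.05)
#' @return list with `table` (per-category counts, proportion, group
#'   letters) and `pairwise` (category pair, p-value)
#' @export
mta_category_enrichment <- function(marker_ids, categories, significant,
                                    alpha = 0.05) {
  stopifnot(length(categories) == length(significant))
  cats <- intersect(c("A", "B", "C", "D", "G"), unique(categories))
  empty <- setdiff(c("A", "B", "C", "D", "G"), cats)
  tab <- data.frame(
    category = cats,
    n_markers = vapply(cats, function(cc) sum(categories == cc), integer(1)),
    n_significant = vapply(cats, function(cc)
      sum(significant & categories == cc), integer(1)),
    stringsAsFactors = FALSE)
  tab$proportion <- tab$n_significant / tab$n_markers
  pairs <- utils::combn(cats, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    m <- matrix(c(tab$n_significant[tab$category == pr[1]],
                  tab$n_markers[tab$category == pr[1]] -
                    tab$n_significant[tab$category == pr[1]],
                  tab$n_significant[tab$category == pr[2]],
                  tab$n_markers[tab$category == pr[2]] -
                    tab$n_significant[tab$category == pr[2]]),
                nrow = 2, byrow = TRUE)
    data.frame(cat1 = pr[1], cat2 = pr[2],
               p_value = stats::fisher.test(m)$p.value,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pw)) pw <- data.frame(cat1 = character(0), cat2 = character(0),
                                    p_value = numeric(0))
  tab$group <- cld_letters(cats, pw, alpha)
  list(table = tab, pairwise = pw)
}

# Compact letter display: maximal runs of categories (sorted by proportion)
# whose members are all pairwise non-significant share a letter.
cld_letters <- function(cats, pairwise, alpha) {
  if (length(cats) == 1L) return("a")
  nonsig <- function(a, b) {
    if (a == b) return(TRUE)
    hit <- (pairwise$cat1 == a & pairwise$cat2 == b) |
      (pairwise$cat1 == b & pairwise$cat2 == a)
    pairwise$p_value[hit] >= alpha
  }
  groups <- list()
  for (i in seq_along(cats)) {
    g <- cats[i]
    for (j in seq_along(cats)[-seq_len(i)]) {
      if (all(vapply(g, nonsig, logical(1), b = cats[j]))) g <- c(g, cats[j])
    }
    covered <- any(vapply(groups, function(gg) all(g %in% gg), logical(1)))
    if (!covered) groups[[length(groups) + 1L]] <- g
  }
  letters_out <- rep("", length(cats))
  for (gi in seq_along(groups)) {
    idx <- cats %in% groups[[gi]]
    letters_out[idx] <- paste0(letters_out[idx], letters[gi])
  }
  letters_out
}

#' QQ-plot table of expected vs observed p-values
#'
#' Sorted observed p-values against uniform quantiles `(i - 0.5) / M`, on
#' the `-log10` scale, ready for plotting.
#'
#' @param p_values numeric vector of p-values (length >= 1)
#' @return data.frame `expected`, `observed` (-log10 scale), sorted
#' @export
qq_table <- function(p_values) {
  stopifnot(length(p_values) >= 1)
  p <- sort(p_values)
  M <- length(p)
  data.frame(expected = -log10((seq_len(M) - 0.5) / M),
             observed = -log10(p))
}
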