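#' Simulation configuration for a synthetic SNP-panel study
#'
#' Builds the parameter set for the synthetic-data generator. Defaults
#' emulate the study design the package targets: 200 winter-wheat accessions
#' from two admixed subpopulations genotyped at ~3.5 thousand polymorphic
#' biallelic markers over 21 nuclear chromosomes (1A..7D) plus an unplaced
#' "Un" bin, with low residual heterozygosity, a background no-call rate,
#' and a carrier subset bearing a contiguous high-missingness block on the
#' short arm of chromosome 1B (the footprint of a 1RS.1BL-type alien
#' translocation). Three-year quantitative traits carry one to three
#' major-effect loci over a polygenic background; one binary trait (awns)
#' is included.
#'
#' @param n_accessions number of accessions (default 200)
#' @param n_markers number of polymorphic markers (default 3500)
#' @param chromosomes chromosome names (default 1A..7D)
#' @param chrom_length_bp chromosome length in bp (default 6e8, wheat scale)
#' @param un_fraction fraction of markers assigned to the unplaced "Un" bin
#' @param K_true number of ancestral subpopulations (default 2)
#' @param divergence Balding-Nichols Fst-like divergence of subpopulation
#'   allele frequencies from the ancestral frequency (default 0.15)
#' @param admixture_fraction fraction of accessions with mixed ancestry
#' @param het_rate target residual heterozygote rate (default 0.02;
#'   selfing crop)
#' @param base_missing_rate background no-call rate (default 0.02)
#' @param ld_rho correlation of adjacent-marker haplotype alleles within a
#'   chromosome (AR(1) latent copula; 0 = linkage equilibrium). The real
#'   panel's LD decay is unknown, so this is a free parameter, not an
#'   emulation claim.
#' @param ld_block_size optional haplotype-block LD: consecutive markers on
#'   a chromosome in blocks of this size share one latent haplotype draw,
#'   giving near-perfect within-block LD (used for imputation experiments);
#'   `NULL` (default) uses the AR(1) decay of `ld_rho` instead
#' @param distal_clustering place markers with density increasing toward
#'   chromosome ends (Beta(0.4, 0.4) positions), mimicking gene-rich distal
#'   regions; `FALSE` gives uniform placement
#' @param category_props proportions of panel selection categories A-G,
#'   matching the composition of the called 16.5K-scale set
#' @param flank_length odd length of the SNP-centred flank (default 101)
#' @param duplicate_fraction fraction of flanks duplicated elsewhere in the
#'   toy reference (homoeologue mimic, default 0.10)
#' @param gc_range range of per-region GC content in the toy reference
#' @param ref_chromosomes,ref_chrom_length_bp toy-reference layout for the
#'   panel-design stage; `NULL` length auto-sizes to hold all flanks
#' @param translocation list(chrom, start, end, n_carriers,
#'   carrier_missing_rate) for the injected high-missingness block
#' @param traits list of trait specifications; see [simulate_traits()]
#' @param rng_seed root seed; each generator stage uses its own child stream
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_accessions = 200,
                       n_markers = 3500,
                       chromosomes = paste0(rep(1:7, each = 3), c("A", "B", "D")),
                       chrom_length_bp = 6e8,
                       un_fraction = 0.01,
                       K_true = 2,
                       divergence = 0.15,
                       admixture_fraction = 0.15,
                       het_rate = 0.02,
                       base_missing_rate = 0.02,
                       ld_rho = 0.5,
                       ld_block_size = NULL,
                       distal_clustering = TRUE,
                       category_props = c(A = 0.0035, B = 0.0703, C = 0.0634,
                                          D = 0.5624, G = 0.3004),
                       flank_length = 101,
                       duplicate_fraction = 0.10,
                       gc_range = c(0.25, 0.75),
                       ref_chromosomes = 6,
                       ref_chrom_length_bp = NULL,
                       translocation = list(chrom = "1B", start = 1,
                                            end = 1.5e8, n_carriers = 39,
                                            carrier_missing_rate = 0.9),
                       traits = default_trait_specs(),
                       rng_seed = 1) {
  cfg <- as.list(environment())
  rates <- c(admixture_fraction, het_rate, base_missing_rate, un_fraction,
             duplicate_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (K_true < 1) stop("K_true must be >= 1")
  if (divergence < 0 || divergence >= 1) stop("divergence must be in [0, 1)")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (!is.null(translocation) &&
      translocation$n_carriers > n_accessions)
    stop("n_carriers exceeds n_accessions")
  if (flank_length %% 2 == 0) stop("flank_length must be odd")
  cfg$category_props <- category_props / sum(category_props)
  class(cfg) <- "sim_config"
  cfg
}

#' Default trait specifications for the synthetic panel
#'
#' Three-year quantitative traits with major-effect loci over a polygenic
#' background (heading date: two loci; plant height: one strong locus,
#' emulating Rht/Ppd-scale effects) and one binary presence/absence trait
#' (awns) controlled by a single locus.
#'
#' @return a list of trait spec lists
#' @export
default_trait_specs <- function() {
  list(
    list(name = "heading_days", type = "quantitative",
         causal = "auto", n_causal = 2, effects = c(0.8, 0.5),
         h2 = 0.7, n_years = 3, year_effects = c(0, 2.5, -1.5)),
    list(name = "plant_height", type = "quantitative",
         causal = "auto", n_causal = 1, effects = 1.0,
         h2 = 0.8, n_years = 3, year_effects = c(0, -3, 1)),
    list(name = "awns", type = "binary",
         causal = "auto", n_causal = 1, effects = 3.0,
         h2 = 0.9, n_years = 1, year_effects = 0, prevalence = 0.3)
  )
}

# Marker ids in the panel's IABxxxxx style.
iab_ids <- function(n) sprintf("IAB%05d", seq_len(n))

#' Simulate the marker map
#'
#' Assigns markers to chromosomes, draws 1-based positions (distally
#' clustered by default), panel categories and alleles. Rows are sorted by
#' chromosome then position; ids keep the sorted order.
#'
#' @param config a [sim_config()]
#' @return a [marker_table()] without flanks
#' @export
simulate_markers <- function(config) {
  with_seed(child_seed(config$rng_seed, 1), {
    n <- config$n_markers
    n_un <- round(config$un_fraction * n)
    chrom <- c(sample(rep(config$chromosomes,
                          length.out = n - n_un)),
               rep("Un", n_un))
    u <- if (config$distal_clustering) stats::rbeta(n, 0.4, 0.4)
         else stats::runif(n)
    pos <- pmax(1L, pmin(config$chrom_length_bp,
                         as.integer(round(u * config$chrom_length_bp))))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    cat <- sample(names(config$category_props), n, replace = TRUE,
                  prob = config$category_props)
    ord <- order(chrom != "Un", chrom, pos, method = "radix",
                 decreasing = c(TRUE, FALSE, FALSE))
    # resolve position ties within a chromosome so the map is strictly ordered
    df <- data.frame(chrom = chrom[ord], pos = pos[ord], ref = ref[ord],
                     alt = alt[ord], category = cat[ord],
                     stringsAsFactors = FALSE)
    dup <- duplicated(df[c("chrom", "pos")])
    while (any(dup)) {
      df$pos[dup] <- df$pos[dup] + 1L
      df <- df[order(df$chrom == "Un", df$chrom, df$pos), ]
      dup <- duplicated(df[c("chrom", "pos")])
    }
    marker_table(iab_ids(nrow(df)), df$chrom, df$pos, df$category,
                 df$ref, df$alt)
  })
}

#' Simulate a toy reference with SNP-centred flanks
#'
#' Builds small reference chromosomes out of flank-sized blocks whose GC
#' content is drawn from `gc_range`, places each candidate marker at the
#' centre of its own block (so every flank occurs verbatim in the
#' reference), and copies a deterministic fraction of flanks to a second
#' location to mimic homoeologous duplication in a polyploid genome.
#'
#' @param config a [sim_config()]
#' @param markers optional [marker_table()]; defaults to
#'   [simulate_markers()] output (categories/ids are reused; toy-reference
#'   coordinates are internal to the reference)
#' @return list with `reference` (named character vector of sequences),
#'   `markers` (marker table with flanks filled in), and `duplicated_ids`
#' @export
simulate_reference <- function(config, markers = NULL) {
  if (is.null(markers)) markers <- simulate_markers(config)
  fl <- config$flank_length
  n <- nrow(markers)
  n_chrom <- config$ref_chromosomes
  len <- config$ref_chrom_length_bp
  if (is.null(len)) len <- ceiling(2.2 * n * fl / n_chrom)
  if (len < fl) stop("reference chromosome shorter than the flank length")
  slots_per_chrom <- len %/% fl
  n_slots <- slots_per_chrom * n_chrom
  n_dup <- round(config$duplicate_fraction * n)
  if (n + n_dup > n_slots)
    stop("more markers (plus duplicates) than available reference positions")
  with_seed(child_seed(config$rng_seed, 2), {
    gc <- stats::runif(n_slots, config$gc_range[1], config$gc_range[2])
    blocks <- vapply(gc, function(g) {
      paste(sample(c("G", "C", "A", "T"), fl, replace = TRUE,
                   prob = c(g / 2, g / 2, (1 - g) / 2, (1 - g) / 2)),
            collapse = "")
    }, character(1))
    slot_of <- sample(n_slots, n + n_dup)       # marker slots then dup slots
    marker_slot <- slot_of[seq_len(n)]
    dup_slot <- slot_of[n + seq_len(n_dup)]
    dup_ids <- if (n_dup > 0) sort(sample(markers$id, n_dup)) else character(0)
    centre <- (fl + 1L) %/% 2L
    for (i in seq_len(n)) {                     # force centre base = ref
      b <- blocks[marker_slot[i]]
      substr(b, centre, centre) <- markers$ref[i]
      blocks[marker_slot[i]] <- b
    }
    markers$flank <- blocks[marker_slot]
    if (n_dup > 0)
      blocks[dup_slot] <- markers$flank[match(dup_ids, markers$id)]
    chrom_of_slot <- rep(seq_len(n_chrom), each = slots_per_chrom)
    reference <- vapply(seq_len(n_chrom), function(k) {
      paste(blocks[chrom_of_slot == k], collapse = "")
    }, character(1))
    names(reference) <- paste0("ref_chr", seq_len(n_chrom))
    list(reference = reference, markers = markers, duplicated_ids = dup_ids)
  })
}

#' Simulate an admixed panel of genotypes
#'
#' Correlated-allele-frequency admixture model: ancestral frequencies are
#' Uniform(0.05, 0.95); each subpopulation's frequency is a Balding-Nichols
#' Beta draw around the ancestral value with the configured divergence;
#' each accession draws two haplotypes whose alleles come from
#' ancestry-weighted subpopulation frequencies, with optional AR(1) latent
#' correlation along chromosomes (`ld_rho`) to create block LD. The
#' heterozygote rate is capped to `het_rate` by collapsing excess
#' heterozygotes to a random one of their two alleles, and background
#' missingness is applied uniformly at random.
#'
#' @param config a [sim_config()]
#' @param markers optional precomputed [simulate_markers()] table
#' @return list with `genotypes` (a [genotype_matrix()]), `markers`, and
#'   `truth` (subpopulation labels, ancestry matrix `Q`, subpopulation
#'   frequencies `P`, carrier/causal slots filled by later stages)
#' @export
simulate_population <- function(config, markers = NULL) {
  if (is.null(markers)) markers <- simulate_markers(config)
  M <- nrow(markers)
  n <- config$n_accessions
  K <- config$K_true
  with_seed(child_seed(config$rng_seed, 3), {
    p_anc <- stats::runif(M, 0.05, 0.95)
    F <- config$divergence
    P <- if (F > 0) {
      a <- p_anc * (1 - F) / F
      b <- (1 - p_anc) * (1 - F) / F
      matrix(stats::rbeta(M * K, rep(a, K), rep(b, K)), nrow = M)
    } else matrix(rep(p_anc, K), nrow = M)
    P <- pmin(pmax(P, 1e-4), 1 - 1e-4)

    Q <- matrix(0, n, K)
    if (K == 1) Q[, 1] <- 1 else {
      pure_pop <- sample(K, n, replace = TRUE)
      Q[cbind(seq_len(n), pure_pop)] <- 1
      adm <- stats::runif(n) < config$admixture_fraction
      for (i in which(adm)) {
        w <- stats::runif(K, 0.2, 0.8)
        Q[i, ] <- w / sum(w)
      }
    }

    qnP <- stats::qnorm(P)
    chrom_f <- factor(markers$chrom, levels = unique(markers$chrom))
    rho <- config$ld_rho
    block_size <- config$ld_block_size
    hap <- function(qi) {
      src <- sample.int(K, M, replace = TRUE, prob = qi)
      z <- stats::rnorm(M)
      if (!is.null(block_size)) {
        for (ch in levels(chrom_f)) {      # one latent draw per block
          idx <- which(chrom_f == ch)
          blk <- ceiling(seq_along(idx) / block_size)
          z[idx] <- z[idx][match(blk, blk)]
        }
      } else if (rho > 0) {
        for (ch in levels(chrom_f)) {
          idx <- which(chrom_f == ch)
          if (length(idx) > 1) {
            zz <- z[idx]
            for (m in 2:length(zz)) zz[m] <- rho * zz[m - 1] +
                sqrt(1 - rho^2) * zz[m]
            z[idx] <- zz
          }
        }
      }
      as.integer(z < qnP[cbind(seq_len(M), src)])
    }
    calls <- matrix(0L, M, n,
                    dimnames = list(markers$id, sprintf("acc%03d", seq_len(n))))
    for (i in seq_len(n)) calls[, i] <- hap(Q[i, ]) + hap(Q[i, ])

    # cap residual heterozygosity (selfing crop): keep a het call with a
    # probability proportional to het_rate / E[het], else collapse it to a
    # random one of its alleles. The proportionality constant is calibrated
    # so the expected genome-wide het rate equals het_rate even where some
    # cells have low expected heterozygosity.
    f <- P %*% t(Q)                              # M x n expected alt freq
    eh <- 2 * f * (1 - f)
    target <- config$het_rate
    if (mean(eh) > target) {
      g <- function(cc) mean(pmin(cc * target, eh)) - target
      cc <- stats::uniroot(g, c(1, 1 / target + 1))$root
    } else cc <- Inf
    het <- which(calls == 1L)
    keep <- stats::runif(length(het)) < pmin(1, cc * target / eh[het])
    calls[het[!keep]] <- 2L * stats::rbinom(sum(!keep), 1L, 0.5)

    if (config$base_missing_rate > 0) {
      miss <- stats::runif(length(calls)) < config$base_missing_rate
      calls[miss] <- NA_integer_
    }
    truth <- list(subpop = max.col(Q), Q = Q, P = P,
                  accession_ids = colnames(calls),
                  carriers = character(0), causal = list())
    list(genotypes = genotype_matrix(calls), markers = markers, truth = truth)
  })
}

#' Inject a translocation-like high-missingness block
#'
#' Marks a set of carrier accessions and sets their calls inside the given
#' chromosome-arm interval to missing, each independently with the carrier
#' missing rate — the genotyping footprint of an alien chromosome-arm
#' substitution (e.g. 1RS.1BL) where panel probes have no target to enrich.
#' Non-carriers are untouched.
#'
#' @param gm a [genotype_matrix()]
#' @param markers the matching [marker_table()]
#' @param spec list(chrom, start, end, n_carriers, carrier_missing_rate)
#' @param truth truth list to record carrier ids into
#' @param seed RNG seed for carrier choice and per-call masking
#' @return list(genotypes, truth) with carriers recorded
#' @export
inject_translocation_missingness <- function(gm, markers, spec, truth,
                                             seed = 1) {
  in_win <- markers$chrom == spec$chrom &
    markers$pos >= spec$start & markers$pos <= spec$end
  if (!any(in_win)) {
    warning("no markers inside the translocation interval; nothing injected")
    return(list(genotypes = gm, truth = truth))
  }
  if (spec$n_carriers == 0)
    return(list(genotypes = gm, truth = truth))
  with_seed(seed, {
    carriers <- sort(sample(gm$accession_ids, spec$n_carriers))
    calls <- gm$calls
    block <- calls[in_win, carriers, drop = FALSE]
    block[stats::runif(length(block)) < spec$carrier_missing_rate] <- NA_integer_
    calls[in_win, carriers] <- block
    truth$carriers <- carriers
    list(genotypes = genotype_matrix(calls), truth = truth)
  })
}

#' Simulate multi-year phenotypes over the panel
#'
#' Generative model per trait: `y_iy = mu + sum_l beta_l * x_il + u_i +
#' year_y + e_iy`, with standardized causal dosages `x`, a polygenic term
#' `u ~ MVN(0, s2_poly * K)` using the centered-IBS kinship of the panel,
#' additive year effects, and iid noise scaled so the single-observation
#' heritability hits its target given the realized genetic variance.
#' Effect sizes are in trait-SD units. Binary traits are generated by
#' thresholding the liability at the configured prevalence. Missing causal
#' dosages are mean-filled for trait generation only; a causal marker with
#' no calls at all is an error.
#'
#' @param gm a [genotype_matrix()]
#' @param markers the matching [marker_table()]
#' @param truth truth list (causal choices are recorded into it)
#' @param trait_specs list of trait specs (see [default_trait_specs()]);
#'   each spec may give `causal` marker ids or `"auto"` with `n_causal`
#' @param seed RNG seed
#' @return list(`traits` = [trait_table()], `truth`)
#' @export
simulate_traits <- function(gm, markers, truth, trait_specs, seed = 1) {
  d <- dosages(gm)
  n <- n_accessions(gm)
  Kmat <- centered_ibs_kinship_dosage(mean_impute(d))
  cholK <- chol(Kmat + diag(1e-6, n))
  rows <- list()
  with_seed(seed, {
    maf_ok <- {
      p <- rowMeans(d, na.rm = TRUE) / 2
      which(pmin(p, 1 - p) >= 0.2 & markers$chrom != "Un")
    }
    for (spec in trait_specs) {
      h2 <- spec$h2
      if (h2 < 0 || h2 > 1) stop("heritability must be in [0, 1]")
      n_causal <- if (identical(spec$causal, "auto")) spec$n_causal
                  else length(spec$causal)
      causal_ids <- character(0)
      g <- numeric(n)
      if (n_causal > 0) {
        causal_ids <- if (identical(spec$causal, "auto"))
          markers$id[sort(sample(maf_ok, n_causal))] else spec$causal
        xs <- d[causal_ids, , drop = FALSE]
        if (any(rowSums(!is.na(xs)) == 0))
          stop("causal marker entirely missing")
        xs <- mean_impute(xs)
        xs <- t(scale(t(xs)))
        xs[is.nan(xs)] <- 0
        g <- as.numeric(crossprod(xs, spec$effects))
      }
      if (h2 > 0) {
        var_major <- stats::var(g)
        s2_poly <- max(h2 - var_major, 0.05 * h2)
        g <- g + sqrt(s2_poly) * as.numeric(crossprod(cholK, stats::rnorm(n)))
      }
      var_g <- stats::var(g)
      var_e <- if (h2 > 0) var_g * (1 - h2) / h2 else 1
      if (var_g == 0 && h2 > 0) var_e <- 1
      truth$causal[[spec$name]] <- list(ids = causal_ids,
                                        effects = spec$effects,
                                        genetic_values = g)
      if (identical(spec$type, "binary")) {
        liab <- g + stats::rnorm(n, 0, sqrt(var_e))
        thr <- stats::quantile(liab, 1 - (spec$prevalence %||% 0.3))
        rows[[spec$name]] <- data.frame(
          accession_id = gm$accession_ids, trait = spec$name, year = "1",
          value = as.numeric(liab > thr), stringsAsFactors = FALSE)
      } else {
        yrs <- seq_len(spec$n_years)
        ye <- rep(spec$year_effects, length.out = spec$n_years)
        out <- do.call(rbind, lapply(yrs, function(y) {
          data.frame(accession_id = gm$accession_ids, trait = spec$name,
                     year = as.character(2018L + y),
                     value = g + ye[y] + stats::rnorm(n, 0, sqrt(var_e)),
                     stringsAsFactors = FALSE)
        }))
        rows[[spec$name]] <- out
      }
    }
  })
  df <- do.call(rbind, rows)
  list(traits = trait_table(df$accession_id, df$trait, df$year, df$value),
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete panel study
#'
#' One call producing everything the downstream stages consume: marker map,
#' genotypes with injected translocation missingness, multi-year traits,
#' toy reference with flanks, and the ground-truth record.
#'
#' @param config a [sim_config()]
#' @param reference also build the toy reference/flanks (default TRUE)
#' @return list(genotypes, markers, traits, truth, reference,
#'   duplicated_ids)
#' @export
simulate_panel <- function(config = sim_config(), reference = TRUE) {
  pop <- simulate_population(config)
  gm <- pop$genotypes; markers <- pop$markers; truth <- pop$truth
  if (!is.null(config$translocation)) {
    tr <- inject_translocation_missingness(
      gm, markers, config$translocation, truth,
      seed = child_seed(config$rng_seed, 4))
    gm <- tr$genotypes; truth <- tr$truth
  }
  traits <- NULL
  if (length(config$traits)) {
    st <- simulate_traits(gm, markers, truth, config$traits,
                          seed = child_seed(config$rng_seed, 5))
    traits <- st$traits; truth <- st$truth
  }
  ref <- NULL; dup_ids <- character(0)
  if (reference) {
    r <- simulate_reference(config, markers)
    ref <- r$reference; markers <- r$markers; dup_ids <- r$duplicated_ids
  }
  list(genotypes = gm, markers = markers, traits = traits, truth = truth,
       reference = ref, duplicated_ids = dup_ids)
}
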