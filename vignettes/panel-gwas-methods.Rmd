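---
title: "Methods: panel QC, imputation, translocation scanning and mixed-model GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel QC, imputation, translocation scanning and mixed-model GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind each stage of `panelgwas`, the
parameters that matter, the numerical conventions, and what the
synthetic-data generator does and does not emulate.

## Genotype model

Calls are unphased dosages 0/1/2 with an explicit missing state. In an
inbred, largely selfing crop a heterozygous call usually reflects
*heterogeneity* — either residual segregation inside a pooled accession or
reads captured from several homoeologous loci — so the single state 1
carries no phase information and high per-marker heterozygosity is treated
as a technical failure signal rather than biology. Coordinates are 1-based
and follow VCF throughout; chromosome names are free strings, and the
unplaced bin `"Un"` is excluded from every position-dependent scan
(imputation windows, translocation windows, genome scans).

## Panel-design screens

A candidate SNP is targetable when a locus-specific enrichment probe can
be designed for it. Two screens approximate this desk-side:

* **Uniqueness.** `count_exact_matches()` counts occurrences of the full
  SNP-centred flank (both strands, overlaps allowed; a palindromic match
  position is counted once) in the reference. One hit = specific; more =
  a homoeologous copy would capture reads too. Using the full flank as
  the exact query keeps the screen deterministic and aligner-free; with a
  real genome one would take the longest exact match of an aligner
  instead, which this operation is the toy analogue of. Whether such hits
  should be strand-collapsed is a convention, not a fact about the assay;
  we count both strands and de-duplicate palindromic positions.
* **GC band.** Probes hybridise reliably only in a window around balanced
  base composition. `probe_feasibility()` uses an acceptance band of
  [0.30, 0.70] GC by default — the range within which enrichment works,
  aiming at 0.50. The tighter empirical band [0.33, 0.70] observed in
  successful panels is *reported* by the analysis scripts, not enforced.
  GC is `(#G + #C) / (#A + #C + #G + #T)` with `N` dropped from the
  denominator; an all-N sequence has undefined GC (`NA`).

`panel_funnel_report()` tabulates survivors per selection category after
each sequential stage; counts are cumulative, hence non-increasing.

## Filter cascade

`apply_filter_cascade()` applies, in order: call rate ≥ `0.90`
(inclusive), heterozygosity among called genotypes ≤ `0.10` (inclusive),
MAF > `0.05` (strict). The inclusive/strict readings follow the usual
phrasing of these rules ("90% or more", "no more than 10%", "greater than
0.05"). Het and MAF use called genotypes only. Filtering precedes
imputation: imputed genotypes never feed the filters, and the MAF rule is
therefore a pre-imputation quantity (the alternative is not
distinguishable from published descriptions; we fix this one).

## LD-kNNi imputation

For a missing call at site *s*, accession *i*:

1. candidate LD partners are same-chromosome sites within
   `max_distance_bp` (default 10⁶ bp) of *s*; the `l = 30` with highest
   squared Pearson correlation to *s* (pairwise-complete accessions;
   zero-variance pairs score 0) are kept;
2. the distance from *i* to every accession *j* called at *s* is the mean
   squared dosage difference over the shared-called subset of those `l`
   sites (no overlap → *j* is skipped). The source method's exact
   treatment of missing pairs in this distance is not fully specified in
   its description; the shared-called mean is our declared choice;
3. the `k = 10` nearest neighbours vote for their genotype at *s* with
   weight 1/d², d floored at ε = 10⁻⁸ so identical neighbours dominate
   rather than divide by zero;
4. ties break toward the more frequent genotype at *s*, then the lower
   dosage — fully deterministic.

When no LD partner or no scored neighbour exists (isolated markers,
unplaced markers), the fallback imputes the site mode (or leaves the call
missing, by option). Observed calls are never altered.

## Translocation scanning

Carriers of an alien-arm substitution lose probe targets across the whole
arm, so their missing calls cluster in a contiguous window. The scan works
on **raw missing counts** per accession over the window (mirroring how
such distributions are inspected), on the *unfiltered* matrix — the
call-rate filter removes exactly the markers carrying the signal.
`auto_thresholds()` is the automatic analogue of reading the histogram by
eye: it finds the largest gap in the sorted counts (and a second gap when
comparably wide, at least half the largest and ≥ `min_gap` = 2), placing
thresholds strictly inside the gap(s); counts between two gaps become
"intermediate". A distribution with no gap ≥ `min_gap` classifies everyone
as non-carrier. Manual thresholds are accepted to reproduce a published
split exactly. Windows are inclusive at both ends and may be given as
marker ids or bp. `concordance()` validates calls against an external
assay's labels, excluding intermediates from the 2×2 table.

## Population structure

* **Kinship**: `K = WᵀW / c`, `W` the dosage matrix with per-marker means
  removed, `c = Σₘ 2pₘ(1 − pₘ)`; symmetric PSD by construction. Requires
  a complete matrix (run after imputation).
* **IBS distance**: `d(i,j) = mean(|xᵢ − xⱼ|) / 2` over markers called in
  both — 0 for identical calls, 0.5 for one shared allele, 1 for opposite
  homozygotes. Pairs with no overlap are undefined (`NA`) and rejected by
  the tree builder.
* **PCA**: eigen-decomposition of the covariance of centred (not
  variance-scaled) dosages; each component's sign is fixed by making its
  largest-magnitude loading positive so scores are platform-reproducible.
* **NJ tree**: Saitou–Nei agglomeration via `ape::nj`; negative branch
  lengths (non-additive inputs) are clamped to zero with the deficit
  moved to the sister edge(s) so path lengths through the node are
  preserved; midpoint rooting is the default. Additive matrices are
  reproduced exactly.

### Admixture model and ΔK

Population assignment uses the binomial admixture likelihood
`Σ x log(qᵀp) + (2 − x) log(1 − qᵀp)` maximised by EM, with one replicate
per seed from random Dirichlet/uniform starts. This is a deliberate design
choice: a Bayesian MCMC implementation of the same model family would be
slow, non-deterministic per seed, and needs burn-in judgement; the ML-EM
replicates play exactly the role of replicate MCMC runs in the Evanno
statistic, which consumes only replicate log-likelihoods
(`ΔK = mean_r |L_r(K+1) − 2L_r(K) + L_r(K−1)| / sd_r(L(K))`, replicates
paired by index, interior K only, undefined when `sd = 0` — e.g. at the
closed-form K = 1 optimum). Treating the 0/1/2 dosage as a Binomial(2)
observation is an approximation under the heterogeneity reading of state
1; it is shared by all dosage-based structure methods. EM is monotone; we
stop when the increment drops below `tol` (default 10⁻⁴; the pipeline's
structure stage uses 0.5, which on a log-likelihood scale of 10⁵ changes
replicate likelihoods far less than the between-K differences ΔK reads).
Ancestry inference saturates well below the full panel size, so the
pipeline thins the panel to at most 1,000 markers (deterministic, evenly
spaced) for the replicate fits — K = 1..5 with 10 replicates completes in
a few minutes at 200 accessions.

## GWAS

* **BLUEs**: fixed-effects fit `value ~ accession + year` with
  sum-to-zero year coding; balanced data reduce to per-accession means,
  single-year traits pass through.
* **MLM**: `y = μ + PCs·γ + x·β + u + e`, `u ~ N(0, σ²g K)`,
  `e ~ N(0, σ²e I)`, with 10 genotype PCs by default. The variance ratio
  λ = σ²g/σ²e is profiled by REML on the spectral decomposition of `K`,
  so each candidate λ costs one reweighted least squares; in the default
  P3D mode λ is estimated once under the null and reused for every marker
  (the common fast configuration; per-marker REML by option). The marker
  F-test uses `df = n − rank(fixed design)`, no small-sample adjustment.
  Markers collinear with the covariates — constants, or a locus passed as
  a conditioning covariate — are flagged with `p = 1`. A zero kinship
  reduces everything to OLS exactly.
* **SimpleM**: per chromosome, eigenvalues of the marker–marker dosage
  correlation matrix; the chromosome's effective test count is the
  smallest number of leading eigenvalues reaching 99.5% of the eigenvalue
  sum (the method's published default cutoff; computed blockwise per
  chromosome, which bounds memory and matches how LD is structured);
  genome Meff is the sum, and the working threshold is `α / Meff`.
* **Enrichment**: per selection category, the share of markers with at
  least one significant MTA; pairwise two-sided Fisher exact tests with
  compact letters at α = 0.05. Binary and ordinal scores are analysed
  with the same linear MLM — a documented simplification; p-values for a
  0/1 trait are approximate.

## What the generator emulates — and what it does not

`sim_config()` defaults are the study conditions the package targets: 200
accessions, 3,500 polymorphic biallelic markers on 21 chromosomes plus
`"Un"` (1% of markers), two subpopulations at Balding–Nichols divergence
0.15 with 15% admixed accessions, residual heterozygosity 0.02,
background no-call rate 0.02, and a translocation block on 1B bp 1–1.5·10⁸
carried by 39 accessions at 90% missingness. Marker positions are drawn
Beta(0.4, 0.4) along the chromosome so density rises toward the distal,
gene-rich ends; category proportions follow the composition of a called
16.5K-scale panel. Traits: three-year heading date (two loci, h² = 0.7),
plant height (one strong locus, h² = 0.8), and binary awns (liability
threshold at 30% prevalence). Heritability is calibrated against the
*realized* genetic variance, so the single-observation h² hits its target
up to Monte-Carlo error; the heterozygote cap is likewise calibrated
(uniroot on the keep-probability constant) so the realized genome-wide het
rate matches the config.

Linkage disequilibrium is a free parameter, not an emulation claim — the
real panel's LD decay is unknown. Two modes exist: an AR(1) latent copula
along each chromosome (`ld_rho`, default 0.5) and an explicit
haplotype-block mode (`ld_block_size`) in which consecutive markers share
one latent draw. Imputation experiments use blocks of 30 markers, matching
the imputation method's `l = 30` LD sites, so the method is evaluated
under the assumption it encodes.

Not emulated: recombination/coalescent genealogy (markers are
exchangeable given ancestry and the latent copula), genotyping error
(missingness is the only error mode), ascertainment bias of the marker
panel beyond the category labels, inbreeding depression or dominance in
traits, genotype-by-year interaction (year effects are additive), and any
LD between the translocation block and phenotypes. Passing tests on this
generator therefore demonstrate correctness of the algorithms under the
stated generative model, not performance on any particular real panel.

All generators flow from one root seed through fixed child streams
(`child_seed()`), so each stage can be re-run independently and every
pipeline output is byte-reproducible for a given seed.

## Problem sizes and test design

The test suite exercises each operation on small fixtures with
independent oracles (naive substring scans, normal-equations solves,
dense eigensolvers, hypergeometric enumeration, topology enumeration with
least-squares branch fitting) and runs the recovery experiments at
reduced scale — 50–200 accessions and 80–300 markers, 10–50 seeds per
property — sizes chosen so the whole suite runs in a few minutes while
keeping Monte-Carlo error well inside the asserted bounds. The
acceptance script runs the full 200 × 3,500 study scale end to end.

## Known limitations

* The MLM treats BLUEs as homoskedastic observations; unbalanced designs
  with very different per-accession replication would call for weighted
  analysis.
* The admixture EM finds local optima; replicates mitigate but do not
  eliminate this (the ΔK statistic actually relies on replicate spread).
* LD-kNNi accuracy degrades toward the site mode when the 1 Mb window
  holds few markers, as on sparse genome-scale maps; the fallback count
  is reported so this is visible.
* `auto_thresholds()` assumes the carrier and non-carrier count modes are
  separated by a gap at least `min_gap` wide; overlapping modes require
  manual thresholds.
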