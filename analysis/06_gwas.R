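#!/usr/bin/env Rscript
# Stage 6: mixed-model GWAS.
#
# Three-year BLUEs per trait; MLM with 10 genotype PCs and centered-IBS
# kinship (P3D variance components); SimpleM effective number of tests for
# the Bonferroni level; per-category MTA enrichment with Fisher exact
# tests.

library(panelgwas)

dat <- "results/data"
inp <- read_genotype_vcf(file.path(dat, "imputed.vcf"))
gm <- inp$genotypes; markers <- inp$markers
tr <- read.delim(file.path(dat, "traits.tsv"))
traits <- trait_table(tr$accession_id, tr$trait, tr$year, tr$value)
truth <- read.delim(file.path(dat, "truth.tsv"))

blues <- compute_blues(traits)
write.table(blues, "results/blues.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

meff <- simplem_meff(gm, markers)
alpha <- bonferroni_threshold(meff)
message(sprintf("SimpleM: Meff = %d of %d markers -> corrected alpha = %.3g",
                as.integer(meff), n_markers(gm), alpha))

kin <- centered_ibs_kinship(gm)
assoc <- NULL
for (t in unique(blues$trait)) {
  b <- blues[blues$trait == t, ]
  y <- setNames(b$blue, b$accession_id)
  a <- mlm_association(gm, markers, y, kinship = kin, spec = mlm_spec())
  a$trait <- t
  a$significant <- a$p_value < alpha
  write.table(qq_table(a$p_value), sprintf("results/qq_%s.tsv", t),
              sep = "\t", quote = FALSE, row.names = FALSE)
  top <- a[which.min(a$p_value), ]
  message(sprintf("%-14s top hit %s (%s:%d)  p = %.2e  %s", t,
                  top$marker_id, top$chrom, top$pos, top$p_value,
                  ifelse(top$significant, "significant", "ns")))
  assoc <- rbind(assoc, a)
}
write.table(assoc, "results/associations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("%d significant MTAs in total", sum(assoc$significant)))

sig_any <- tapply(assoc$significant, assoc$marker_id, any)
enr <- mta_category_enrichment(markers$id, markers$category,
                               as.logical(sig_any[markers$id]))
write.table(enr$table, "results/mta_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(enr$table)
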