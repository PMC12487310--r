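#!/usr/bin/env Rscript
# Stage 3: marker filter cascade and LD-kNNi imputation.
#
# Filters: call rate >= 90%, heterozygosity <= 10%, MAF > 0.05, applied in
# that order; the per-category survival funnel mirrors the panel's
# published filtering table. Missing calls in the surviving matrix are
# imputed with LD-kNNi (30 LD sites, 10 neighbours, 1 Mb window).

library(panelgwas)

dat <- "results/data"
inp <- read_genotype_vcf(file.path(dat, "genotypes.vcf"))

res <- apply_filter_cascade(inp$genotypes, inp$markers)
write.table(res$funnel, "results/funnel.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("cascade: %d -> %d markers (call rate -> het -> MAF)",
                n_markers(inp$genotypes), n_markers(res$genotypes)))
print(res$funnel)

imp <- impute_ld_knni(res$genotypes, res$markers)
message(sprintf("imputed %d missing calls (%d via site-mode fallback)",
                sum(is.na(res$genotypes$calls)), imp$n_fallback))
write_genotype_vcf(imp$genotypes, res$markers,
                   file.path(dat, "imputed.vcf"))
message("wrote results/funnel.tsv and results/data/imputed.vcf")
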