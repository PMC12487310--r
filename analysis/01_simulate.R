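#!/usr/bin/env Rscript
# Stage 1: generate the synthetic panel study.
#
# Emulates the target study design: 200 winter-wheat accessions from two
# admixed subpopulations, ~3.5 K polymorphic SNP-seq markers over 21 + 1
# chromosomes with distal clustering, 39 carriers of a 1RS.1BL-like
# translocation (contiguous high missingness on 1BS), three-year
# quantitative traits with major loci, and one binary trait. Everything
# downstream reads the files written here.

library(panelgwas)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(rng_seed = 42)
sim <- simulate_panel(cfg)

write_genotype_vcf(sim$genotypes, sim$markers, file.path(out, "genotypes.vcf"))
write.table(sim$markers, file.path(out, "markers.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$traits, file.path(out, "traits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(accession_id = sim$truth$accession_ids,
                       subpop = sim$truth$subpop,
                       carrier = sim$truth$accession_ids %in%
                         sim$truth$carriers),
            file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(paste0(">", names(sim$reference), "\n", sim$reference),
           file.path(out, "reference.fasta"))

message(sprintf("simulated %d markers x %d accessions (%.2f%% missing)",
                n_markers(sim$genotypes), n_accessions(sim$genotypes),
                100 * mean(is.na(sim$genotypes$calls))))
message(sprintf("injected %d translocation carriers on %s:%d-%d",
                length(sim$truth$carriers), cfg$translocation$chrom,
                cfg$translocation$start, cfg$translocation$end))
message(sprintf("traits: %s", paste(unique(sim$traits$trait), collapse = ", ")))
message("wrote genotypes.vcf, markers.tsv, traits.tsv, truth.tsv, reference.fasta")
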