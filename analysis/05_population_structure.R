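#!/usr/bin/env Rscript
# Stage 5: population structure on the filtered + imputed panel.
#
# Centered-IBS kinship, genotype PCA, neighbor-joining tree on the IBS
# distance matrix (midpoint-rooted), and admixture EM replicates over
# K = 1..5 with Evanno delta-K model selection.

library(panelgwas)

dat <- "results/data"
inp <- read_genotype_vcf(file.path(dat, "imputed.vcf"))
gm <- inp$genotypes
truth <- read.delim(file.path(dat, "truth.tsv"))

K <- centered_ibs_kinship(gm)
pca <- pca_genotypes(gm, 10)
write.table(data.frame(accession_id = rownames(pca$scores), pca$scores),
            "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("PC1 %.1f%%, PC2 %.1f%%; first 10 PCs cover %.1f%% of variance",
                100 * pca$variance_fraction[1], 100 * pca$variance_fraction[2],
                100 * sum(pca$variance_fraction)))

tree <- neighbor_joining(ibs_distance(gm))
writeLines(write_tree_newick(tree), "results/nj_tree.nwk")

# thin to 1,000 markers for the EM replicates (ancestry inference
# saturates well below the full panel)
thin <- unique(round(seq(1, n_markers(gm), length.out = 1000)))
gm_s <- subset_genotypes(gm, markers = thin)
reps <- admixture_replicates(gm_s, k_range = 1:5, n_replicates = 10,
                             seed = 42, max_iter = 150, tol = 0.5)
ev <- evanno_delta_k(reps)
write.table(ev, "results/evanno.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(ev)
kb <- best_k(ev)
message(sprintf("delta-K selects K = %d", kb))

fits <- Filter(function(r) r$K == kb, reps)
fit <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
Q <- align_q_to_labels(fit$Q, truth$subpop)
write.table(data.frame(accession_id = gm$accession_ids, Q),
            "results/q_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("subpopulation assignment agrees with truth for %.1f%% of accessions",
                100 * mean(max.col(Q) == truth$subpop)))
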