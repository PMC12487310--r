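#!/usr/bin/env Rscript
# Stage 2: panel-design quality screens.
#
# For every candidate marker: GC content of the SNP-centred flank, exact
# uniqueness of the flank in the toy reference (homoeologous duplicates
# cannot be targeted by a locus-specific probe), and probe feasibility
# under the 30-70% GC acceptance band.

library(panelgwas)

dat <- "results/data"
stopifnot(file.exists(file.path(dat, "markers.tsv")))
markers <- read.delim(file.path(dat, "markers.tsv"))
reference <- as_reference(file.path(dat, "reference.fasta"))

fr <- flank_report(markers, reference)
feas <- probe_feasibility(fr)
report <- merge(fr, feas, by = "marker_id")
write.table(report, "results/panel_design.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("%d candidate flanks screened", nrow(report)))
message(sprintf("multi-locus flanks: %d (%.1f%%)", sum(!report$unique),
                100 * mean(!report$unique)))
message(sprintf("feasible probes: %d (%.1f%%)", sum(report$feasible),
                100 * mean(report$feasible)))
gc_ok <- report$gc_fraction[report$feasible]
message(sprintf("feasible-set flank GC: mean %.2f, %.1f%% inside [0.33, 0.70]",
                mean(gc_ok), 100 * mean(gc_ok >= 0.33 & gc_ok <= 0.70)))
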