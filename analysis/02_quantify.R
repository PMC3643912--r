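#!/usr/bin/env Rscript

# RPKM quantification and per-library summary of the simulated libraries:
# genes detected (>= 1 mapped read) and genes at RPKM >= 1 and >= 5.

suppressPackageStartupMessages(library(segdig))

counts <- read_counts("results/data/counts.tsv")
genes <- read_gene_lengths("results/data/gene_lengths.tsv")
libraries <- read_library_metadata("results/data/library_metadata.tsv")

rpkm <- compute_rpkm(counts, genes, libraries)
summary_tab <- library_summary(rpkm, counts, thresholds = c(1, 5))

segdig:::write_tsv(cbind(data.frame(gene_id = rownames(rpkm)),
                         as.data.frame(rpkm)), "results/rpkm.tsv")
segdig:::write_tsv(summary_tab, "results/library_summary.tsv")

cat("per-library summary (detected / RPKM>=1 / RPKM>=5):\n")
print(summary_tab, row.names = FALSE)
cat("wrote results/rpkm.tsv and results/library_summary.tsv\n")
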