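#!/usr/bin/env Rscript

# Exact two-library differential-expression tests, one XX-vs-XY comparison
# per stage, with per-stage Benjamini-Hochberg FDR adjustment.

suppressPackageStartupMessages(library(segdig))

counts <- read_counts("results/data/counts.tsv")
genes <- read_gene_lengths("results/data/gene_lengths.tsv")
libraries <- read_library_metadata("results/data/library_metadata.tsv")
rpkm <- compute_rpkm(counts, genes, libraries)

for (s in unique(libraries$stage)) {
  tt <- test_stage(counts, rpkm, libraries, s)
  out <- sprintf("results/test_%sdah.tsv", s)
  segdig:::write_tsv(tt, out)
  cat(sprintf("stage %s dah: %d genes tested, %d with q <= 1e-2 (%s)\n",
              s, nrow(tt), sum(tt$q_value <= 1e-2), out))
}
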