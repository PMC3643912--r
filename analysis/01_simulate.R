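#!/usr/bin/env Rscript

# Generate the synthetic two-sex stage-course dataset that stands in for the
# eight gonad libraries (XX/XY at 5, 30, 90, 180 dah) and write it as TSV
# fixtures with ground truth. Downstream scripts read only these files.

suppressPackageStartupMessages(library(segdig))

seed <- as.integer(Sys.getenv("SEGDIG_SEED", "1"))
cfg <- simulation_config(n_genes = 21000, seed = seed)
cat(sprintf("simulating %d genes x %d libraries (seed %d)\n",
            cfg$n_genes, length(cfg$library_sizes), seed))

dataset <- generate_dataset(cfg)
paths <- write_dataset(dataset, "results/data")

cat("planted class sizes at 5 dah:\n")
print(table(dataset$truth$labels[, 1]))
cat("wrote:\n")
cat(paste(" ", paths, collapse = "\n"), "\n")
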