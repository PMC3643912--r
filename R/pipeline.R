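#' Pipeline run configuration
#'
#' Bundles input paths and analysis thresholds for [run_pipeline()]. Either a
#' gene-length TSV or a GFF3 annotation supplies gene lengths.
#'
#' @param counts Path to the counts TSV (see [read_counts()]).
#' @param library_metadata Path to the library metadata TSV.
#' @param gene_lengths Path to a gene-length TSV, or `NULL` if `gff3` given.
#' @param gff3 Path to a GFF3 annotation, or `NULL` if `gene_lengths` given.
#' @param out_dir Output directory; created if needed.
#' @param fdr_threshold,log2_threshold Dual-criterion bounds; defaults 1e-2
#'   and 1.
#' @param min_count Detection threshold; default 1.
#' @param rpkm_summary_cutoffs RPKM cutoffs for the library summary; default
#'   `c(1, 5)`.
#' @param groups Two group labels; first plays the "XX" role in ratios.
#' @param anchor_stage Anchor stage for enhanced-gene selection; default the
#'   first stage in the metadata.
#' @param min_other_stages Enhanced-gene requirement beyond the anchor;
#'   default 2.
#' @param fdr_method `"BH"` or `"BY"`.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(counts, library_metadata, gene_lengths = NULL,
                       gff3 = NULL, out_dir = "segdig_out",
                       fdr_threshold = 1e-2, log2_threshold = 1,
                       min_count = 1, rpkm_summary_cutoffs = c(1, 5),
                       groups = c("XX", "XY"), anchor_stage = NULL,
                       min_other_stages = 2, fdr_method = "BH") {
  if (is.null(gene_lengths) == is.null(gff3))
    stop("supply exactly one of gene_lengths or gff3")
  if (fdr_threshold <= 0 || log2_threshold <= 0)
    stop("thresholds must be positive")
  structure(list(counts = counts, library_metadata = library_metadata,
                 gene_lengths = gene_lengths, gff3 = gff3, out_dir = out_dir,
                 fdr_threshold = fdr_threshold,
                 log2_threshold = log2_threshold, min_count = min_count,
                 rpkm_summary_cutoffs = rpkm_summary_cutoffs, groups = groups,
                 anchor_stage = anchor_stage,
                 min_other_stages = min_other_stages,
                 fdr_method = fdr_method),
            class = "run_config")
}

#' Run the full classification pipeline
#'
#' Reads the inputs, computes RPKM, runs the per-stage exact tests with FDR
#' control, classifies every gene at every stage, derives the cross-stage
#' sets, and writes all result tables plus a run log to the output directory.
#' Re-running with identical inputs reproduces identical outputs (the
#' pipeline itself draws no random numbers).
#'
#' Files written: `rpkm.tsv`, `library_summary.tsv`, `test_<stage>.tsv` and
#' `classification_<stage>.tsv` per stage, `stage_type_counts.tsv`,
#' `venn_partitions.tsv`, `xx_specific.txt` / `xy_specific.txt`,
#' `cog_all_stages.txt`, `xx_enhanced.tsv` / `xy_enhanced.tsv`, `run_log.txt`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results: `rpkm`, `summary`,
#'   `tests` (per stage), `calls`, `type_counts`, `venn`, `specific`,
#'   `cog_all`, `enhanced`, and `paths` of everything written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  counts <- read_counts(config$counts)
  libraries <- read_library_metadata(config$library_metadata)
  genes <- if (!is.null(config$gene_lengths))
    read_gene_lengths(config$gene_lengths) else read_gff3_lengths(config$gff3)
  missing_meta <- setdiff(colnames(counts), libraries$library_id)
  if (length(missing_meta) > 0)
    stop("count columns without metadata: ",
         paste(missing_meta, collapse = ", "))

  stages <- unique(libraries$stage)
  anchor <- if (is.null(config$anchor_stage)) stages[1] else config$anchor_stage
  if (!anchor %in% stages)
    stop("anchor_stage '", anchor, "' absent from metadata stages")

  rpkm <- compute_rpkm(counts, genes, libraries)
  flags <- detection_flags(counts, config$min_count)
  summary_tab <- library_summary(rpkm, counts, config$rpkm_summary_cutoffs)

  tests <- lapply(stages, function(s)
    test_stage(counts, rpkm, libraries, s, config$groups, config$min_count,
               config$fdr_method))
  names(tests) <- as.character(stages)
  calls <- do.call(rbind, lapply(stages, function(s)
    classify_stage(tests[[as.character(s)]], flags, libraries, s,
                   config$groups, config$fdr_threshold,
                   config$log2_threshold)))

  type_counts <- stage_type_counts(calls)
  venn <- venn_partitions(flags, libraries, config$groups)
  specific <- sex_specific_genes(flags, libraries, config$groups)
  cog_all <- cog_all_stages(calls)
  enhanced <- enhanced_genes(calls, anchor, config$min_other_stages)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$out_dir, f)
  paths <- c(rpkm = pth("rpkm.tsv"), summary = pth("library_summary.tsv"))
  write_tsv(cbind(data.frame(gene_id = rownames(rpkm)), as.data.frame(rpkm)),
            paths["rpkm"])
  write_tsv(summary_tab, paths["summary"])
  for (s in stages) {
    p1 <- pth(sprintf("test_%s.tsv", s))
    p2 <- pth(sprintf("classification_%s.tsv", s))
    write_tsv(tests[[as.character(s)]], p1)
    cs <- calls[calls$stage == s, ]
    cs$label <- as.character(cs$label)
    write_tsv(cs, p2)
    paths[sprintf("test_%s", s)] <- p1
    paths[sprintf("classification_%s", s)] <- p2
  }
  paths["type_counts"] <- pth("stage_type_counts.tsv")
  write_tsv(type_counts, paths["type_counts"])
  paths["venn"] <- pth("venn_partitions.tsv")
  write_tsv(data.frame(partition = names(venn), n_genes = as.integer(venn)),
            paths["venn"])
  paths["xx_specific"] <- pth("xx_specific.txt")
  writeLines(specific$xx_specific, paths["xx_specific"])
  paths["xy_specific"] <- pth("xy_specific.txt")
  writeLines(specific$xy_specific, paths["xy_specific"])
  paths["cog_all_stages"] <- pth("cog_all_stages.txt")
  writeLines(cog_all, paths["cog_all_stages"])
  paths["xx_enhanced"] <- pth("xx_enhanced.tsv")
  write_tsv(enhanced$xx_enhanced, paths["xx_enhanced"])
  paths["xy_enhanced"] <- pth("xy_enhanced.tsv")
  write_tsv(enhanced$xy_enhanced, paths["xy_enhanced"])

  paths["run_log"] <- pth("run_log.txt")
  log_lines <- c(
    paste0("segdig ", as.character(utils::packageVersion("segdig"))),
    paste0("run at: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    "config:",
    paste0("  counts: ", config$counts),
    paste0("  library_metadata: ", config$library_metadata),
    paste0("  gene_lengths: ",
           if (is.null(config$gene_lengths)) paste0("GFF3 ", config$gff3)
           else config$gene_lengths),
    paste0("  fdr_threshold: ", config$fdr_threshold,
           "  log2_threshold: ", config$log2_threshold,
           "  min_count: ", config$min_count,
           "  fdr_method: ", config$fdr_method),
    paste0("  anchor_stage: ", anchor,
           "  min_other_stages: ", config$min_other_stages),
    "per-stage label tallies:",
    utils::capture.output(print(type_counts, row.names = FALSE)),
    sprintf("venn: both=%d xx_only=%d xy_only=%d neither=%d",
            venn["both"], venn["xx_only"], venn["xy_only"], venn["neither"]),
    sprintf("sex-specific: xx=%d xy=%d", length(specific$xx_specific),
            length(specific$xy_specific)),
    sprintf("all-stage COGs: %d", length(cog_all)),
    sprintf("enhanced: xx=%d xy=%d", nrow(enhanced$xx_enhanced),
            nrow(enhanced$xy_enhanced))
  )
  writeLines(log_lines, paths["run_log"])

  invisible(list(rpkm = rpkm, summary = summary_tab, tests = tests,
                 calls = calls, type_counts = type_counts, venn = venn,
                 specific = specific, cog_all = cog_all, enhanced = enhanced,
                 paths = paths))
}
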