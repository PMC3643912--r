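#' @name classification
#' @title Five-type per-stage gene classification
#'
#' @description
#' At each stage every gene receives exactly one label from the dual
#' criterion "FDR <= fdr_threshold AND |log2(XX/XY RPKM)| >= log2_threshold":
#'
#' * detected in both groups: `XX-DIG` / `XY-DIG` when both criteria hold
#'   (sign of the ratio gives the direction), else `COG`;
#' * detected in one group only: the ratio is infinite so the fold criterion
#'   is automatically satisfied, and the gene is `XX-SEG` / `XY-SEG` when the
#'   FDR criterion holds, else `ND-SEG`;
#' * detected in neither: `NOT-EXPRESSED`.
#'
#' The ratio is log2(group1/group2) everywhere; positive means biased toward
#' the first group (the "XX" role).
NULL

stage_labels <- c("COG", "XX-DIG", "XY-DIG", "XX-SEG", "XY-SEG", "ND-SEG",
                  "NOT-EXPRESSED")

#' Classify every gene at one stage
#'
#' @param stage_test Per-gene test table from [test_stage()] for this stage.
#' @param flags Genes x libraries logical detection matrix from
#'   [detection_flags()]; its row names define the gene universe.
#' @param libraries Library metadata (see [test_stage()]).
#' @param stage Stage label being classified.
#' @param groups Character pair of group labels; first plays the "XX" role.
#' @param fdr_threshold Significance bound on the q-value; default 1e-2.
#' @param log2_threshold Bound on |log2 ratio|; default 1.
#' @return Data frame, one row per gene in the universe: `gene_id`, `stage`,
#'   `label`, `detected_xx`, `detected_xy`, and the carried statistics
#'   (`rpkm_xx`, `rpkm_xy`, `log2_ratio`, `p_value`, `q_value`; `NA` for
#'   untested genes).
#' @export
classify_stage <- function(stage_test, flags, libraries, stage,
                           groups = c("XX", "XY"),
                           fdr_threshold = 1e-2, log2_threshold = 1) {
  pair <- stage_library_pair(libraries, stage, groups)
  universe <- rownames(flags)
  f1 <- flags[, pair$lib1]
  f2 <- flags[, pair$lib2]
  tested <- universe[f1 | f2]
  if (!setequal(stage_test$gene_id, tested))
    stop("test table and detection flags cover different gene sets at stage '",
         stage, "'")
  idx <- match(universe, stage_test$gene_id)

  q <- stage_test$q_value[idx]
  lr <- stage_test$log2_ratio[idx]
  sig <- !is.na(q) & q <= fdr_threshold
  fold <- !is.na(lr) & abs(lr) >= log2_threshold

  label <- rep("NOT-EXPRESSED", length(universe))
  both <- f1 & f2
  label[both] <- "COG"
  label[both & sig & fold & lr > 0] <- "XX-DIG"
  label[both & sig & fold & lr < 0] <- "XY-DIG"
  one <- xor(f1, f2)
  label[one] <- "ND-SEG"
  label[one & f1 & sig] <- "XX-SEG"
  label[one & f2 & sig] <- "XY-SEG"

  data.frame(
    gene_id = universe, stage = stage,
    label = factor(label, levels = stage_labels),
    detected_xx = f1, detected_xy = f2,
    rpkm_xx = stage_test$rpkm_xx[idx],
    rpkm_xy = stage_test$rpkm_xy[idx],
    log2_ratio = lr,
    p_value = stage_test$p_value[idx],
    q_value = q,
    row.names = NULL
  )
}

#' Classify all stages of a dataset
#'
#' Convenience wrapper: runs [test_stage()] and [classify_stage()] for every
#' stage in the metadata and stacks the per-stage call tables.
#'
#' @inheritParams test_stage
#' @inheritParams classify_stage
#' @return Long data frame of stage calls (see [classify_stage()]), stages in
#'   metadata order.
#' @export
classify_all_stages <- function(counts, rpkm, libraries,
                                groups = c("XX", "XY"), min_count = 1,
                                fdr_threshold = 1e-2, log2_threshold = 1,
                                fdr_method = "BH") {
  flags <- detection_flags(counts, min_count)
  calls <- lapply(unique(libraries$stage), function(s) {
    tt <- test_stage(counts, rpkm, libraries, s, groups, min_count, fdr_method)
    classify_stage(tt, flags, libraries, s, groups, fdr_threshold,
                   log2_threshold)
  })
  do.call(rbind, calls)
}

#' Sex-specific genes across all stages
#'
#' A gene is specific to a group when it is detected in at least one of that
#' group's libraries and in none of the other group's, over the whole stage
#' course (the any-stage detection reading of a two-set Venn diagram).
#'
#' @param flags Genes x libraries logical detection matrix.
#' @param libraries Library metadata.
#' @param groups Character pair of group labels.
#' @return List with character vectors `xx_specific` and `xy_specific`.
#' @export
sex_specific_genes <- function(flags, libraries, groups = c("XX", "XY")) {
  in1 <- rowSums(flags[, group_libs(libraries, groups[1]), drop = FALSE]) > 0
  in2 <- rowSums(flags[, group_libs(libraries, groups[2]), drop = FALSE]) > 0
  list(xx_specific = rownames(flags)[in1 & !in2],
       xy_specific = rownames(flags)[in2 & !in1])
}

#' Detection Venn partition
#'
#' Partitions the gene universe by any-stage detection into both-groups,
#' first-group-only, second-group-only, and neither; the four counts always
#' sum to the universe size.
#'
#' @inheritParams sex_specific_genes
#' @return Named integer vector `c(both, xx_only, xy_only, neither)`.
#' @export
venn_partitions <- function(flags, libraries, groups = c("XX", "XY")) {
  in1 <- rowSums(flags[, group_libs(libraries, groups[1]), drop = FALSE]) > 0
  in2 <- rowSums(flags[, group_libs(libraries, groups[2]), drop = FALSE]) > 0
  c(both = sum(in1 & in2), xx_only = sum(in1 & !in2),
    xy_only = sum(in2 & !in1), neither = sum(!in1 & !in2))
}

group_libs <- function(libraries, group) {
  ids <- libraries$library_id[libraries$group == group]
  if (length(ids) == 0) stop("no libraries for group '", group, "'")
  ids
}

#' Genes co-expressed at every stage
#'
#' Genes labeled `COG` at all stages in the call table (or the subset of
#' stages given).
#'
#' @param calls Stage-call table from [classify_all_stages()].
#' @param stages Stages that must all be COG; default: every stage present.
#' @return Character vector of gene ids.
#' @export
cog_all_stages <- function(calls, stages = NULL) {
  if (is.null(stages)) stages <- unique(calls$stage)
  sub <- calls[calls$stage %in% stages, ]
  is_cog <- tapply(sub$label == "COG", sub$gene_id, all)
  names(is_cog)[is_cog]
}

#' Sex-enhanced genes
#'
#' A gene is XX-enhanced when it favors the XX side (label `XX-DIG` or
#' `XX-SEG`) at the anchor stage and at no fewer than `min_other_stages` of
#' the remaining stages; symmetrically for XY. Stages where the gene fails or
#' is untested simply do not count toward the requirement. The supporting
#' stages are recorded per gene, enabling stage-pattern partitions (e.g.
#' genes qualifying at the anchor plus exactly two named later stages).
#'
#' A gene can never be both XX- and XY-enhanced: both would require opposing
#' labels at the anchor stage, and each (gene, stage) has exactly one label.
#'
#' @param calls Stage-call table from [classify_all_stages()].
#' @param anchor_stage Stage that must qualify; default the first stage in
#'   the call table (5 dah in the standard design).
#' @param min_other_stages Minimum number of qualifying non-anchor stages;
#'   default 2.
#' @return List with data frames `xx_enhanced` and `xy_enhanced`, columns
#'   `gene_id`, `stages` (comma-separated supporting stages, anchor
#'   included), `n_stages`.
#' @export
enhanced_genes <- function(calls, anchor_stage = NULL, min_other_stages = 2) {
  all_stages <- unique(calls$stage)
  if (is.null(anchor_stage)) anchor_stage <- all_stages[1]
  if (!anchor_stage %in% all_stages)
    stop("anchor stage '", anchor_stage, "' has no calls")
  pick <- function(side_labels) {
    hit <- calls[calls$label %in% side_labels, c("gene_id", "stage")]
    sp <- split(hit$stage, hit$gene_id)
    keep <- vapply(sp, function(st)
      anchor_stage %in% st && sum(st != anchor_stage) >= min_other_stages,
      logical(1))
    sp <- sp[keep]
    data.frame(
      gene_id = names(sp),
      stages = vapply(sp, function(st)
        paste(all_stages[all_stages %in% st], collapse = ","), character(1)),
      n_stages = lengths(sp),
      row.names = NULL
    )
  }
  out <- list(xx_enhanced = pick(c("XX-DIG", "XX-SEG")),
              xy_enhanced = pick(c("XY-DIG", "XY-SEG")))
  stopifnot(length(intersect(out$xx_enhanced$gene_id,
                             out$xy_enhanced$gene_id)) == 0)
  out
}

#' Per-stage label tallies
#'
#' Counts of each of the seven labels per stage; the per-stage counts always
#' sum to the size of the gene universe.
#'
#' @param calls Stage-call table from [classify_all_stages()].
#' @return Data frame: `stage`, then one column per label.
#' @export
stage_type_counts <- function(calls) {
  tab <- table(calls$stage, calls$label)
  out <- data.frame(stage = rownames(tab), row.names = NULL)
  for (l in colnames(tab)) out[[l]] <- as.integer(tab[, l])
  out
}
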