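# hand-built one-stage fixture exercising every branch of the dual criterion
branch_fixture <- function() {
  genes <- c("dig_xx", "dig_xy", "cog_sig_only", "cog_fold_only", "cog_plain",
             "seg_xx", "seg_xy", "ndseg", "absent")
  flags <- matrix(c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE,
                    TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
                  9, 2, dimnames = list(genes, c("XX_5dah", "XY_5dah")))
  libraries <- data.frame(library_id = c("XX_5dah", "XY_5dah"),
                          group = c("XX", "XY"), stage = 5,
                          total_mapped_reads = 1e6)
  # rpkm pairs: dig_xx uses published qPCR-validation RPKMs (66.32 vs 2.92)
  tt <- data.frame(
    gene_id = genes[-9],
    x = 1L, y = 1L, n1 = 1e6, n2 = 1e6,
    rpkm_xx = c(66.32, 1, 10, 40, 10, 8, 0, 3),
    rpkm_xy = c(2.92, 9, 19, 10, 11, 0, 5, 0),
    log2_ratio = log2_ratio(c(66.32, 1, 10, 40, 10, 8, 0, 3),
                            c(2.92, 9, 19, 10, 11, 0, 5, 0)),
    p_value = c(1e-4, 1e-4, 1e-4, 0.5, 0.5, 1e-4, 1e-4, 0.5),
    q_value = c(1e-3, 1e-3, 1e-3, 0.6, 0.6, 1e-3, 1e-3, 0.5)
  )
  list(tt = tt, flags = flags, libraries = libraries)
}

test_that("classify_stage applies the dual criterion branchwise", {
  f <- branch_fixture()
  calls <- classify_stage(f$tt, f$flags, f$libraries, 5)
  got <- setNames(as.character(calls$label), calls$gene_id)
  expect_identical(got[["dig_xx"]], "XX-DIG")   # q<=1e-2 and |log2|>=1, XX up
  expect_identical(got[["dig_xy"]], "XY-DIG")
  expect_identical(got[["cog_sig_only"]], "COG")   # significant but <2-fold
  expect_identical(got[["cog_fold_only"]], "COG")  # 4-fold but q too large
  expect_identical(got[["cog_plain"]], "COG")
  expect_identical(got[["seg_xx"]], "XX-SEG")   # one-sided, infinite ratio
  expect_identical(got[["seg_xy"]], "XY-SEG")
  expect_identical(got[["ndseg"]], "ND-SEG")    # one-sided, q fails
  expect_identical(got[["absent"]], "NOT-EXPRESSED")
  # single-detection labels carry exactly one detection flag
  one <- calls$label %in% c("XX-SEG", "XY-SEG", "ND-SEG")
  expect_true(all(xor(calls$detected_xx[one], calls$detected_xy[one])))
  expect_error(classify_stage(f$tt[-1, ], f$flags, f$libraries, 5),
               "different gene sets")
})

test_that("per-stage labels partition the gene universe exactly", {
  d <- tiny_dataset(400, seed = 23)
  rp <- compute_rpkm(d$counts, d$genes, d$libraries)
  calls <- classify_all_stages(d$counts, rp, d$libraries)
  tc <- stage_type_counts(calls)
  expect_equal(unname(rowSums(tc[, -1])), rep(400L, 4))
  # every (gene, stage) has exactly one row
  expect_equal(nrow(calls), 400 * 4)
  expect_false(anyNA(calls$label))
})

test_that("planted classes are recovered at each stage", {
  d <- tiny_dataset(600, seed = 29)
  rp <- compute_rpkm(d$counts, d$genes, d$libraries)
  calls <- classify_all_stages(d$counts, rp, d$libraries)
  planted_to_call <- c(cog = "COG", xx_dig = "XX-DIG", xy_dig = "XY-DIG",
                       xx_seg = "XX-SEG", xy_seg = "XY-SEG",
                       silent = "NOT-EXPRESSED")
  for (s in c(5, 30, 90, 180)) {
    truth <- d$truth$labels[, as.character(s)]
    got <- as.character(calls$label[calls$stage == s])
    for (cls in c("xx_dig", "xy_dig", "xx_seg", "xy_seg")) {
      acc <- mean(got[truth == cls] == planted_to_call[[cls]])
      expect_gte(acc, 0.95)
    }
    false_dig <- mean(got[truth == "cog"] %in% c("XX-DIG", "XY-DIG"))
    expect_lte(false_dig, 0.05)
  }
})

test_that("sex-specific sets and Venn partition agree with direct set algebra", {
  set.seed(19)
  flags <- matrix(runif(200) < 0.5, 25, 8)
  libs <- data.frame(
    library_id = paste0(rep(c("XX", "XY"), 4), "_", rep(c(5, 30, 90, 180),
                                                        each = 2), "dah"),
    group = rep(c("XX", "XY"), 4), stage = rep(c(5, 30, 90, 180), each = 2),
    total_mapped_reads = 1e6)
  dimnames(flags) <- list(paste0("g", 1:25), libs$library_id)
  in_xx <- apply(flags[, libs$group == "XX"], 1, any)
  in_xy <- apply(flags[, libs$group == "XY"], 1, any)
  sp <- sex_specific_genes(flags, libs)
  expect_setequal(sp$xx_specific, rownames(flags)[in_xx & !in_xy])
  expect_setequal(sp$xy_specific, rownames(flags)[in_xy & !in_xx])
  expect_length(intersect(sp$xx_specific, sp$xy_specific), 0)
  v <- venn_partitions(flags, libs)
  expect_equal(unname(v), c(sum(in_xx & in_xy), sum(in_xx & !in_xy),
                            sum(in_xy & !in_xx), sum(!in_xx & !in_xy)))
  expect_equal(sum(v), nrow(flags))
  # degenerate: nothing detected
  v0 <- venn_partitions(flags & FALSE, libs)
  expect_equal(unname(v0), c(0L, 0L, 0L, 25L))
})

test_that("planted group-specific genes land in the sex-specific sets", {
  d <- tiny_dataset(500, seed = 37)
  flags <- detection_flags(d$counts)
  sp <- sex_specific_genes(flags, d$libraries)
  planted_xx <- rownames(d$counts)[d$truth$labels[, 1] == "xx_seg"]
  expect_true(all(planted_xx %in% sp$xx_specific))
  planted_xy <- rownames(d$counts)[d$truth$labels[, 1] == "xy_seg"]
  expect_true(all(planted_xy %in% sp$xy_specific))
})

test_that("all-stage co-expression requires COG at every stage", {
  calls <- data.frame(
    gene_id = rep(c("a", "b"), each = 4),
    stage = rep(c(5, 30, 90, 180), 2),
    label = factor(c("COG", "COG", "COG", "XX-DIG",
                     rep("COG", 4)),
                   levels = c("COG", "XX-DIG", "XY-DIG", "XX-SEG", "XY-SEG",
                              "ND-SEG", "NOT-EXPRESSED")))
  expect_identical(cog_all_stages(calls), "b")
})

test_that("enhanced genes require the anchor stage plus two others, same sex", {
  lv <- c("COG", "XX-DIG", "XY-DIG", "XX-SEG", "XY-SEG", "ND-SEG",
          "NOT-EXPRESSED")
  mk <- function(gene, labels)
    data.frame(gene_id = gene, stage = c(5, 30, 90, 180),
               label = factor(labels, levels = lv))
  calls <- rbind(
    mk("all4", c("XX-DIG", "XX-DIG", "XX-DIG", "XX-DIG")),
    mk("no_anchor", c("COG", "XX-DIG", "XX-DIG", "XX-DIG")),
    mk("seg_mix", c("XY-SEG", "COG", "XY-DIG", "XY-DIG")),
    mk("only_one_other", c("XX-DIG", "XX-DIG", "COG", "COG")),
    mk("gap_ok", c("XX-SEG", "NOT-EXPRESSED", "XX-DIG", "XX-DIG")))
  e <- enhanced_genes(calls, anchor_stage = 5)
  expect_setequal(e$xx_enhanced$gene_id, c("all4", "gap_ok"))
  expect_identical(e$xx_enhanced$stages[e$xx_enhanced$gene_id == "all4"],
                   "5,30,90,180")
  expect_identical(e$xx_enhanced$stages[e$xx_enhanced$gene_id == "gap_ok"],
                   "5,90,180")
  expect_setequal(e$xy_enhanced$gene_id, "seg_mix")
  expect_identical(e$xy_enhanced$stages, "5,90,180")
  expect_length(intersect(e$xx_enhanced$gene_id, e$xy_enhanced$gene_id), 0)
  expect_error(enhanced_genes(calls, anchor_stage = 999), "anchor")
})
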