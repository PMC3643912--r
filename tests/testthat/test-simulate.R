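test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_genes = 0), "positive")
  expect_error(simulation_config(library_sizes = rep(5e6, 3)),
               "one entry per library")
  expect_error(simulation_config(dig_fold = 1.5), "dig_fold")
  expect_error(simulation_config(groups = c("XX", "XX")), "distinct")
  f <- c(cog = 0.5, xx_dig = 0.2, xy_dig = 0.2, xx_seg = 0.05, xy_seg = 0.05,
         silent = 0.1)
  expect_error(simulation_config(class_fractions = f), "sum to 1")
})

test_that("all-silent configurations produce exactly zero counts", {
  f <- c(cog = 0, xx_dig = 0, xy_dig = 0, xx_seg = 0, xy_seg = 0, silent = 1)
  d <- generate_dataset(simulation_config(n_genes = 50, class_fractions = f,
                                          seed = 2))
  expect_true(all(d$counts == 0))
  expect_true(all(d$truth$true_rpkm == 0))
})

test_that("identical configuration and seed reproduce counts exactly", {
  d1 <- tiny_dataset(300, seed = 7)
  d2 <- tiny_dataset(300, seed = 7)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$truth$labels, d2$truth$labels)
  d3 <- tiny_dataset(300, seed = 8)
  expect_false(identical(d1$counts, d3$counts))
})

test_that("appending stages leaves earlier library columns unchanged", {
  cfg2 <- simulation_config(n_genes = 150, stages = c(5, 30), seed = 13,
                            library_sizes = rep(5e6, 4))
  cfg3 <- simulation_config(n_genes = 150, stages = c(5, 30, 90), seed = 13,
                            library_sizes = rep(5e6, 6))
  d2 <- generate_dataset(cfg2)
  d3 <- generate_dataset(cfg3)
  expect_identical(d2$counts, d3$counts[, 1:4])
})

test_that("counts obey the Poisson mean mu = q*L*N/1e9", {
  # 200 co-expressed genes pinned at RPKM 50, length 1000, N = 1e7:
  # each count has mean 500, so the gene-averaged count per library must lie
  # within 3 standard errors, 500 +/- 3*sqrt(500/200)
  f <- c(cog = 1, xx_dig = 0, xy_dig = 0, xx_seg = 0, xy_seg = 0, silent = 0)
  cfg <- simulation_config(n_genes = 200, class_fractions = f,
                           base_expression_range = c(50, 50),
                           gene_length_range = c(1000, 1000),
                           library_sizes = rep(1e7, 8), seed = 5)
  d <- generate_dataset(cfg)
  se <- sqrt(500 / 200)
  for (j in seq_len(ncol(d$counts)))
    expect_lt(abs(mean(d$counts[, j]) - 500), 3 * se)
})

test_that("planted group-specific genes have exactly zero counts in the other group", {
  d <- tiny_dataset(500, seed = 31)
  xx_seg <- d$truth$labels[, 1] == "xx_seg"
  xy_libs <- d$libraries$library_id[d$libraries$group == "XY"]
  expect_true(all(d$counts[xx_seg, xy_libs] == 0))
  xy_seg <- d$truth$labels[, 1] == "xy_seg"
  xx_libs <- d$libraries$library_id[d$libraries$group == "XX"]
  expect_true(all(d$counts[xy_seg, xx_libs] == 0))
  # planted co-expressed genes have identical true expression in both groups
  cog <- d$truth$labels[, 1] == "cog"
  expect_equal(d$truth$true_rpkm[cog, xx_libs[1]],
               d$truth$true_rpkm[cog, xy_libs[1]])
})

test_that("a per-stage class schedule plants stage-restricted effects", {
  sched <- matrix("cog", 60, 4)
  sched[1:10, c(1, 2, 3)] <- "xx_dig"   # qualifies at 5, 30, 90 dah
  sched[11:20, c(2, 3, 4)] <- "xy_dig"  # no anchor-stage effect
  cfg <- simulation_config(n_genes = 60, seed = 17, class_schedule = sched)
  d <- generate_dataset(cfg)
  expect_identical(unname(d$truth$labels[1, ]),
                   c("xx_dig", "xx_dig", "xx_dig", "cog"))
  xx5 <- d$truth$true_rpkm[, "XX_5dah"]
  xy5 <- d$truth$true_rpkm[, "XY_5dah"]
  expect_true(all(xx5[1:10] == 8 * xy5[1:10]))
  expect_true(all(xx5[21:60] == xy5[21:60]))
})

test_that("written fixtures round-trip through the readers", {
  d <- tiny_dataset(10, seed = 7)
  dir <- withr::local_tempdir()
  paths <- write_dataset(d, dir)
  expect_identical(read_counts(paths["counts"]), d$counts)
  expect_equal(read_gene_lengths(paths["gene_lengths"]), d$genes)
  expect_equal(read_library_metadata(paths["library_metadata"]), d$libraries)
  # counts file: one header line plus one row per gene
  expect_length(readLines(paths["counts"]), 11)
})
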