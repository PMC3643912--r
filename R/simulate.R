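#' Simulation configuration for the two-sex, multi-stage count model
#'
#' Defines the synthetic study: two genotype groups sequenced once per
#' developmental stage, with genes planted into six classes:
#'
#' * `cog` — identical true expression in both groups,
#' * `xx_dig` / `xy_dig` — expression multiplied by `dig_fold` in the named
#'   group,
#' * `xx_seg` / `xy_seg` — expressed only in the named group (true expression
#'   exactly 0 in the other),
#' * `silent` — true expression 0 everywhere.
#'
#' True expression is specified on the RPKM scale; counts are later drawn as
#' Poisson with mean \eqn{\mu = q \, L \, N / 10^9} (the RPKM formula
#' inverted), matching the sampling model the exact two-library test assumes.
#'
#' Defaults emulate a gonadal transcriptome study design: ~21,000 genes, four
#' stages (5, 30, 90, 180 days after hatching), groups XX and XY, one library
#' per group per stage.
#'
#' @param n_genes Number of genes; positive integer.
#' @param stages Ordered, unique stage labels. Default `c(5, 30, 90, 180)`
#'   (days after hatching).
#' @param groups Exactly two genotype labels. Default `c("XX", "XY")`.
#' @param library_sizes Total mapped reads per library, in stage-major order
#'   (all groups within a stage, stages in order). Default 5e6 per library.
#' @param gene_length_range Integer min/max gene length in nucleotides;
#'   lengths are drawn uniformly. Default `c(500, 3000)`.
#' @param class_fractions Named proportions of the six planted classes,
#'   summing to 1. Defaults: cog .70, xx_dig .08, xy_dig .08, xx_seg .02,
#'   xy_seg .02, silent .10.
#' @param dig_fold Fold change applied to planted differential genes; must be
#'   >= 2 so planted effects pass the |log2| >= 1 criterion in expectation.
#'   Default 8.
#' @param base_expression_range Min/max baseline true expression (RPKM
#'   scale), drawn uniformly per gene. Default `c(40, 200)`, chosen so that
#'   with the default library size and shortest genes the expected count of an
#'   expressed gene is at least 100.
#' @param seed Master seed; per-library streams are derived from it so adding
#'   libraries never perturbs earlier columns.
#' @param class_schedule Optional character matrix (`n_genes` x
#'   `length(stages)`) of per-stage class labels, overriding the single
#'   per-gene class; used to plant stage-restricted effects.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 21000,
                              stages = c(5, 30, 90, 180),
                              groups = c("XX", "XY"),
                              library_sizes = NULL,
                              gene_length_range = c(500, 3000),
                              class_fractions = c(cog = 0.70, xx_dig = 0.08,
                                                  xy_dig = 0.08, xx_seg = 0.02,
                                                  xy_seg = 0.02, silent = 0.10),
                              dig_fold = 8,
                              base_expression_range = c(40, 200),
                              seed = 1,
                              class_schedule = NULL) {
  if (is.null(library_sizes))
    library_sizes <- rep(5e6, length(stages) * length(groups))
  cfg <- structure(
    list(n_genes = n_genes, stages = stages, groups = groups,
         library_sizes = library_sizes,
         gene_length_range = gene_length_range,
         class_fractions = class_fractions, dig_fold = dig_fold,
         base_expression_range = base_expression_range, seed = seed,
         class_schedule = class_schedule),
    class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

planted_classes <- c("cog", "xx_dig", "xy_dig", "xx_seg", "xy_seg", "silent")

validate_simulation_config <- function(cfg) {
  if (length(cfg$n_genes) != 1 || cfg$n_genes < 1 ||
      cfg$n_genes != round(cfg$n_genes))
    stop("n_genes must be a positive integer")
  if (length(cfg$groups) != 2 || anyDuplicated(cfg$groups))
    stop("exactly two distinct group labels are required")
  if (length(cfg$stages) < 1 || anyDuplicated(cfg$stages))
    stop("stages must be non-empty and unique")
  n_libs <- length(cfg$stages) * 2
  if (length(cfg$library_sizes) != n_libs)
    stop("library_sizes must have one entry per library (", n_libs, ")")
  if (any(cfg$library_sizes < 1) ||
      any(cfg$library_sizes != round(cfg$library_sizes)))
    stop("library_sizes must be positive integers")
  f <- cfg$class_fractions
  if (!setequal(names(f), planted_classes))
    stop("class_fractions must be named: ",
         paste(planted_classes, collapse = ", "))
  if (any(f < 0)) stop("class fractions must be non-negative")
  if (abs(sum(f) - 1) > 1e-9) stop("class fractions must sum to 1")
  if (cfg$dig_fold < 2) stop("dig_fold must be >= 2")
  if (length(cfg$gene_length_range) != 2 ||
      cfg$gene_length_range[1] < 1 || diff(cfg$gene_length_range) < 0)
    stop("gene_length_range must be an increasing pair of positive integers")
  if (length(cfg$base_expression_range) != 2 ||
      cfg$base_expression_range[1] < 0 ||
      diff(cfg$base_expression_range) < 0)
    stop("base_expression_range must be a non-decreasing non-negative pair")
  if (!is.null(cfg$class_schedule)) {
    cs <- cfg$class_schedule
    if (!is.matrix(cs) || nrow(cs) != cfg$n_genes ||
        ncol(cs) != length(cfg$stages))
      stop("class_schedule must be an n_genes x n_stages matrix of labels")
    if (!all(cs %in% planted_classes))
      stop("class_schedule contains unknown class labels")
  }
  invisible(cfg)
}

#' Generate a synthetic two-sex stage-course count dataset
#'
#' Draws gene lengths, baseline expression, and planted class labels from the
#' configuration, builds the true RPKM-scale expression of every gene in every
#' library, and samples counts as Poisson with mean
#' \eqn{\mu = q \, L \, N / 10^9}. The output carries the ground truth needed
#' to score recovery of the planted structure.
#'
#' Determinism: gene-level draws use the master seed; each library's counts
#' use a seed derived from (master seed, library index), so the same
#' configuration and seed reproduce counts bit for bit, and appending
#' libraries leaves earlier columns unchanged.
#'
#' @param config A [simulation_config()].
#' @return A list of class `"segdig_dataset"`:
#' \describe{
#'   \item{counts}{integer genes x libraries matrix}
#'   \item{genes}{data frame `gene_id`, `length`}
#'   \item{libraries}{data frame `library_id`, `group`, `stage`,
#'     `total_mapped_reads`}
#'   \item{truth}{list: `labels`, a genes x stages character matrix of planted
#'     classes; `true_rpkm`, a genes x libraries matrix of true RPKM-scale
#'     expression}
#' }
#' @export
generate_dataset <- function(config) {
  validate_simulation_config(config)
  n <- config$n_genes
  stages <- config$stages
  groups <- config$groups
  gene_id <- sprintf("gene%05d", seq_len(n))

  libraries <- data.frame(
    library_id = as.vector(vapply(stages, function(s)
      paste0(groups, "_", s, "dah"), character(2))),
    group = rep(groups, times = length(stages)),
    stage = rep(stages, each = 2),
    total_mapped_reads = config$library_sizes,
    stringsAsFactors = FALSE
  )

  set.seed(seed_in_range(config$seed))
  len_vals <- seq(config$gene_length_range[1], config$gene_length_range[2])
  lengths <- len_vals[sample.int(length(len_vals), n, replace = TRUE)]
  base_q <- stats::runif(n, config$base_expression_range[1],
                         config$base_expression_range[2])

  if (is.null(config$class_schedule)) {
    cls <- sample(apportion_classes(config$class_fractions, n))
    labels <- matrix(cls, nrow = n, ncol = length(stages))
  } else {
    labels <- config$class_schedule
  }
  dimnames(labels) <- list(gene_id, as.character(stages))

  true_rpkm <- matrix(0, n, nrow(libraries),
                      dimnames = list(gene_id, libraries$library_id))
  for (j in seq_len(nrow(libraries))) {
    st <- as.character(libraries$stage[j])
    own <- libraries$group[j]  # groups[1] is the "XX" role, groups[2] "XY"
    lab <- labels[, st]
    q <- base_q
    q[lab == "silent"] <- 0
    if (own == groups[1]) {
      q[lab == "xy_seg"] <- 0
      q[lab == "xx_dig"] <- base_q[lab == "xx_dig"] * config$dig_fold
    } else {
      q[lab == "xx_seg"] <- 0
      q[lab == "xy_dig"] <- base_q[lab == "xy_dig"] * config$dig_fold
    }
    true_rpkm[, j] <- q
  }

  counts <- matrix(0L, n, nrow(libraries),
                   dimnames = dimnames(true_rpkm))
  for (j in seq_len(nrow(libraries))) {
    set.seed(seed_in_range(config$seed, j))
    mu <- true_rpkm[, j] * lengths * libraries$total_mapped_reads[j] / 1e9
    counts[, j] <- stats::rpois(n, mu)
  }

  structure(
    list(counts = counts,
         genes = data.frame(gene_id = gene_id, length = lengths,
                            stringsAsFactors = FALSE),
         libraries = libraries,
         truth = list(labels = labels, true_rpkm = true_rpkm)),
    class = "segdig_dataset")
}

# integer class sizes by largest remainder, so planted counts are exact
apportion_classes <- function(fractions, n) {
  fractions <- fractions[planted_classes]
  k <- floor(fractions * n)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(fractions * n - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  rep(planted_classes, times = k)
}

# fold (seed, stream) into [1, 2^31 - 2] for set.seed
seed_in_range <- function(seed, stream = 0) {
  as.integer((abs(as.double(seed)) * 1009 + 7919 * stream) %% 2147483646) + 1L
}

#' Write a simulated dataset as TSV fixtures
#'
#' Emits the count, gene-length, library-metadata, and ground-truth tables in
#' the formats the package readers consume, so a simulated dataset
#' round-trips losslessly through [read_counts()] and friends.
#'
#' @param dataset A `"segdig_dataset"` from [generate_dataset()].
#' @param dir Target directory, created if needed.
#' @return Invisibly, a named character vector of the file paths written
#'   (`counts`, `gene_lengths`, `library_metadata`, `truth_labels`,
#'   `truth_rpkm`).
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    gene_lengths = file.path(dir, "gene_lengths.tsv"),
    library_metadata = file.path(dir, "library_metadata.tsv"),
    truth_labels = file.path(dir, "truth_labels.tsv"),
    truth_rpkm = file.path(dir, "truth_rpkm.tsv")
  )
  write_tsv(cbind(data.frame(gene_id = rownames(dataset$counts)),
                  as.data.frame(dataset$counts)), paths["counts"])
  write_tsv(dataset$genes, paths["gene_lengths"])
  write_tsv(dataset$libraries, paths["library_metadata"])
  lab <- as.data.frame(dataset$truth$labels)
  names(lab) <- paste0("stage_", colnames(dataset$truth$labels))
  write_tsv(cbind(data.frame(gene_id = rownames(dataset$truth$labels)), lab),
            paths["truth_labels"])
  tr <- as.data.frame(dataset$truth$true_rpkm)
  write_tsv(cbind(data.frame(gene_id = rownames(dataset$truth$true_rpkm)), tr),
            paths["truth_rpkm"])
  invisible(paths)
}
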