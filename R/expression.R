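#' RPKM expression values
#'
#' Reads per kilobase of gene model per million mapped reads:
#' \deqn{RPKM = \frac{10^9 \, C}{N \, L}}
#' where `C` is the mapped read count of a gene, `L` its exonic length in
#' nucleotides, and `N` the total mapped read count of the library. `N` is
#' taken from the library metadata, not from column sums: multi-mapped reads
#' make column sums differ from the library's mapped total.
#'
#' @param counts Genes x libraries integer matrix of mapped read counts; row
#'   names are gene ids, column names library ids.
#' @param genes Data frame with columns `gene_id` and `length` (nucleotides)
#'   covering every row of `counts`.
#' @param libraries Data frame with columns `library_id` and
#'   `total_mapped_reads` covering every column of `counts`.
#' @return Numeric matrix of RPKM values with the same dimnames as `counts`.
#' @examples
#' counts <- matrix(100L, 1, 1, dimnames = list("g1", "L1"))
#' genes <- data.frame(gene_id = "g1", length = 2000L)
#' libs <- data.frame(library_id = "L1", total_mapped_reads = 5e7)
#' compute_rpkm(counts, genes, libs)  # 1.0
#' @export
compute_rpkm <- function(counts, genes, libraries) {
  validate_count_matrix(counts)
  gi <- match(rownames(counts), genes$gene_id)
  if (anyNA(gi))
    stop("no gene length for: ",
         paste(utils::head(rownames(counts)[is.na(gi)], 5), collapse = ", "))
  L <- genes$length[gi]
  if (any(L <= 0)) stop("gene lengths must be positive")
  li <- match(colnames(counts), libraries$library_id)
  if (anyNA(li))
    stop("no library metadata for: ",
         paste(colnames(counts)[is.na(li)], collapse = ", "))
  N <- libraries$total_mapped_reads[li]
  if (any(N < 1)) stop("total_mapped_reads must be positive")
  1e9 * counts / outer(L, N)
}

#' Per-library detection flags
#'
#' A gene is detected ("expressed") in a library when its mapped read count
#' reaches `min_count`. The default of 1 treats any mapped read as evidence of
#' expression, consistent with reporting RPKM cutoffs separately.
#'
#' @inheritParams compute_rpkm
#' @param min_count Minimum count for detection; default 1.
#' @return Logical matrix with the dimnames of `counts`.
#' @export
detection_flags <- function(counts, min_count = 1) {
  validate_count_matrix(counts)
  if (min_count < 1) stop("min_count must be >= 1")
  counts >= min_count
}

#' Per-library expression summary
#'
#' For each library: the number of genes detected (count >= 1) and the number
#' of genes at or above each RPKM cutoff, in the style of per-transcriptome
#' summary tables.
#'
#' @inheritParams compute_rpkm
#' @param rpkm RPKM matrix matching `counts`, as from [compute_rpkm()].
#' @param thresholds RPKM cutoffs; default `c(1, 5)`.
#' @return Data frame: `library_id`, `genes_detected`, then one column
#'   `rpkm_ge_<cutoff>` per threshold.
#' @export
library_summary <- function(rpkm, counts, thresholds = c(1, 5)) {
  if (length(thresholds) == 0) stop("thresholds must be non-empty")
  if (!identical(dim(rpkm), dim(counts)))
    stop("rpkm and counts must have identical dimensions")
  out <- data.frame(
    library_id = colnames(counts),
    genes_detected = colSums(counts >= 1),
    row.names = NULL
  )
  for (t in thresholds)
    out[[sprintf("rpkm_ge_%g", t)]] <- colSums(rpkm >= t)
  out
}

validate_count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids as row names and library ids as column names")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  invisible(counts)
}
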