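#' Read a gene count table
#'
#' Tab-separated, UTF-8, header row; first column `gene_id`, one integer
#' column per library. Duplicate gene ids, missing values, and negative or
#' non-integer counts are rejected with the offending row or cell named.
#'
#' @param path Path to the counts TSV.
#' @return Integer matrix, genes x libraries, dimnames set.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path, "counts")
  if (names(df)[1] != "gene_id")
    stop("counts file must start with a 'gene_id' column: ", path)
  if (ncol(df) < 2)
    stop("counts file has no library columns: ", path)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in counts: ",
         df$gene_id[duplicated(df$gene_id)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("invalid count at gene '", df$gene_id[bad[1, 1]], "', library '",
         colnames(m)[bad[1, 2]], "'")
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  m
}

#' Read a gene-length table
#'
#' Columns `gene_id`, `length` (positive integers, nucleotides).
#'
#' @param path Path to the gene-length TSV.
#' @return Data frame `gene_id`, `length`.
#' @export
read_gene_lengths <- function(path) {
  df <- read_tsv(path, "gene lengths", c("gene_id", "length"))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in gene lengths: ",
         df$gene_id[duplicated(df$gene_id)][1])
  bad <- which(is.na(df$length) | df$length < 1 |
                 df$length != round(df$length))
  if (length(bad) > 0)
    stop("invalid length for gene '", df$gene_id[bad[1]], "'")
  df[c("gene_id", "length")]
}

#' Read library metadata
#'
#' Columns `library_id`, `group`, `stage`, `total_mapped_reads`. Library ids
#' must be unique and totals positive integers.
#'
#' @param path Path to the metadata TSV.
#' @return Data frame with the four columns above.
#' @export
read_library_metadata <- function(path) {
  df <- read_tsv(path, "library metadata",
                 c("library_id", "group", "stage", "total_mapped_reads"))
  if (anyDuplicated(df$library_id))
    stop("duplicate library_id: ", df$library_id[duplicated(df$library_id)][1])
  bad <- which(is.na(df$total_mapped_reads) | df$total_mapped_reads < 1 |
                 df$total_mapped_reads != round(df$total_mapped_reads))
  if (length(bad) > 0)
    stop("invalid total_mapped_reads for library '", df$library_id[bad[1]], "'")
  df[c("library_id", "group", "stage", "total_mapped_reads")]
}

read_tsv <- function(path, what, required = NULL) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0)
      stop(what, " file missing column(s): ",
           paste(missing, collapse = ", "), " (", path, ")")
  }
  df
}

# TSV dialect: tab-separated, header, "NA" for undefined, Inf/-Inf literal;
# p/q values at 3 significant digits scientific, other floats at 6
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    col <- df[[nm]]
    if (is.double(col)) {
      if (nm %in% c("p_value", "q_value")) {
        out <- formatC(col, digits = 3, format = "e")
      } else {
        out <- formatC(signif(col, 6), format = "g", digits = 6)
      }
      out[is.na(col)] <- "NA"
      out[is.infinite(col) & col > 0] <- "Inf"
      out[is.infinite(col) & col < 0] <- "-Inf"
      df[[nm]] <- out
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Gene lengths from a GFF3 annotation
#'
#' Computes each gene's length as the total length of the union of its exon
#' intervals, in the GFF3 convention of 1-based end-inclusive coordinates
#' (a single exon 101..200 has length 100). Exons are attributed to genes via
#' a `gene_id` attribute when present, otherwise by climbing `Parent`
#' references (exon to transcript to gene).
#'
#' @param path Path to a GFF3 file.
#' @return Data frame `gene_id`, `length`, one row per gene with exons.
#' @export
read_gff3_lengths <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0) stop("no exon features in ", path)
  ids <- exon_gene_ids(ex, gr)
  per_gene <- GenomicRanges::reduce(GenomicRanges::split(ex, ids))
  lens <- sum(GenomicRanges::width(per_gene))
  data.frame(gene_id = names(lens), length = as.integer(lens),
             row.names = NULL, stringsAsFactors = FALSE)
}

exon_gene_ids <- function(ex, gr) {
  if (!is.null(ex$gene_id) && !anyNA(ex$gene_id))
    return(as.character(ex$gene_id))
  if (is.null(ex$Parent))
    stop("exons carry neither gene_id nor Parent attributes")
  parent_of <- as.character(gr$Parent)
  names(parent_of) <- as.character(gr$ID)
  is_gene <- tolower(as.character(gr$type)) == "gene"
  gene_ids <- as.character(gr$ID)[is_gene]
  resolve <- function(id) {
    seen <- 0
    while (!(id %in% gene_ids) && id %in% names(parent_of) && seen < 10) {
      nxt <- parent_of[[id]]
      if (is.na(nxt) || length(nxt) == 0) break
      id <- nxt
      seen <- seen + 1
    }
    id
  }
  vapply(as.character(ex$Parent), resolve, character(1), USE.NAMES = FALSE)
}
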