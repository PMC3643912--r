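#' Exact two-library count test (Audic-Claverie)
#'
#' Computes the two-sided p-value for a difference in mapped-read counts of a
#' gene between two sequencing libraries of known sizes, using the
#' Audic-Claverie conditional distribution. Given `x` reads in library 1 (total
#' size `n1`), the probability of observing `k` reads in library 2 (size `n2`)
#' is
#' \deqn{P(k \mid x) = \left(\frac{n_2}{n_1}\right)^k
#'   \frac{(x+k)!}{x!\,k!\,(1+n_2/n_1)^{x+k+1}}}
#' The two-sided p-value is twice the smaller of the two tails that include the
#' observed `y`, capped at 1:
#' \deqn{p = \min\left(1,\; 2\min\Big(\sum_{k \le y} P(k\mid x),\;
#'   \sum_{k \ge y} P(k \mid x)\Big)\right)}
#'
#' All probability terms are evaluated in log space through `lgamma`; the
#' smaller tail is summed directly and the larger recovered through the exact
#' identity \eqn{S(y) = 1 - F(y) + P(y|x)}, so no tail is ever formed by
#' subtracting two nearly equal numbers. A p-value that underflows is reported
#' as the smallest positive normal double rather than 0, preserving
#' \eqn{p \in (0, 1]}.
#'
#' Note that the statistic conditions on the count in the *first* library, so
#' it is not exactly invariant under swapping the two libraries; the
#' discrepancy is visible at small counts and vanishes as counts grow.
#'
#' @param x,y Non-negative integer read counts in library 1 and library 2.
#'   Vectors are recycled to a common length.
#' @param n1,n2 Positive total mapped read counts (library sizes) of the two
#'   libraries.
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @examples
#' audic_pvalue(10, 0, 1e6, 1e6)   # 2^-10
#' audic_pvalue(100, 130, 5e6, 5e6)
#' @seealso [audic_pmf()] for the conditional probability mass itself,
#'   [bh_fdr()] for multiplicity adjustment, [test_stage()] for the per-stage
#'   genewise application.
#' @export
audic_pvalue <- function(x, y, n1, n2) {
  len <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, len); y <- rep_len(y, len)
  n1 <- rep_len(n1, len); n2 <- rep_len(n2, len)
  if (anyNA(x) || anyNA(y) || anyNA(n1) || anyNA(n2))
    stop("counts and library sizes must not contain NA")
  if (any(x < 0) || any(y < 0))
    stop("counts must be non-negative")
  if (any(x != round(x)) || any(y != round(y)))
    stop("counts must be integers")
  if (any(n1 < 1) || any(n2 < 1))
    stop("library sizes must be positive")
  vapply(seq_len(len), function(i) ac_p2_one(x[i], y[i], n1[i], n2[i]),
         numeric(1))
}

#' Audic-Claverie conditional probability mass
#'
#' `P(k | x)` for observing `k` reads in a library of size `n2` given `x`
#' reads in a library of size `n1`, evaluated in log space.
#'
#' @param k Non-negative integer count(s) at which to evaluate the mass.
#' @inheritParams audic_pvalue
#' @return Numeric vector of probabilities.
#' @export
audic_pmf <- function(k, x, n1, n2) {
  if (any(k < 0) || any(x < 0)) stop("counts must be non-negative")
  if (any(n1 < 1) || any(n2 < 1)) stop("library sizes must be positive")
  exp(ac_logpmf(k, x, log(n2) - log(n1), log(n1 + n2) - log(n1)))
}

# log P(k|x); lr = log(n2/n1), l1pr = log(1 + n2/n1), both supplied in the
# cancellation-free forms log(n2)-log(n1) and log(n1+n2)-log(n1)
ac_logpmf <- function(k, x, lr, l1pr) {
  lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) + k * lr -
    (x + k + 1) * l1pr
}

ac_p2_one <- function(x, y, n1, n2) {
  lr <- log(n2) - log(n1)
  l1pr <- log(n1 + n2) - log(n1)
  log_py <- ac_logpmf(y, x, lr, l1pr)
  py <- exp(log_py)
  mode_k <- floor(exp(lr) * x)  # terms increase while k < (n2/n1)*x
  # The tail on the far side of the mode from y has monotonically decreasing
  # terms moving away from y, so it can be summed outward from y (relative to
  # P(y|x)) and truncated once terms are negligible; the complementary tail
  # is recovered through S(y) = 1 - F(y) + P(y|x), which never subtracts two
  # nearly equal numbers because the directly summed tail is the smaller one.
  if (y <= mode_k) {
    lower <- exp(log_py + log(ac_tail_rel(x, y, lr, l1pr, log_py, -1L)))
    upper <- 1 - lower + py
  } else {
    upper <- exp(log_py + log(ac_tail_rel(x, y, lr, l1pr, log_py, +1L)))
    lower <- 1 - upper + py
  }
  lower <- min(max(lower, 0), 1)
  upper <- min(max(upper, 0), 1)
  p <- min(1, 2 * min(lower, upper))
  if (p <= 0) p <- .Machine$double.xmin
  p
}

# sum_{k in tail} P(k|x) / P(y|x), the tail running from y downward
# (direction -1, stopping at 0) or upward (direction +1)
ac_tail_rel <- function(x, y, lr, l1pr, log_py, direction) {
  if (!is.finite(log_py)) return(1)  # underflowed point mass; caller floors p
  rel_sum <- 0
  offset <- 0L
  chunk <- 256L
  repeat {
    ks <- y + direction * (offset + seq_len(chunk) - 1L)
    ks <- ks[ks >= 0]
    if (length(ks) == 0) break
    rel <- exp(ac_logpmf(ks, x, lr, l1pr) - log_py)
    rel_sum <- rel_sum + sum(rel)
    if (rel[length(rel)] < 1e-18 || length(ks) < chunk) break
    offset <- offset + chunk
  }
  rel_sum
}

#' False discovery rate adjustment
#'
#' Benjamini-Hochberg step-up q-values (default), or the Benjamini-Yekutieli
#' variant, in the input order. Thin validated wrapper over
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values, each in (0, 1].
#' @param method `"BH"` (default) or `"BY"`.
#' @return q-values, same length and order as `p`; elementwise `q >= p`.
#' @export
bh_fdr <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = method)
}

#' Log2 expression ratio with zero-handling conventions
#'
#' `log2(a / b)` for two RPKM values, with the conventions used by the dual
#' significance criterion: `+Inf` when only `b` is zero, `-Inf` when only `a`
#' is zero, and `NA` when both are zero (the gene is not expressed and never
#' reaches the criterion).
#'
#' @param a,b Non-negative RPKM values; recycled to a common length.
#' @return Numeric vector, possibly containing `Inf`, `-Inf`, `NA`.
#' @examples
#' log2_ratio(66.32, 2.92)  # ~ 4.51
#' log2_ratio(5, 0)         # Inf
#' @export
log2_ratio <- function(a, b) {
  len <- max(length(a), length(b))
  a <- rep_len(a, len); b <- rep_len(b, len)
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
    stop("RPKM values must be non-negative")
  out <- rep(NA_real_, len)
  both <- a > 0 & b > 0
  out[both] <- log2(a[both] / b[both])
  out[a > 0 & b == 0] <- Inf
  out[a == 0 & b > 0] <- -Inf
  out
}

#' Genewise two-library test for one developmental stage
#'
#' Runs the Audic-Claverie test for every gene detected in at least one of the
#' two libraries (one per group) at the given stage, computes the
#' log2(group1/group2) RPKM ratio, and adjusts p-values across exactly the
#' genes tested at this stage (the per-stage FDR family).
#'
#' The test consumes raw mapped counts with the two libraries' total mapped
#' read counts; RPKM enters only the fold-change column.
#'
#' @param counts Integer count matrix, genes x libraries (row names = gene
#'   ids, column names = library ids).
#' @param rpkm Matching RPKM matrix, as from [compute_rpkm()].
#' @param libraries Library metadata with columns `library_id`, `group`,
#'   `stage`, `total_mapped_reads`.
#' @param stage Stage label to test; exactly one library per group must exist
#'   at this stage.
#' @param groups Character pair naming the two groups; the ratio is
#'   log2(first/second). Default `c("XX", "XY")`.
#' @param min_count Detection threshold: genes with fewer mapped reads than
#'   this in both libraries are not tested. Default 1.
#' @param fdr_method Passed to [bh_fdr()].
#' @return A data frame with one row per tested gene: `gene_id`, `x`, `y`,
#'   `n1`, `n2`, `rpkm_xx`, `rpkm_xy`, `log2_ratio`, `p_value`, `q_value`.
#' @export
test_stage <- function(counts, rpkm, libraries, stage,
                       groups = c("XX", "XY"), min_count = 1,
                       fdr_method = "BH") {
  pair <- stage_library_pair(libraries, stage, groups)
  x <- counts[, pair$lib1]
  y <- counts[, pair$lib2]
  keep <- x >= min_count | y >= min_count
  x <- x[keep]; y <- y[keep]
  p <- audic_pvalue(x, y, pair$n1, pair$n2)
  res <- data.frame(
    gene_id = rownames(counts)[keep],
    x = x, y = y, n1 = pair$n1, n2 = pair$n2,
    rpkm_xx = rpkm[keep, pair$lib1],
    rpkm_xy = rpkm[keep, pair$lib2],
    log2_ratio = log2_ratio(rpkm[keep, pair$lib1], rpkm[keep, pair$lib2]),
    p_value = p,
    q_value = bh_fdr(p, fdr_method),
    row.names = NULL
  )
  res
}

# resolve the (group1, group2) library pair at a stage; errors name the gap
stage_library_pair <- function(libraries, stage, groups) {
  if (length(groups) != 2)
    stop("exactly two group labels are required")
  at_stage <- libraries[libraries$stage == stage, , drop = FALSE]
  if (nrow(at_stage) == 0)
    stop("no libraries at stage '", stage, "'")
  pick <- function(g) {
    ids <- at_stage$library_id[at_stage$group == g]
    if (length(ids) != 1)
      stop("stage '", stage, "' must have exactly one '", g, "' library, found ",
           length(ids))
    ids
  }
  lib1 <- pick(groups[1]); lib2 <- pick(groups[2])
  list(
    lib1 = lib1, lib2 = lib2,
    n1 = at_stage$total_mapped_reads[at_stage$library_id == lib1],
    n2 = at_stage$total_mapped_reads[at_stage$library_id == lib2]
  )
}
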