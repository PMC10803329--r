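`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ratio of shared to total calls, as used in sibling-sharing summaries
#'
#' The presence/absence sharing statistic is a plain ratio: the number of
#' merged SV clusters seen in both members of a pair over the number seen in
#' either.  Exposed separately so that published count pairs can be pushed
#' through exactly the same arithmetic as cohort runs.
#'
#' @param n_shared clusters containing calls from both samples
#' @param n_total clusters containing a call from either sample
#' @return fraction in `[0, 1]`, `NA` when `n_total == 0`
#' @seealso [allele_sharing()]
#' @export
sharing_fraction <- function(n_shared, n_total) {
  stopifnot(n_shared >= 0, n_total >= 0, n_shared <= n_total | n_total == 0)
  ifelse(n_total == 0, NA_real_, n_shared / n_total)
}

#' Sharing fraction as a percentage rounded to two decimals
#' @inheritParams sharing_fraction
#' @export
sharing_percent <- function(n_shared, n_total) {
  round(100 * sharing_fraction(n_shared, n_total), 2)
}

#' Alleles-per-gene density rounded to two decimals
#'
#' @param n_alleles number of alleles overlapping the gene set
#' @param n_genes number of distinct genes overlapped
#' @export
allele_gene_density <- function(n_alleles, n_genes) {
  stopifnot(n_genes > 0)
  round(n_alleles / n_genes, 2)
}

#' Rejection (or singleton) rate as a percentage to one decimal
#'
#' @param n numerator count
#' @param total denominator count
#' @return percentage rounded to 1 decimal; `NA` when `total == 0`
#' @export
percent_of <- function(n, total) {
  ifelse(total == 0, NA_real_, round(100 * n / total, 1))
}

## IRanges helpers ------------------------------------------------------

# 0-based half-open (start, end) -> IRanges (1-based closed)
.ir <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

# union length of 0-based half-open intervals, clipped to [0, len)
.union_bp <- function(start, end, len = NULL) {
  if (length(start) == 0) return(0L)
  if (!is.null(len)) {
    start <- pmax(start, 0L); end <- pmin(end, len)
  }
  keep <- end > start
  if (!any(keep)) return(0L)
  sum(IRanges::width(IRanges::reduce(.ir(start[keep], end[keep]))))
}

# gap distance between two 0-based half-open intervals (0 if overlapping)
.gap_dist <- function(s1, e1, s2, e2) {
  pmax(pmax(s2 - e1, s1 - e2), 0L)
}

.random_dna <- function(n) {
  # raw-byte construction: much faster than paste(collapse = "") at Mbp scale
  rawToChar(as.raw(sample(c(65L, 67L, 71L, 84L), n, replace = TRUE)))
}

.stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
}
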