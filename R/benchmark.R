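#' Read structural-variant calls from a VCF
#'
#' Extracts SV records (INFO `SVTYPE`, `SVLEN`, `END`; FORMAT `GT`) into a
#' long per-sample table; only carrier genotypes (copy number of the ALT
#' allele at least 1) produce rows.  An INFO `MAF` field, when present, is
#' carried through for frequency stratification.
#'
#' @param path VCF 4.x file
#' @return data.frame with `call_id`, `sample_id`, `chrom`, `pos` (1-based),
#'   `start` (0-based), `end`, `svtype`, `svlen`, `cn`, `maf`
#' @export
read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_get <- function(key) vcfR::extract.info(v, element = key)
  svtype <- info_get("SVTYPE")
  svlen <- suppressWarnings(as.numeric(info_get("SVLEN")))
  end <- suppressWarnings(as.numeric(info_get("END")))
  maf <- suppressWarnings(as.numeric(info_get("MAF")))
  gt <- vcfR::extract.gt(v, element = "GT")
  cn <- matrix(0L, nrow = nrow(gt), ncol = ncol(gt), dimnames = dimnames(gt))
  cn[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  cn[gt %in% c("1/1", "1|1")] <- 2L
  carriers <- which(cn > 0L, arr.ind = TRUE)
  pos <- as.integer(fix$POS)
  data.frame(
    call_id = paste0(fix$ID[carriers[, 1]], "@", colnames(gt)[carriers[, 2]]),
    sample_id = colnames(gt)[carriers[, 2]],
    chrom = fix$CHROM[carriers[, 1]],
    pos = pos[carriers[, 1]],
    start = pos[carriers[, 1]] - 1L,
    end = as.integer(end[carriers[, 1]]),
    svtype = svtype[carriers[, 1]],
    svlen = svlen[carriers[, 1]],
    cn = cn[carriers],
    maf = maf[carriers[, 1]],
    stringsAsFactors = FALSE)
}

#' Derive benchmark-eligible graph SV calls from a genotype matrix
#'
#' Restricts to biallelic bubbles (exactly two alleles in the matrix), takes
#' the less common of the two alleles as ALT (ties broken toward the
#' non-reference, then the lexicographically later key), flags the
#' star-deletion subset (ALT is the direct source-to-sink edge), and removes
#' calls whose backbone interval lies less than `gap_dist_bp` away from a
#' reference assembly gap.  One call per diploid sample carrying the ALT.
#'
#' @param gm a `genotype_matrix` built with `bubbles`
#' @param reference_gaps optional data.frame `chrom`, `start`, `end` of
#'   reference gaps
#' @param gap_dist_bp exclusion distance from gaps (default 100)
#' @return data.frame of graph calls with `graph_id`, `bubble_id`,
#'   `sample_id`, `chrom`, `start`, `end`, `cn`, `is_star_deletion`, `maf`
#' @export
graph_calls_for_benchmark <- function(gm, reference_gaps = NULL, gap_dist_bp = 100L) {
  tab <- table(gm$alleles$bubble_id)
  biallelic <- names(tab)[tab == 2L]
  keep_col <- gm$samples$cohort != "reference"
  out <- list()
  for (b in biallelic) {
    rows <- which(gm$alleles$bubble_id == b)
    counts <- rowSums(gm$geno[rows, keep_col, drop = FALSE])
    alt_local <- if (counts[1] != counts[2]) {
      which.min(counts)
    } else {
      nonref <- which(!gm$alleles$is_reference[rows])
      if (length(nonref) == 1L) nonref else which.max(xtfrm(gm$alleles$allele_key[rows]))
    }
    alt_row <- rows[alt_local]
    key <- gm$alleles$allele_key[alt_row]
    star <- length(strsplit(key, "+", fixed = TRUE)[[1]]) == 2L
    carriers <- gm$geno[alt_row, , drop = TRUE] > 0L
    samp <- unique(gm$samples$sample_id[carriers[gm$samples$hap_id] &
                                          gm$samples$cohort != "reference"])
    if (!length(samp)) next
    cn <- vapply(samp, function(s) {
      cols <- gm$samples$hap_id[gm$samples$sample_id == s]
      sum(gm$geno[alt_row, cols])
    }, integer(1))
    out[[b]] <- data.frame(
      graph_id = paste0(b, "@", samp),
      bubble_id = b, sample_id = samp,
      chrom = gm$alleles$chrom[alt_row],
      start = gm$alleles$start[alt_row],
      end = pmax(gm$alleles$end[alt_row], gm$alleles$start[alt_row] + 1L),
      cn = cn,
      is_star_deletion = star,
      maf = sum(counts[alt_local]) / sum(keep_col),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(graph_id = character(), bubble_id = character(),
               sample_id = character(), chrom = character(), start = integer(),
               end = integer(), cn = integer(), is_star_deletion = logical(),
               maf = numeric())
  rownames(res) <- NULL
  if (!is.null(reference_gaps) && nrow(res)) {
    near <- rep(FALSE, nrow(res))
    for (chrom in unique(res$chrom)) {
      ri <- which(res$chrom == chrom)
      gi <- which(reference_gaps$chrom == chrom)
      if (!length(gi)) next
      d <- IRanges::distance(
        .ir(res$start[ri], res$end[ri])[rep(seq_along(ri), each = length(gi))],
        .ir(reference_gaps$start[gi], reference_gaps$end[gi])[rep(seq_along(gi), length(ri))])
      near[ri] <- rowSums(matrix(d < gap_dist_bp, nrow = length(ri), byrow = TRUE)) > 0L
    }
    res <- res[!near, , drop = FALSE]
  }
  res[order(res$sample_id, res$chrom, res$start), , drop = FALSE]
}

# one-to-one nearest matching between two interval sets (same sample/chrom
# blocks): returns pairs (ai, bi, distance); ties broken by leftmost.
.match_interval_sets <- function(a, b, window_bp) {
  pairs <- list()
  blocks <- unique(rbind(a[, c("sample_id", "chrom")], b[, c("sample_id", "chrom")]))
  for (k in seq_len(nrow(blocks))) {
    ai <- which(a$sample_id == blocks$sample_id[k] & a$chrom == blocks$chrom[k])
    bi <- which(b$sample_id == blocks$sample_id[k] & b$chrom == blocks$chrom[k])
    if (!length(ai) || !length(bi)) next
    h <- IRanges::findOverlaps(.ir(a$start[ai], a$end[ai]),
                               .ir(b$start[bi], b$end[bi]), maxgap = window_bp)
    if (!length(h)) next
    qa <- ai[S4Vectors::queryHits(h)]
    qb <- bi[S4Vectors::subjectHits(h)]
    d <- .gap_dist(a$start[qa], a$end[qa], b$start[qb], b$end[qb])
    ord <- order(d, b$start[qb], a$start[qa])
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    for (j in ord) {
      if (used_a[qa[j]] || used_b[qb[j]]) next
      used_a[qa[j]] <- TRUE; used_b[qb[j]] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(qa[j], qb[j], d[j])
    }
  }
  if (!length(pairs)) {
    return(data.frame(ai = integer(), bi = integer(), distance = integer()))
  }
  m <- do.call(rbind, pairs)
  data.frame(ai = m[, 1], bi = m[, 2], distance = m[, 3])
}

#' Match graph SV calls with reference-based SV calls
#'
#' A reference call (non-BND, `|svlen| > min_sv_bp`) matches a graph call of
#' the same sample when the gap distance between the two breakpoint
#' intervals is at most `window_bp` (0 when they overlap).  Matching is
#' one-to-one: candidate pairs are assigned nearest-first with leftmost
#' tie-break, so the result is symmetric in the distance and invariant to
#' input order.
#'
#' @param graph_calls output of [graph_calls_for_benchmark()]
#' @param ref_calls output of [read_sv_vcf()] (or equivalent table)
#' @param window_bp maximum gap distance (default 100)
#' @param min_sv_bp reference calls at most this long are ignored
#'   (strict; default 50)
#' @return list with `pairs` (data.frame `graph_id`, `ref_id`, `sample_id`,
#'   `distance`), `n_graph`, `n_ref` (eligible counts) and `n_matched`
#' @export
match_calls <- function(graph_calls, ref_calls, window_bp = 100L, min_sv_bp = 50L) {
  ga <- attr(graph_calls, "genome"); gb <- attr(ref_calls, "genome")
  if (!is.null(ga) && !is.null(gb) && !identical(ga, gb)) {
    stop("call sets are on different reference backbones: ", ga, " vs ", gb)
  }
  ref <- ref_calls[ref_calls$svtype != "BND" & abs(ref_calls$svlen) > min_sv_bp, ,
                   drop = FALSE]
  g <- graph_calls[order(graph_calls$sample_id, graph_calls$chrom, graph_calls$start), ,
                   drop = FALSE]
  r <- ref[order(ref$sample_id, ref$chrom, ref$start), , drop = FALSE]
  r$end2 <- ifelse(is.na(r$end), r$start + 1L, pmax(r$end, r$start + 1L))
  rr <- data.frame(sample_id = r$sample_id, chrom = r$chrom,
                   start = r$start, end = r$end2)
  gg <- g[, c("sample_id", "chrom", "start", "end")]
  m <- .match_interval_sets(gg, rr, window_bp)
  list(pairs = data.frame(graph_id = g$graph_id[m$ai],
                          ref_id = r$call_id[m$bi],
                          sample_id = g$sample_id[m$ai],
                          distance = m$distance,
                          stringsAsFactors = FALSE),
       n_graph = nrow(g), n_ref = nrow(r), n_matched = nrow(m))
}

#' Recall and precision of graph calls against a reference callset
#'
#' Treating the reference calls as ground truth, recall is the number of
#' matched calls over the total reference calls and precision the number of
#' matched calls over the total graph calls.  Undefined ratios (zero
#' denominator) are reported as `NA`, never 0.
#'
#' @param matches output of [match_calls()], or a matched count
#' @param n_graph,n_ref totals (taken from `matches` when omitted)
#' @return list with `R` and `P`
#' @export
recall_precision <- function(matches, n_graph = NULL, n_ref = NULL) {
  if (is.list(matches) && !is.null(matches$n_matched)) {
    n_matched <- matches$n_matched
    n_graph <- n_graph %||% matches$n_graph
    n_ref <- n_ref %||% matches$n_ref
  } else n_matched <- matches
  list(R = if (n_ref > 0) n_matched / n_ref else NA_real_,
       P = if (n_graph > 0) n_matched / n_graph else NA_real_)
}

#' Region-stratified recall/precision
#'
#' Clusters all calls (graph and reference) into regions separated by more
#' than `region_gap_bp`, computes per-region recall and precision, and
#' averages over the regions having at least one call from each caller.
#'
#' @param matches output of [match_calls()]
#' @param graph_calls,ref_calls the call tables given to [match_calls()]
#' @param region_gap_bp gap separating regions (default 1000)
#' @return list with `per_region` data.frame and `mean_R`, `mean_P`
#' @export
benchmark_by_region <- function(matches, graph_calls, ref_calls,
                                region_gap_bp = 1000L) {
  pts <- rbind(data.frame(id = graph_calls$graph_id, caller = "graph",
                          chrom = graph_calls$chrom, start = graph_calls$start,
                          end = graph_calls$end, stringsAsFactors = FALSE),
               data.frame(id = ref_calls$call_id, caller = "ref",
                          chrom = ref_calls$chrom, start = ref_calls$start,
                          end = pmax(ifelse(is.na(ref_calls$end),
                                            ref_calls$start + 1L, ref_calls$end),
                                     ref_calls$start + 1L),
                          stringsAsFactors = FALSE))
  pts$region <- NA_integer_
  nreg <- 0L
  for (chrom in unique(pts$chrom)) {
    ci <- which(pts$chrom == chrom)
    ord <- ci[order(pts$start[ci])]
    brk <- c(0, cumsum(diff(pts$start[ord]) > region_gap_bp))
    pts$region[ord] <- nreg + brk + 1L
    nreg <- nreg + max(brk) + 1L
  }
  matched_graph <- unique(matches$pairs$graph_id)
  matched_ref <- unique(matches$pairs$ref_id)
  per <- do.call(rbind, lapply(split(pts, pts$region), function(d) {
    n_g <- sum(d$caller == "graph"); n_r <- sum(d$caller == "ref")
    n_m <- sum(d$id %in% c(matched_graph) & d$caller == "graph")
    data.frame(region = d$region[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end),
               n_graph = n_g, n_ref = n_r,
               R = if (n_r) min(n_m, n_r) / n_r else NA_real_,
               P = if (n_g) n_m / n_g else NA_real_)
  }))
  both <- per$n_graph > 0 & per$n_ref > 0
  list(per_region = per,
       mean_R = mean(per$R[both]), mean_P = mean(per$P[both]))
}

#' Recall of chromosomal-microarray intervals by graph SV alleles
#'
#' For each sufficiently covered sample, reports the fraction of its CMA
#' intervals that overlap a non-reference graph SV allele (any-bp).
#'
#' @param cma_intervals data.frame `sample_id`, `chrom`, `start`, `end`
#' @param sv_intervals data.frame `sample_id`, `chrom`, `start`, `end` of
#'   the sample's non-reference allele loci
#' @param coverage optional named vector of per-sample sequencing depth
#' @param min_depth samples below this depth are excluded (default 20)
#' @return list with `per_sample` (fractions), `mean`, `median`
#' @export
cma_recall <- function(cma_intervals, sv_intervals, coverage = NULL,
                       min_depth = 20) {
  samples <- unique(cma_intervals$sample_id)
  if (!is.null(coverage)) {
    samples <- samples[samples %in% names(coverage)[coverage >= min_depth]]
  }
  per <- do.call(rbind, lapply(samples, function(s) {
    ci <- cma_intervals[cma_intervals$sample_id == s, , drop = FALSE]
    si <- sv_intervals[sv_intervals$sample_id == s, , drop = FALSE]
    hit <- vapply(seq_len(nrow(ci)), function(k) {
      sj <- si[si$chrom == ci$chrom[k], , drop = FALSE]
      if (!nrow(sj)) return(FALSE)
      any(IRanges::overlapsAny(.ir(ci$start[k], ci$end[k]),
                               .ir(sj$start, sj$end)))
    }, logical(1))
    data.frame(sample_id = s, n_intervals = nrow(ci), n_overlapped = sum(hit),
               fraction = sum(hit) / nrow(ci), stringsAsFactors = FALSE)
  }))
  if (is.null(per)) per <- data.frame(sample_id = character(), n_intervals = integer(),
                                      n_overlapped = integer(), fraction = numeric())
  list(per_sample = per, mean = mean(per$fraction), median = median(per$fraction))
}
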