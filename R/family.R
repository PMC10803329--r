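#' Read a 6-column PED pedigree file
#'
#' @param path PED file (family, individual, father, mother, sex, phenotype;
#'   `0` for unknown parents)
#' @return data.frame with those columns
#' @export
read_ped <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("family_id", "sample_id", "father_id", "mother_id", "sex",
                 "phenotype")
  if (any(df$sample_id == df$father_id | df$sample_id == df$mother_id)) {
    stop("pedigree lists a sample as its own parent")
  }
  df
}

#' Sibling pairs sharing both listed parents
#'
#' @param ped pedigree data.frame from [read_ped()]
#' @return data.frame with `family_id`, `sample1`, `sample2`
#' @export
sibling_pairs <- function(ped) {
  kids <- ped[ped$father_id != "0" & ped$mother_id != "0", , drop = FALSE]
  key <- paste(kids$father_id, kids$mother_id)
  out <- do.call(rbind, lapply(split(kids, key), function(d) {
    if (nrow(d) < 2L) return(NULL)
    cmb <- utils::combn(d$sample_id, 2L)
    data.frame(family_id = d$family_id[1], sample1 = cmb[1, ], sample2 = cmb[2, ],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(family_id = character(),
                                      sample1 = character(), sample2 = character())
  rownames(out) <- NULL
  out
}

#' Merge reference-based SV calls across samples by breakpoint proximity
#'
#' Calls shorter than `min_size_bp` are discarded.  Within each chromosome
#' and SV type, two calls satisfy the merge predicate when both their start
#' and their end breakpoints lie within `max_dist_frac` times the longer of
#' the two SV lengths.  Clusters are the connected components of this
#' pairwise relation (single linkage, computed with a sorted sweep and
#' union-find), which makes the result order-independent and identical to a
#' brute-force transitive closure.
#'
#' @param calls data.frame with `call_id`, `sample_id`, `chrom`, `svtype`,
#'   `start`, `end`, `svlen` (and optionally `cn`, `maf`)
#' @param min_size_bp minimum |svlen| retained (default 50)
#' @param max_dist_frac distance tolerance as a fraction of SV length
#'   (default 0.10)
#' @return data.frame of clusters: representative interval, `n_members`,
#'   list columns `members` (call ids), `samples`, and `cn_by_sample`
#'   (named vector of the maximum copy number per member sample)
#' @export
merge_ref_calls <- function(calls, min_size_bp = 50L, max_dist_frac = 0.10) {
  calls <- calls[abs(calls$svlen) >= min_size_bp, , drop = FALSE]
  if (!nrow(calls)) {
    out <- data.frame(cluster_id = character(), chrom = character(),
                      svtype = character(), start = integer(), end = integer(),
                      n_members = integer())
    out$members <- list(); out$samples <- list(); out$cn_by_sample <- list()
    return(out)
  }
  calls <- calls[order(calls$chrom, calls$svtype, calls$start, calls$end,
                       calls$call_id), , drop = FALSE]
  parent <- seq_len(nrow(calls))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  blocks <- split(seq_len(nrow(calls)), paste(calls$chrom, calls$svtype))
  for (idx in blocks) {
    if (length(idx) < 2L) next
    maxlen <- max(abs(calls$svlen[idx]))
    for (u in seq_along(idx)[-length(idx)]) {
      i <- idx[u]
      for (v in (u + 1L):length(idx)) {
        j <- idx[v]
        if (calls$start[j] - calls$start[i] > max_dist_frac * maxlen) break
        tol <- max_dist_frac * max(abs(calls$svlen[i]), abs(calls$svlen[j]))
        if (abs(calls$start[i] - calls$start[j]) <= tol &&
            abs(calls$end[i] - calls$end[j]) <= tol) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(nrow(calls)), find, integer(1))
  groups <- split(seq_len(nrow(calls)), roots)
  out <- do.call(rbind, lapply(groups, function(g) {
    rep_i <- g[1]
    data.frame(cluster_id = NA_character_, chrom = calls$chrom[rep_i],
               svtype = calls$svtype[rep_i],
               start = calls$start[rep_i], end = calls$end[rep_i],
               n_members = length(g), stringsAsFactors = FALSE)
  }))
  out$members <- lapply(groups, function(g) calls$call_id[g])
  out$samples <- lapply(groups, function(g) unique(calls$sample_id[g]))
  out$cn_by_sample <- lapply(groups, function(g) {
    if (is.null(calls$cn)) return(NULL)
    tapply(calls$cn[g], calls$sample_id[g], max)
  })
  out <- out[order(out$chrom, out$start, out$svtype), , drop = FALSE]
  out$cluster_id <- sprintf("mc%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Merge graph calls by bubble identity
#'
#' Graph alleles delimited by the same source and sink nodes (i.e. belonging
#' to the same bubble) form one cluster; a sample is a member when it
#' carries any non-reference allele of the bubble.
#'
#' @param gm a `genotype_matrix` built with `bubbles`
#' @return cluster data.frame in the same shape as [merge_ref_calls()]
#' @export
merge_graph_calls <- function(gm) {
  nonref <- which(!gm$alleles$is_reference)
  bubbles <- unique(gm$alleles$bubble_id[nonref])
  out <- do.call(rbind, lapply(bubbles, function(b) {
    rows <- nonref[gm$alleles$bubble_id[nonref] == b]
    carried <- colSums(gm$geno[rows, , drop = FALSE]) > 0L
    hap <- gm$samples$hap_id[gm$samples$cohort != "reference"]
    samp <- unique(gm$samples$sample_id[match(names(carried)[carried], gm$samples$hap_id)])
    cn <- vapply(samp, function(s) {
      cols <- gm$samples$hap_id[gm$samples$sample_id == s]
      as.integer(sum(gm$geno[rows, cols, drop = FALSE]))
    }, integer(1))
    d <- data.frame(cluster_id = b, chrom = gm$alleles$chrom[rows[1]],
                    svtype = "GRAPH", start = gm$alleles$start[rows[1]],
                    end = gm$alleles$end[rows[1]], n_members = length(rows),
                    stringsAsFactors = FALSE)
    d$members <- list(gm$alleles$row_id[rows])
    d$samples <- list(samp)
    d$cn_by_sample <- list(cn)
    d
  }))
  if (is.null(out)) {
    out <- data.frame(cluster_id = character(), chrom = character(),
                      svtype = character(), start = integer(), end = integer(),
                      n_members = integer())
    out$members <- list(); out$samples <- list(); out$cn_by_sample <- list()
  }
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Presence/absence allele sharing of a sample pair
#'
#' The fraction of merged SV clusters seen in both samples over those seen
#' in either (default), in both only over the intersection, or the Jaccard
#' variant (identical to `"union"`; kept for symmetry with other tools).
#'
#' @param pair character vector of two sample ids
#' @param clusters cluster table from [merge_ref_calls()] or
#'   [merge_graph_calls()]
#' @param denominator `"union"` (default) or `"intersection"`
#' @return list with `n_shared`, `n_total`, `fraction` (`NA` when the pair
#'   touches no clusters)
#' @export
allele_sharing <- function(pair, clusters, denominator = c("union", "intersection")) {
  denominator <- match.arg(denominator)
  stopifnot(length(pair) == 2L)
  in1 <- vapply(clusters$samples, function(s) pair[1] %in% s, logical(1))
  in2 <- vapply(clusters$samples, function(s) pair[2] %in% s, logical(1))
  n_shared <- sum(in1 & in2)
  n_total <- if (denominator == "union") sum(in1 | in2) else n_shared + 0L
  if (denominator == "intersection") n_total <- sum(in1 & in2)
  list(n_shared = n_shared, n_total = n_total,
       fraction = sharing_fraction(n_shared, n_total))
}

#' Permutation null for sibling allele sharing
#'
#' Permutes the second member across pairs (never reuniting a true pair when
#' a derangement is available), recomputes sharing for each permuted pair,
#' and returns the null distribution and its mean alongside the true values.
#'
#' @param pairs data.frame with `sample1`, `sample2`
#' @param clusters cluster table
#' @param n_permutations number of permutations (default 10)
#' @param seed integer seed; the same seed reproduces the same permutations
#' @return list with `true` (per-pair fractions), `true_mean`,
#'   `perm` (matrix permutation x pair), `perm_means`, `perm_mean`
#' @export
permute_sharing <- function(pairs, clusters, n_permutations = 10L, seed = 1L) {
  stopifnot(nrow(pairs) >= 2L)
  true <- vapply(seq_len(nrow(pairs)), function(i) {
    allele_sharing(c(pairs$sample1[i], pairs$sample2[i]), clusters)$fraction
  }, numeric(1))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- nrow(pairs)
  perm <- matrix(NA_real_, nrow = n_permutations, ncol = n)
  for (p in seq_len(n_permutations)) {
    for (try in 1:100) {
      idx <- sample.int(n)
      if (!any(idx == seq_len(n))) break
    }
    if (any(idx == seq_len(n))) {   # fall back: rotate (always a derangement)
      idx <- c(seq_len(n)[-1], 1L)
    }
    perm[p, ] <- vapply(seq_len(n), function(i) {
      allele_sharing(c(pairs$sample1[i], pairs$sample2[idx[i]]), clusters)$fraction
    }, numeric(1))
  }
  list(true = true, true_mean = mean(true, na.rm = TRUE),
       perm = perm, perm_means = rowMeans(perm, na.rm = TRUE),
       perm_mean = mean(perm, na.rm = TRUE))
}

#' Mendelian-consistency verdict for a trio genotype
#'
#' Given ALT copy numbers of proband, father and mother, the minimum number
#' of transmissible copies is the number of homozygous parents and the
#' maximum is the number of carrier parents.  A proband below the minimum is
#' a false negative (a call the caller must have missed), above the maximum
#' a false positive (more copies than the parents can transmit); anything
#' else is consistent.  Vectorized.
#'
#' @param proband_cn,father_cn,mother_cn copy numbers in `{0, 1, 2}`
#' @return character vector of verdicts: `"consistent"`, `"false_negative"`
#'   or `"false_positive"`
#' @export
mendelian_verdict <- function(proband_cn, father_cn, mother_cn) {
  cn <- c(proband_cn, father_cn, mother_cn)
  if (any(!cn %in% 0:2)) stop("copy numbers must be in {0, 1, 2}")
  min_t <- (father_cn == 2L) + (mother_cn == 2L)
  max_t <- (father_cn >= 1L) + (mother_cn >= 1L)
  ifelse(proband_cn < min_t, "false_negative",
         ifelse(proband_cn > max_t, "false_positive", "consistent"))
}

#' Mendelian verdicts over merged trio SV clusters
#'
#' Merges the trio's reference-based calls, extracts the per-member copy
#' number of each cluster (0 when absent), and classifies every cluster.
#'
#' @param calls reference-based calls of the three trio members (with `cn`)
#' @param proband,father,mother sample ids
#' @param ... passed to [merge_ref_calls()]
#' @return data.frame with `cluster_id`, the three copy numbers and
#'   `verdict`
#' @export
trio_verdicts <- function(calls, proband, father, mother, ...) {
  trio <- calls[calls$sample_id %in% c(proband, father, mother), , drop = FALSE]
  cl <- merge_ref_calls(trio, ...)
  cn_of <- function(cns, who) {
    v <- cns[who]
    if (is.null(cns) || is.na(v)) 0L else as.integer(v)
  }
  out <- data.frame(cluster_id = cl$cluster_id,
                    proband_cn = vapply(cl$cn_by_sample, cn_of, integer(1), proband),
                    father_cn = vapply(cl$cn_by_sample, cn_of, integer(1), father),
                    mother_cn = vapply(cl$cn_by_sample, cn_of, integer(1), mother),
                    stringsAsFactors = FALSE)
  out$verdict <- mendelian_verdict(out$proband_cn, out$father_cn, out$mother_cn)
  out
}
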