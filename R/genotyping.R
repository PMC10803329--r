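#' Ingest a per-haplotype bubble call track
#'
#' The call track is a BED-like TSV with one record per traversed bubble:
#' backbone chrom, start, end, node-path string (`">n1>n2>..."`, or `"."` for
#' the reference allele) and the supporting interval on the sample assembly
#' (`contig:start-end`).  `"."` paths are resolved to the bubble's reference
#' allele key, which is why the bubble table is required.
#'
#' @param input file path, character vector of lines, or a data.frame with
#'   the five columns
#' @param sample_id sample identifier
#' @param haplotype 1 or 2
#' @param bubbles bubble table from [detect_bubbles()] (or the generator
#'   truth), used to resolve reference-allele records
#' @return data.frame of calls with `hap_id`, `sample_id`, `haplotype`,
#'   `bubble_id`, `allele_key`, coordinates, support interval and a
#'   `validity` column initialised to `"unknown"`
#' @export
ingest_calls <- function(input, sample_id, haplotype, bubbles) {
  stopifnot(haplotype %in% c(1L, 2L))
  if (is.data.frame(input)) {
    df <- input
    names(df)[1:5] <- c("chrom", "start", "end", "path", "support")
  } else {
    lines <- if (length(input) == 1L && file.exists(input)) readLines(input) else input
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
      df <- data.frame(chrom = character(), start = integer(), end = integer(),
                       path = character(), support = character())
    } else {
      f <- strsplit(lines, "\t", fixed = TRUE)
      bad <- which(lengths(f) < 5L)
      if (length(bad)) stop("malformed call record at line ", bad[1])
      df <- data.frame(chrom = vapply(f, `[`, "", 1),
                       start = as.integer(vapply(f, `[`, "", 2)),
                       end = as.integer(vapply(f, `[`, "", 3)),
                       path = vapply(f, `[`, "", 4),
                       support = vapply(f, `[`, "", 5),
                       stringsAsFactors = FALSE)
    }
  }
  bkey <- paste(bubbles$chrom, bubbles$start, bubbles$end)
  i <- match(paste(df$chrom, df$start, df$end), bkey)
  if (anyNA(i)) {
    stop("call record at line ", which(is.na(i))[1],
         " does not correspond to any bubble")
  }
  ok_path <- df$path == "." | grepl("^(>[^>[:space:]]+){2,}$", df$path)
  if (any(!ok_path)) {
    stop("malformed path token at line ", which(!ok_path)[1], ": ",
         df$path[which(!ok_path)[1]])
  }
  allele_key <- ifelse(df$path == ".",
                       bubbles$ref_allele_key[i],
                       gsub(">", "+", sub("^>", "", df$path), fixed = TRUE))
  sup <- regmatches(df$support, regexec("^(.+):([0-9]+)-([0-9]+)$", df$support))
  bad <- which(lengths(sup) != 4L)
  if (length(bad)) stop("malformed support interval at line ", bad[1])
  data.frame(hap_id = paste0(sample_id, ".h", haplotype),
             sample_id = sample_id, haplotype = as.integer(haplotype),
             bubble_id = bubbles$bubble_id[i],
             allele_key = allele_key,
             chrom = df$chrom, start = df$start, end = df$end,
             support_contig = vapply(sup, `[`, "", 2),
             support_start = as.integer(vapply(sup, `[`, "", 3)),
             support_end = as.integer(vapply(sup, `[`, "", 4)),
             validity = "unknown",
             stringsAsFactors = FALSE)
}

.validity_levels <- c("haploid", "unknown", "duplicated", "collapsed", "error")

#' Assign assembly-validity labels to calls
#'
#' A call is `haploid` (reliable) if and only if its support interval lies
#' entirely within haploid-labelled intervals of the assembly validity
#' track.  Otherwise it is labelled by the worst overlapping label, with
#' precedence `error > collapsed > duplicated > unknown`.  Invalid calls are
#' flagged, never deleted.  Calls on contigs absent from the track are
#' labelled `unknown` with a warning.
#'
#' @param calls call table from [ingest_calls()]
#' @param track data.frame with `contig`, `start`, `end`, `label`
#' @return `calls` with the `validity` column filled in
#' @export
apply_validity <- function(calls, track) {
  stopifnot(all(track$label %in% c("haploid", "error", "collapsed", "duplicated")))
  by_contig <- split(track, track$contig)
  missing_contigs <- setdiff(unique(calls$support_contig), names(by_contig))
  if (length(missing_contigs)) {
    warning("contig(s) absent from validity track: ",
            paste(missing_contigs, collapse = ", "))
  }
  out <- calls
  for (ctg in intersect(unique(calls$support_contig), names(by_contig))) {
    tr <- by_contig[[ctg]]
    ci <- which(calls$support_contig == ctg)
    hap <- tr[tr$label == "haploid", , drop = FALSE]
    hap_red <- IRanges::reduce(.ir(hap$start, hap$end))
    qry <- .ir(calls$support_start[ci], calls$support_end[ci])
    within <- IRanges::overlapsAny(qry, hap_red, type = "within")
    lab <- rep("unknown", length(ci))
    lab[within] <- "haploid"
    notin <- which(!within)
    if (length(notin)) {
      bad <- tr[tr$label != "haploid", , drop = FALSE]
      if (nrow(bad)) {
        hits <- IRanges::findOverlaps(qry[notin], .ir(bad$start, bad$end))
        if (length(hits)) {
          worst <- tapply(bad$label[S4Vectors::subjectHits(hits)],
                          S4Vectors::queryHits(hits),
                          function(l) .validity_levels[max(match(l, .validity_levels))])
          lab[notin[as.integer(names(worst))]] <- unname(worst)
        }
      }
    }
    out$validity[ci] <- lab
  }
  out
}

#' Build the binary allele-by-haplotype genotype matrix
#'
#' Rows are the distinct `(bubble, allele)` pairs among retained calls,
#' columns are haplotype samples, and a cell is 1 when that haplotype was
#' observed to carry that allele.  Within a bubble each column has at most
#' one 1 (a haplotype traverses one path).  When `keep_only_valid` is set
#' (the default), calls whose validity is not `haploid` contribute neither a
#' 1 nor "observed data": a companion missingness mask records, per bubble
#' and haplotype, whether usable data exist, so that allele frequencies can
#' be computed over haplotypes-with-data rather than all haplotypes.
#'
#' @param calls combined call table over all samples (after
#'   [apply_validity()] if validity filtering is wanted)
#' @param cohorts named character vector mapping `sample_id` to a cohort
#'   label; the label `"reference"` marks pseudo-samples excluded from
#'   frequency denominators
#' @param keep_only_valid drop (mask) calls not labelled `haploid`
#' @param bubbles optional bubble table used to flag reference-allele rows
#' @return object of class `genotype_matrix`: list with `geno` (integer
#'   matrix), `alleles` (row metadata), `samples` (column metadata), `mask`
#'   (bubble-by-haplotype logical matrix of data presence)
#' @export
build_matrix <- function(calls, cohorts, keep_only_valid = TRUE, bubbles = NULL) {
  dup <- duplicated(calls[, c("hap_id", "bubble_id")])
  if (any(dup)) {
    d <- calls[dup, ][1, ]
    both <- calls[calls$hap_id == d$hap_id & calls$bubble_id == d$bubble_id, ]
    if (length(unique(both$allele_key)) > 1L) {
      stop("conflicting calls for ", d$hap_id, " at ", d$bubble_id, ": ",
           paste(unique(both$allele_key), collapse = " vs "))
    }
    calls <- calls[!dup, , drop = FALSE]
  }
  retained <- if (keep_only_valid) calls[calls$validity == "haploid", , drop = FALSE] else calls

  hap_ids <- sort(unique(calls$hap_id))
  samples <- data.frame(hap_id = hap_ids,
                        sample_id = sub("\\.h[12]$", "", hap_ids),
                        haplotype = as.integer(sub("^.*\\.h", "", hap_ids)),
                        stringsAsFactors = FALSE)
  if (!all(samples$sample_id %in% names(cohorts))) {
    stop("cohort label missing for sample(s): ",
         paste(setdiff(samples$sample_id, names(cohorts)), collapse = ", "))
  }
  samples$cohort <- unname(cohorts[samples$sample_id])

  akey <- paste(retained$bubble_id, retained$allele_key, sep = "\r")
  ukeys <- unique(akey)
  meta <- retained[match(ukeys, akey),
                   c("bubble_id", "allele_key", "chrom", "start", "end"), drop = FALSE]
  ord <- order(meta$chrom, meta$start, meta$allele_key)
  meta <- meta[ord, , drop = FALSE]
  rownames(meta) <- NULL
  meta$row_id <- paste(meta$bubble_id, meta$allele_key, sep = ":")
  if (!is.null(bubbles)) {
    meta$is_reference <- meta$allele_key ==
      bubbles$ref_allele_key[match(meta$bubble_id, bubbles$bubble_id)]
  } else meta$is_reference <- NA

  geno <- matrix(0L, nrow = nrow(meta), ncol = length(hap_ids),
                 dimnames = list(meta$row_id, hap_ids))
  ri <- match(paste(retained$bubble_id, retained$allele_key, sep = "\r"),
              paste(meta$bubble_id, meta$allele_key, sep = "\r"))
  geno[cbind(ri, match(retained$hap_id, hap_ids))] <- 1L

  bub_ids <- sort(unique(calls$bubble_id))
  mask <- matrix(FALSE, nrow = length(bub_ids), ncol = length(hap_ids),
                 dimnames = list(bub_ids, hap_ids))
  mask[cbind(match(retained$bubble_id, bub_ids),
             match(retained$hap_id, hap_ids))] <- TRUE

  structure(list(geno = geno, alleles = meta, samples = samples, mask = mask),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "alleles x", ncol(x$geno),
      "haplotypes;", length(unique(x$alleles$bubble_id)), "bubbles\n")
  cat("  cohorts:", paste(sprintf("%s=%d", names(table(x$samples$cohort)),
                                  table(x$samples$cohort)), collapse = ", "), "\n")
  invisible(x)
}

#' Cohort partition and allele-frequency spectrum
#'
#' Assigns each non-reference allele to a partition (shared between the two
#' cohorts, or private to one), computes carrier counts and frequencies, and
#' bins the frequency spectrum.  Columns whose cohort label is
#' `"reference"` are excluded from all counts and denominators.  With
#' `missing_aware = TRUE` (default) frequencies are carriers over
#' haplotypes-with-data at the allele's bubble; otherwise over all non-
#' reference haplotypes.  The partition counts always satisfy
#' `shared + A_only + B_only == total` (asserted).
#'
#' @param gm a `genotype_matrix`
#' @param bin_edges frequency bin edges; defaults include the 10% and 90%
#'   thresholds used for rare/near-fixed summaries
#' @param missing_aware use per-bubble haplotypes-with-data denominators
#' @param include_reference_alleles also report reference-path alleles
#' @return list with `records` (per-allele data.frame: `count`, `n_data`,
#'   `frequency`, `partition`, `is_singleton`), `spectrum` (per-bin counts)
#'   and `summary`
#' @export
partition_and_spectrum <- function(gm, bin_edges = c(0, 0.01, 0.05, 0.1, 0.5, 0.9, 1),
                                   missing_aware = TRUE,
                                   include_reference_alleles = FALSE) {
  keep_col <- gm$samples$cohort != "reference"
  cohort_levels <- sort(unique(gm$samples$cohort[keep_col]))
  if (length(cohort_levels) > 2L) {
    stop("partitioning expects at most two non-reference cohorts")
  }
  keep_row <- if (include_reference_alleles) rep(TRUE, nrow(gm$geno)) else !gm$alleles$is_reference
  keep_row[is.na(keep_row)] <- TRUE
  g <- gm$geno[keep_row, keep_col, drop = FALSE]
  meta <- gm$alleles[keep_row, , drop = FALSE]
  if (nrow(g) == 0L) {
    return(list(records = cbind(meta, count = integer(), n_data = integer(),
                                frequency = numeric(), partition = character(),
                                is_singleton = logical())[0, ],
                spectrum = data.frame(bin_lo = numeric(), bin_hi = numeric(), n = integer()),
                summary = list(n_total = 0L, n_shared = 0L, n_singletons = 0L)))
  }
  count <- as.integer(rowSums(g))
  in_cohort <- sapply(cohort_levels, function(cl) {
    rowSums(g[, gm$samples$cohort[keep_col] == cl, drop = FALSE]) > 0
  })
  if (is.null(dim(in_cohort))) in_cohort <- matrix(in_cohort, nrow = 1)
  partition <- rep(NA_character_, nrow(g))
  if (length(cohort_levels) == 2L) {
    partition[in_cohort[, 1] & in_cohort[, 2]] <- "shared"
    partition[in_cohort[, 1] & !in_cohort[, 2]] <- paste0(cohort_levels[1], "_only")
    partition[!in_cohort[, 1] & in_cohort[, 2]] <- paste0(cohort_levels[2], "_only")
  } else {
    partition[in_cohort[, 1]] <- paste0(cohort_levels[1], "_only")
  }
  observed <- count > 0L
  meta <- meta[observed, , drop = FALSE]
  count <- count[observed]
  partition <- partition[observed]
  n_data <- if (missing_aware) {
    as.integer(rowSums(gm$mask[meta$bubble_id, keep_col, drop = FALSE]))
  } else rep(sum(keep_col), length(count))
  rec <- cbind(meta,
               data.frame(count = count, n_data = n_data,
                          frequency = count / n_data,
                          partition = partition,
                          is_singleton = count == 1L))
  rownames(rec) <- NULL
  part_tab <- table(factor(rec$partition,
                           levels = c("shared", paste0(cohort_levels, "_only"))))
  stopifnot(sum(part_tab) == nrow(rec))   # conservation identity
  bins <- cut(rec$frequency, breaks = bin_edges, include.lowest = FALSE, right = TRUE)
  spectrum <- data.frame(bin_lo = head(bin_edges, -1), bin_hi = bin_edges[-1],
                         n = as.integer(table(bins)))
  list(records = rec,
       spectrum = spectrum,
       summary = c(list(n_total = nrow(rec), n_singletons = sum(rec$is_singleton)),
                   as.list(setNames(as.integer(part_tab), names(part_tab)))))
}

#' Non-reference SV counts per haplotype and per diploid sample
#'
#' @param gm a `genotype_matrix` built with a `bubbles` table (so that
#'   reference rows are identifiable)
#' @return list with `per_haplotype` and `per_sample` data.frames; the
#'   diploid count is the number of distinct non-reference alleles carried on
#'   either haplotype (hence at most the sum of the two haplotype counts)
#' @export
genotyped_sv_counts <- function(gm) {
  if (anyNA(gm$alleles$is_reference)) {
    stop("reference rows are not identifiable; build the matrix with `bubbles`")
  }
  nr <- gm$geno[!gm$alleles$is_reference, , drop = FALSE]
  per_hap <- data.frame(hap_id = colnames(nr), n_sv = as.integer(colSums(nr)),
                        stringsAsFactors = FALSE)
  ids <- unique(gm$samples$sample_id)
  per_sample <- data.frame(sample_id = ids,
                           n_sv = vapply(ids, function(s) {
                             cols <- gm$samples$hap_id[gm$samples$sample_id == s]
                             sum(rowSums(nr[, cols, drop = FALSE]) > 0L)
                           }, integer(1)),
                           stringsAsFactors = FALSE)
  list(per_haplotype = per_hap, per_sample = per_sample)
}

#' Validity-rejection rate by allele-frequency class
#'
#' Compares how often calls supporting singleton alleles are rejected by the
#' validity filter versus calls supporting common alleles; in cohorts where
#' assembly errors create spurious private alleles, singletons are expected
#' to be rejected more often.
#'
#' @param calls call table with validity labels
#' @param min_common carrier-count threshold defining "common" (default 10)
#' @return data.frame with one row per class: carrier calls, rejected calls,
#'   and the rejection percentage (one decimal)
#' @export
rejection_by_count <- function(calls, min_common = 10L) {
  key <- paste(calls$bubble_id, calls$allele_key, sep = "\r")
  count <- table(key)[key]
  rejected <- calls$validity != "haploid"
  cls <- ifelse(count == 1L, "singleton",
                ifelse(count >= min_common, "common", "intermediate"))
  out <- do.call(rbind, lapply(c("singleton", "intermediate", "common"), function(cl) {
    n <- sum(cls == cl); nr <- sum(rejected[cls == cl])
    data.frame(class = cl, n = n, n_rejected = nr, pct_rejected = percent_of(nr, n))
  }))
  out
}

#' Export a genotype matrix and its row metadata as TSV
#' @param gm a `genotype_matrix`
#' @param prefix output path prefix; writes `<prefix>_matrix.tsv` and
#'   `<prefix>_alleles.tsv`
#' @export
export_matrix <- function(gm, prefix) {
  write.table(gm$geno, paste0(prefix, "_matrix.tsv"), sep = "\t", quote = FALSE)
  write.table(gm$alleles, paste0(prefix, "_alleles.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
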