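#' Classify an allele as insertion, deletion or complex
#'
#' Classification uses path topology within the bubble: an allele is a
#' deletion when it is the direct source-to-sink edge while the reference
#' path has interior sequence; an insertion when the reference path is the
#' direct edge while the allele has interior sequence; anything else
#' (two alternative interiors, tandem-repeat copy-number series, nested
#' rearrangements) is complex.
#'
#' @param allele_nodes node-id vector of the allele path (source..sink)
#' @param ref_nodes node-id vector of the bubble's reference path
#' @return one of `"deletion"`, `"insertion"`, `"complex"` (or
#'   `"reference"` when the allele is the reference path itself)
#' @export
classify_allele <- function(allele_nodes, ref_nodes) {
  if (allele_nodes[1] != ref_nodes[1] ||
      allele_nodes[length(allele_nodes)] != ref_nodes[length(ref_nodes)]) {
    stop("allele does not belong to this bubble (source/sink mismatch)")
  }
  a_int <- length(allele_nodes) - 2L
  r_int <- length(ref_nodes) - 2L
  if (identical(allele_nodes, ref_nodes)) return("reference")
  if (a_int == 0L && r_int > 0L) return("deletion")
  if (r_int == 0L && a_int > 0L) return("insertion")
  "complex"
}

#' Classify every allele of an allele table
#'
#' @param alleles data.frame with `node_ids` (list column) and `bubble_id`
#' @param bubbles bubble table with `ref_path`
#' @return `alleles` with a `class` column added
#' @export
classify_bubble_alleles <- function(alleles, bubbles) {
  i <- match(alleles$bubble_id, bubbles$bubble_id)
  alleles$class <- vapply(seq_len(nrow(alleles)), function(k) {
    classify_allele(alleles$node_ids[[k]], bubbles$ref_path[[i[k]]])
  }, character(1))
  alleles
}

#' Full-length mobile-element call for an allele
#'
#' An allele is a full-length SINE when more than 80% of its interior
#' sequence is covered by SINE-family repeat hits and its length is within
#' 250-400 bp; a full-length LINE when more than 80% is covered by
#' LINE-family hits and its length is within 5,000-10,000 bp.  Coverage is
#' computed after merging overlapping hits; the coverage inequality is
#' strict and the length bounds are inclusive.
#'
#' @param length_bp interior length of the allele
#' @param hits data.frame of repeat hits on the allele sequence with
#'   `start`, `end` (0-based half-open) and `class` (`"SINE"`, `"LINE"`, ...)
#' @param min_coverage coverage threshold (strict; default 0.80)
#' @return `"SINE"`, `"LINE"` or `"none"`
#' @export
full_length_te <- function(length_bp, hits, min_coverage = 0.80) {
  if (length_bp <= 0L) return("none")
  cov_of <- function(cls) {
    h <- hits[hits$class == cls, , drop = FALSE]
    .union_bp(h$start, h$end, length_bp) / length_bp
  }
  if (cov_of("SINE") > min_coverage && length_bp >= 250L && length_bp <= 400L) {
    return("SINE")
  }
  if (cov_of("LINE") > min_coverage && length_bp >= 5000L && length_bp <= 10000L) {
    return("LINE")
  }
  "none"
}

#' Read a RepeatMasker .out file
#'
#' Parses the whitespace-delimited RepeatMasker output dialect (three header
#' lines skipped).  Repeat classes are mapped to
#' `{SINE, LINE, LTR, DNA, simple, satellite, other}` by the class/family
#' column prefix.
#'
#' @param path file path
#' @return data.frame with `target`, `start`, `end` (0-based half-open on
#'   the target sequence), `family` (repeat name) and `class`
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(target = character(), start = integer(), end = integer(),
                      family = character(), class = character()))
  }
  f <- strsplit(lines, "[[:space:]]+")
  data.frame(target = vapply(f, `[`, "", 5),
             start = as.integer(vapply(f, `[`, "", 6)) - 1L,
             end = as.integer(vapply(f, `[`, "", 7)),
             family = vapply(f, `[`, "", 10),
             class = .rm_class(vapply(f, `[`, "", 11)),
             stringsAsFactors = FALSE)
}

.rm_class <- function(x) {
  out <- rep("other", length(x))
  out[startsWith(x, "SINE")] <- "SINE"
  out[startsWith(x, "LINE")] <- "LINE"
  out[startsWith(x, "LTR")] <- "LTR"
  out[startsWith(x, "DNA")] <- "DNA"
  out[startsWith(x, "Simple_repeat") | startsWith(x, "Low_complexity")] <- "simple"
  out[startsWith(x, "Satellite")] <- "satellite"
  out
}

#' Project bubbles (and hence their alleles) to backbone intervals
#'
#' Every allele of a bubble inherits the bubble's backbone interval: the
#' polymorphic locus itself.  Insertion-point bubbles (zero-width interval)
#' are anchored at a 1 bp interval at the insertion point so that
#' breakpoint-style overlap works uniformly.  Bubbles without a backbone
#' anchor are excluded and tallied.
#'
#' @param bubbles bubble table
#' @return list with `intervals` (data.frame `bubble_id`, `chrom`, `start`,
#'   `end`) and `n_unplaced`
#' @export
project_allele <- function(bubbles) {
  unplaced <- is.na(bubbles$chrom) | is.na(bubbles$start)
  b <- bubbles[!unplaced, , drop = FALSE]
  end <- ifelse(b$end > b$start, b$end, b$start + 1L)
  list(intervals = data.frame(bubble_id = b$bubble_id, chrom = b$chrom,
                              start = b$start, end = end,
                              stringsAsFactors = FALSE),
       n_unplaced = sum(unplaced))
}

#' Assign alleles to genomic compartments
#'
#' Each placed interval is assigned the most specific overlapped category:
#' `omim_exonic` (exon of an OMIM disease gene) over `exonic` over `genic`
#' over `intergenic`.  The overlap predicate is any-bp intersection (at
#' least `min_overlap` bp).
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and an id column as its first column
#' @param features list with `genes` (data.frame `gene_id`, `chrom`,
#'   `start`, `end`, `omim` logical) and `exons` (data.frame `exon_id`,
#'   `gene_id`, `chrom`, `start`, `end`)
#' @param min_overlap minimum overlap in bp (default 1)
#' @return data.frame: the input id column, `compartment`, plus list columns
#'   `genes` and `exons` with the overlapped feature ids
#' @export
overlap_features <- function(intervals, features, min_overlap = 1L) {
  genes <- features$genes
  exons <- features$exons
  n <- nrow(intervals)
  gene_hits <- vector("list", n); exon_hits <- vector("list", n)
  for (chrom in unique(intervals$chrom)) {
    qi <- which(intervals$chrom == chrom)
    q <- .ir(intervals$start[qi], intervals$end[qi])
    gi <- which(genes$chrom == chrom)
    if (length(gi)) {
      h <- IRanges::findOverlaps(q, .ir(genes$start[gi], genes$end[gi]),
                                 minoverlap = min_overlap)
      for (k in seq_along(h)) {
        i <- qi[S4Vectors::queryHits(h)[k]]
        gene_hits[[i]] <- c(gene_hits[[i]], genes$gene_id[gi[S4Vectors::subjectHits(h)[k]]])
      }
    }
    ei <- which(exons$chrom == chrom)
    if (length(ei)) {
      h <- IRanges::findOverlaps(q, .ir(exons$start[ei], exons$end[ei]),
                                 minoverlap = min_overlap)
      for (k in seq_along(h)) {
        i <- qi[S4Vectors::queryHits(h)[k]]
        exon_hits[[i]] <- c(exon_hits[[i]], exons$exon_id[ei[S4Vectors::subjectHits(h)[k]]])
      }
    }
  }
  omim_genes <- genes$gene_id[genes$omim]
  exon_gene <- setNames(exons$gene_id, exons$exon_id)
  compartment <- vapply(seq_len(n), function(i) {
    ex <- exon_hits[[i]]
    if (length(ex)) {
      if (any(exon_gene[ex] %in% omim_genes)) return("omim_exonic")
      return("exonic")
    }
    if (length(gene_hits[[i]])) return("genic")
    "intergenic"
  }, character(1))
  out <- data.frame(intervals[[1]], compartment, stringsAsFactors = FALSE)
  names(out)[1] <- names(intervals)[1]
  out$genes <- gene_hits
  out$exons <- exon_hits
  # genes reached through an exon overlap (used for alleles-per-gene tallies)
  out$exon_genes <- lapply(exon_hits, function(ex) unique(unname(exon_gene[ex])))
  out$omim_exons <- lapply(exon_hits, function(ex) ex[exon_gene[ex] %in% omim_genes])
  out$omim_exon_genes <- lapply(out$omim_exons, function(ex) unique(unname(exon_gene[ex])))
  out
}

#' Allele / gene / exon tallies with alleles-per-gene densities
#'
#' @param overlaps output of [overlap_features()]
#' @return data.frame with one row per level (`gene`, `exon`, `omim_exon`):
#'   number of alleles, distinct genes, distinct exons (where applicable)
#'   and the alleles-per-gene density rounded to two decimals
#' @export
compartment_tallies <- function(overlaps) {
  in_gene <- lengths(overlaps$genes) > 0L
  in_exon <- lengths(overlaps$exons) > 0L
  in_omim <- lengths(overlaps$omim_exons) > 0L
  lvl <- function(name, sel, gene_col, exon_col) {
    genes <- unique(unlist(gene_col[sel]))
    exons <- unique(unlist(exon_col[sel]))
    data.frame(level = name, n_alleles = sum(sel),
               n_genes = length(genes), n_exons = length(exons),
               density = if (length(genes)) allele_gene_density(sum(sel), length(genes)) else NA_real_)
  }
  rbind(lvl("gene", in_gene, overlaps$genes, list()),
        lvl("exon", in_exon, overlaps$exon_genes, overlaps$exons),
        lvl("omim_exon", in_omim, overlaps$omim_exon_genes, overlaps$omim_exons))
}

#' Singleton fraction per genomic compartment
#'
#' @param records allele-frequency records (from [partition_and_spectrum()])
#'   with an `is_singleton` column
#' @param compartments data.frame mapping the records' `bubble_id` (or row
#'   id) to a `compartment`; matched by the first column
#' @param by name of the column shared between `records` and `compartments`
#' @return data.frame per compartment: `n`, `n_singletons`, `pct_singleton`
#'   (one decimal; `NA` for empty compartments)
#' @export
singleton_fraction_by_compartment <- function(records, compartments,
                                              by = "bubble_id") {
  comp <- compartments$compartment[match(records[[by]], compartments[[by]])]
  levels <- c("intergenic", "genic", "exonic", "omim_exonic")
  do.call(rbind, lapply(levels, function(cl) {
    sel <- !is.na(comp) & comp == cl
    data.frame(compartment = cl, n = sum(sel),
               n_singletons = sum(records$is_singleton[sel]),
               pct_singleton = percent_of(sum(records$is_singleton[sel]), sum(sel)))
  }))
}

#' Account for novel (unaligned, non-repeat) sequence in graph nodes
#'
#' Considers non-reference nodes longer than `min_node_len` bp.  For each,
#' the repeat hits and reference alignments on the node sequence are
#' unioned and subtracted; remaining fragments shorter than `min_fragment`
#' bp are ignored.  Intervals extending past the node bounds are clipped
#' with a warning.
#'
#' @param nodes data.frame with `node_id`, `length` and optionally `group`
#'   (e.g. a cohort label) for per-group totals
#' @param repeat_hits data.frame `target`, `start`, `end`
#' @param alignments data.frame `target`, `start`, `end` (intervals mapped
#'   to the reference)
#' @param min_node_len only nodes strictly longer than this are surveyed
#' @param min_fragment novel fragments shorter than this are discarded
#' @return list with `per_node` (novel/repeat/aligned bp per node) and
#'   `totals` (overall and per group)
#' @export
novel_sequence_accounting <- function(nodes, repeat_hits, alignments,
                                      min_node_len = 100L, min_fragment = 10L) {
  keep <- nodes$length > min_node_len
  nd <- nodes[keep, , drop = FALSE]
  clip <- function(df, len, id) {
    d <- df[df$target == id, , drop = FALSE]
    if (nrow(d) && (any(d$start < 0L) || any(d$end > len))) {
      warning("interval outside node bounds on ", id, "; clipped")
      d$start <- pmax(d$start, 0L); d$end <- pmin(d$end, len)
    }
    d[d$end > d$start, , drop = FALSE]
  }
  per <- do.call(rbind, lapply(seq_len(nrow(nd)), function(i) {
    id <- nd$node_id[i]; len <- nd$length[i]
    rh <- clip(repeat_hits, len, id)
    al <- clip(alignments, len, id)
    rep_red <- IRanges::reduce(.ir(rh$start, rh$end))
    aln_red <- IRanges::reduce(.ir(al$start, al$end))
    covered <- IRanges::reduce(c(rep_red, aln_red))
    novel <- IRanges::setdiff(.ir(0L, len), covered)
    novel <- novel[IRanges::width(novel) >= min_fragment]
    data.frame(node_id = id, length = len,
               repeat_bp = sum(IRanges::width(rep_red)),
               aligned_not_repeat_bp = sum(IRanges::width(IRanges::setdiff(aln_red, rep_red))),
               novel_bp = sum(IRanges::width(novel)))
  }))
  if (is.null(per)) per <- data.frame(node_id = character(), length = integer(),
                                      repeat_bp = integer(),
                                      aligned_not_repeat_bp = integer(),
                                      novel_bp = integer())
  totals <- data.frame(group = "all",
                       repeat_bp = sum(per$repeat_bp),
                       aligned_not_repeat_bp = sum(per$aligned_not_repeat_bp),
                       novel_bp = sum(per$novel_bp))
  if (!is.null(nd$group) && nrow(per)) {
    g <- nd$group[match(per$node_id, nd$node_id)]
    totals <- rbind(totals, do.call(rbind, lapply(unique(g), function(gr) {
      sel <- g == gr
      data.frame(group = gr, repeat_bp = sum(per$repeat_bp[sel]),
                 aligned_not_repeat_bp = sum(per$aligned_not_repeat_bp[sel]),
                 novel_bp = sum(per$novel_bp[sel]))
    })))
  }
  list(per_node = per, totals = totals)
}

#' Detect SV hotspots in fixed genomic windows
#'
#' Tiles each chromosome into `window_bp` windows, counts overlapping SV
#' intervals (any-bp), takes the given percentile of the nonzero window
#' counts (type-1 quantile, i.e. an observed count) as the threshold, and
#' flags nonzero windows whose count is at or above it.
#'
#' @param intervals data.frame `chrom`, `start`, `end`
#' @param genome_sizes named numeric vector of chromosome lengths
#' @param window_bp window size in bp (default 1 Mbp)
#' @param percentile hotspot percentile of nonzero counts (default 90)
#' @return data.frame of windows with `sv_count` and `is_hotspot`; the
#'   threshold is attached as attribute `threshold`
#' @export
detect_hotspots <- function(intervals, genome_sizes, window_bp = 1e6,
                            percentile = 90) {
  if (window_bp <= 0) stop("window_bp must be positive")
  win <- do.call(rbind, lapply(names(genome_sizes), function(chrom) {
    starts <- seq(0, genome_sizes[[chrom]] - 1, by = window_bp)
    data.frame(chrom = chrom, start = starts,
               end = pmin(starts + window_bp, genome_sizes[[chrom]]),
               stringsAsFactors = FALSE)
  }))
  win$sv_count <- 0L
  for (chrom in unique(win$chrom)) {
    wi <- which(win$chrom == chrom)
    qi <- which(intervals$chrom == chrom)
    if (!length(qi)) next
    cnt <- IRanges::countOverlaps(.ir(win$start[wi], win$end[wi]),
                                  .ir(intervals$start[qi], intervals$end[qi]))
    win$sv_count[wi] <- as.integer(cnt)
  }
  nz <- win$sv_count[win$sv_count > 0L]
  # type-1 quantile: the cutoff is an observed window count, and windows at
  # or above it are hotspots (so a single loaded window is itself a hotspot)
  thr <- if (length(nz)) unname(quantile(nz, percentile / 100, type = 1)) else Inf
  win$is_hotspot <- win$sv_count >= thr & win$sv_count > 0L
  attr(win, "threshold") <- thr
  win
}

#' Read gene/exon features from GFF3 (plus an OMIM gene list)
#'
#' @param path GFF3 file with `gene` and `exon` records; exon records must
#'   carry a `Parent` (or `gene_id`) attribute
#' @param omim_genes character vector of OMIM gene ids (e.g. from
#'   [read_omim_list()])
#' @return feature list as consumed by [overlap_features()]
#' @export
read_features_gff3 <- function(path, omim_genes = character()) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  is_gene <- df$type == "gene"
  is_exon <- df$type == "exon"
  gene_id <- if ("ID" %in% names(df)) df$ID else df$gene_id
  parent <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
           character(1))
  } else df$gene_id
  genes <- data.frame(gene_id = gene_id[is_gene],
                      chrom = as.character(df$seqnames[is_gene]),
                      start = df$start[is_gene] - 1L, end = df$end[is_gene],
                      stringsAsFactors = FALSE)
  genes$omim <- genes$gene_id %in% omim_genes
  exons <- data.frame(exon_id = gene_id[is_exon],
                      gene_id = parent[is_exon],
                      chrom = as.character(df$seqnames[is_exon]),
                      start = df$start[is_exon] - 1L, end = df$end[is_exon],
                      stringsAsFactors = FALSE)
  list(genes = genes, exons = exons)
}

#' Read a one-symbol-per-line OMIM gene list
#' @param path file path
#' @export
read_omim_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
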