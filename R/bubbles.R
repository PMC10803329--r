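#' Detect backbone-anchored bubbles
#'
#' A bubble is the graph representation of a polymorphic locus: it begins at
#' a source node where genome paths diverge and ends at the sink node where
#' all genomes coincide again.  Anchors are the backbone nodes traversed by
#' every end-to-end path; bubbles are the intervals between consecutive
#' anchors that contain variation (off-backbone nodes, or a backbone-skipping
#' deletion edge).  Interiors of distinct bubbles are node-disjoint.
#'
#' Regions whose interior subgraph is cyclic, off-backbone components that
#' touch more than one backbone contig, and dead-end components attached to a
#' single anchor cannot be expressed as source/sink bubbles; they are
#' reported in the `unresolvable` attribute rather than silently dropped.
#'
#' @param graph a [pangenome_graph()]
#' @return data.frame of bubbles ordered by `(chrom, start)` with columns
#'   `bubble_id`, `chrom`, `start`, `end` (0-based half-open backbone
#'   interval between the source's end and the sink's start), `source_id`,
#'   `sink_id`, `interior` (list column), `ref_path` (list column: backbone
#'   node path source..sink) and `ref_allele_key`; attribute `unresolvable`
#'   lists the problem regions
#' @export
detect_bubbles <- function(graph) {
  nodes <- graph$nodes
  edges <- graph$edges
  node_len <- setNames(nchar(nodes$sequence), nodes$node_id)
  node_off <- setNames(nodes$stable_offset, nodes$node_id)

  bb_chrom <- rep(names(graph$backbone), lengths(graph$backbone))
  bb_id <- unlist(graph$backbone, use.names = FALSE)
  bb_pos <- unlist(lapply(graph$backbone, seq_along), use.names = FALSE)
  chrom_of <- setNames(bb_chrom, bb_id)
  pos_of <- setNames(bb_pos, bb_id)
  is_bb <- nodes$node_id %in% bb_id
  off_ids <- nodes$node_id[!is_bb]

  unresolvable <- list()
  spans <- list()   # each: list(chrom, lo, hi, off = character())

  ## connected components over off-backbone nodes (undirected)
  if (length(off_ids)) {
    comp <- seq_along(off_ids)
    names(comp) <- off_ids
    find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
    idx <- setNames(seq_along(off_ids), off_ids)
    for (k in seq_len(nrow(edges))) {
      a <- edges$from[k]; b <- edges$to[k]
      if (!is.na(idx[a]) && !is.na(idx[b])) {
        ra <- find(idx[[a]]); rb <- find(idx[[b]])
        if (ra != rb) comp[ra] <- rb
      }
    }
    roots <- vapply(seq_along(off_ids), find, integer(1))
    groups <- split(off_ids, roots)
    for (g in groups) {
      touch_from <- edges$from[edges$to %in% g]
      touch_to <- edges$to[edges$from %in% g]
      anchors <- setdiff(unique(c(touch_from, touch_to)), g)
      chroms <- unique(chrom_of[anchors])
      chroms <- chroms[!is.na(chroms)]
      if (length(anchors) == 0L || length(chroms) != 1L) {
        unresolvable <- c(unresolvable,
                          list(list(reason = "component not anchored to a single backbone contig",
                                    nodes = g)))
        next
      }
      p <- pos_of[anchors]
      if (min(p) == max(p)) {
        unresolvable <- c(unresolvable,
                          list(list(reason = "dead-end component attached to a single anchor",
                                    nodes = g)))
        next
      }
      spans[[length(spans) + 1L]] <- list(chrom = chroms, lo = min(p), hi = max(p), off = g)
    }
  }

  ## backbone-skipping edges (deletion alleles)
  both_bb <- edges$from %in% bb_id & edges$to %in% bb_id
  for (k in which(both_bb)) {
    a <- edges$from[k]; b <- edges$to[k]
    if (chrom_of[[a]] != chrom_of[[b]]) {
      unresolvable <- c(unresolvable,
                        list(list(reason = "edge joins two backbone contigs", nodes = c(a, b))))
      next
    }
    d <- abs(pos_of[[a]] - pos_of[[b]])
    if (d > 1L) {
      spans[[length(spans) + 1L]] <- list(chrom = chrom_of[[a]],
                                          lo = min(pos_of[[a]], pos_of[[b]]),
                                          hi = max(pos_of[[a]], pos_of[[b]]),
                                          off = character())
    }
    if (d == 0L) {
      unresolvable <- c(unresolvable, list(list(reason = "self loop on backbone", nodes = a)))
    }
  }

  ## merge properly-overlapping spans per chromosome (shared endpoint = two bubbles)
  out <- list()
  for (chrom in names(graph$backbone)) {
    sp <- Filter(function(s) s$chrom == chrom, spans)
    if (!length(sp)) next
    ord <- order(vapply(sp, `[[`, numeric(1), "lo"), vapply(sp, `[[`, numeric(1), "hi"))
    sp <- sp[ord]
    merged <- list(sp[[1]])
    for (s in sp[-1]) {
      last <- merged[[length(merged)]]
      if (s$lo < last$hi) {
        last$hi <- max(last$hi, s$hi)
        last$off <- union(last$off, s$off)
        merged[[length(merged)]] <- last
      } else merged[[length(merged) + 1L]] <- s
    }
    chain <- graph$backbone[[chrom]]
    for (m in merged) {
      src <- chain[m$lo]; snk <- chain[m$hi]
      between <- if (m$hi - m$lo > 1L) chain[(m$lo + 1L):(m$hi - 1L)] else character()
      interior <- c(between, m$off)
      if (.has_cycle(c(src, interior, snk), edges)) {
        unresolvable <- c(unresolvable,
                          list(list(reason = "cyclic region between source and sink",
                                    nodes = interior)))
        next
      }
      ref_path <- chain[m$lo:m$hi]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom,
        start = unname(node_off[src] + node_len[src]),
        end = unname(node_off[snk]),
        source_id = src, sink_id = snk,
        stringsAsFactors = FALSE)
      attr(out[[length(out)]], "interior") <- interior
      attr(out[[length(out)]], "ref_path") <- ref_path
    }
  }

  if (!length(out)) {
    res <- data.frame(bubble_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      source_id = character(), sink_id = character(),
                      ref_allele_key = character(), stringsAsFactors = FALSE)
    res$interior <- list(); res$ref_path <- list()
  } else {
    res <- do.call(rbind, out)
    res$interior <- lapply(out, attr, "interior")
    res$ref_path <- lapply(out, attr, "ref_path")
    ord <- order(res$chrom, res$start, res$end)
    res <- res[ord, , drop = FALSE]
    res$ref_allele_key <- vapply(res$ref_path, paste, character(1), collapse = "+")
    res$bubble_id <- sprintf("bub_%s_%d_%d", res$chrom, res$start, res$end)
    rownames(res) <- NULL
    res <- res[, c("bubble_id", "chrom", "start", "end", "source_id", "sink_id",
                   "interior", "ref_path", "ref_allele_key")]
  }
  attr(res, "unresolvable") <- unresolvable
  res
}

# directed cycle check on the induced subgraph (Kahn's algorithm)
.has_cycle <- function(node_set, edges) {
  e <- edges[edges$from %in% node_set & edges$to %in% node_set, , drop = FALSE]
  if (!nrow(e)) return(FALSE)
  indeg <- setNames(integer(length(node_set)), node_set)
  tab <- table(e$to)
  indeg[names(tab)] <- as.integer(tab)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    outs <- e$to[e$from == v]
    for (w in outs) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  seen < length(node_set)
}

#' Enumerate the distinct alleles observed in a bubble
#'
#' Alleles are the distinct source-to-sink node paths among the observed
#' traversals; combinatorial paths that no genome took are not enumerated.
#' The allele key is the `+`-joined node path, and `length_bp` is the total
#' interior sequence length (0 for the direct-edge deletion allele).
#'
#' @param graph a [pangenome_graph()]
#' @param bubble a single bubble (one row of [detect_bubbles()] output)
#' @param observed_paths list of node-id vectors, each from source to sink
#' @return data.frame ordered by `allele_key` with columns `bubble_id`,
#'   `allele_key`, `node_ids` (list), `length_bp`, `n_observed`,
#'   `is_reference`
#' @export
enumerate_alleles <- function(graph, bubble, observed_paths) {
  src <- bubble$source_id; snk <- bubble$sink_id
  interior <- bubble$interior[[1]]
  node_len <- setNames(nchar(graph$nodes$sequence), graph$nodes$node_id)
  keys <- vapply(observed_paths, function(p) {
    if (p[1] != src || p[length(p)] != snk) {
      stop("observed path does not run from bubble source to sink")
    }
    mid <- p[-c(1L, length(p))]
    out <- setdiff(mid, interior)
    if (length(out)) {
      stop("path leaves bubble interior at node: ", out[1])
    }
    paste(p, collapse = "+")
  }, character(1))
  uk <- sort(unique(keys))
  paths <- observed_paths[match(uk, keys)]
  data.frame(
    bubble_id = bubble$bubble_id,
    allele_key = uk,
    node_ids = I(paths),
    length_bp = vapply(paths, function(p) {
      mid <- p[-c(1L, length(p))]
      if (!length(mid)) 0L else sum(node_len[mid])
    }, numeric(1)),
    n_observed = as.integer(table(keys)[uk]),
    is_reference = uk == bubble$ref_allele_key,
    stringsAsFactors = FALSE)
}

#' Export bubbles and alleles as a BED9-like TSV
#'
#' One row per allele: backbone chrom, start, end, bubble id, number of
#' alleles in the bubble, strand placeholder, allele key, allele class (or
#' `.` when not annotated) and interior length.
#'
#' @param bubbles output of [detect_bubbles()]
#' @param alleles data.frame with `bubble_id`, `allele_key`, `length_bp` and
#'   optionally `class`
#' @param path output path
#' @export
export_bubbles_bed <- function(bubbles, alleles, path) {
  n_all <- table(alleles$bubble_id)
  i <- match(alleles$bubble_id, bubbles$bubble_id)
  df <- data.frame(chrom = bubbles$chrom[i],
                   start = bubbles$start[i],
                   end = bubbles$end[i],
                   bubble_id = alleles$bubble_id,
                   n_alleles = as.integer(n_all[alleles$bubble_id]),
                   strand = ".",
                   allele_key = alleles$allele_key,
                   class = alleles$class %||% rep(".", nrow(alleles)),
                   length_bp = alleles$length_bp)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
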