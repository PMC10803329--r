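#' Construct a pangenome graph object
#'
#' A pangenome graph is a set of sequence-labelled nodes and oriented edges,
#' anchored to a reference backbone.  Each node carries the rGFA stable tags:
#' the origin contig (`SN`), the 0-based offset on that origin (`SO`) and the
#' rank of the genome that introduced it (`SR`; 0 is the backbone reference).
#' The backbone is the ordered chain of rank-0 nodes per backbone contig.
#'
#' @param nodes data.frame with columns `node_id`, `sequence`, `stable_name`,
#'   `stable_offset`, `rank`
#' @param edges data.frame with columns `from`, `from_orient`, `to`,
#'   `to_orient`
#' @param backbone optional named list of ordered node-id vectors (one per
#'   backbone contig); derived from rank-0 nodes ordered by stable offset
#'   when omitted
#' @return an object of class `pangenome_graph`
#' @export
pangenome_graph <- function(nodes, edges, backbone = NULL) {
  .stop_if_missing_cols(nodes, c("node_id", "sequence", "stable_name",
                                 "stable_offset", "rank"), "nodes")
  .stop_if_missing_cols(edges, c("from", "from_orient", "to", "to_orient"),
                        "edges")
  if (anyDuplicated(nodes$node_id)) {
    stop("duplicate node_id: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "))
  }
  if (any(nchar(nodes$sequence) < 1L)) stop("node sequences must be non-empty")
  if (any(nodes$stable_offset < 0L) || any(nodes$rank < 0L)) {
    stop("stable_offset and rank must be non-negative")
  }
  bad <- setdiff(c(edges$from, edges$to), nodes$node_id)
  if (length(bad)) stop("edge endpoint(s) not in node set: ",
                        paste(unique(bad), collapse = ", "))
  if (is.null(backbone)) {
    bb <- nodes[nodes$rank == 0L, , drop = FALSE]
    backbone <- lapply(split(bb, bb$stable_name), function(d) {
      d$node_id[order(d$stable_offset)]
    })
  }
  structure(list(nodes = nodes, edges = edges, backbone = backbone),
            class = "pangenome_graph")
}

#' @export
print.pangenome_graph <- function(x, ...) {
  cat("pangenome_graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges;",
      length(x$backbone), "backbone contig(s) [",
      paste(names(x$backbone), collapse = ", "), "]\n")
  cat("  non-reference nodes:", sum(x$nodes$rank > 0L),
      "(", sum(nchar(x$nodes$sequence[x$nodes$rank > 0L])), "bp )\n")
  invisible(x)
}

.parse_rgfa_tag <- function(fields, tag, type, lineno) {
  hit <- grep(paste0("^", tag, ":", type, ":"), fields, value = TRUE)
  if (length(hit) == 0L) {
    stop("rGFA format error at line ", lineno, ": missing ", tag, " tag")
  }
  sub(paste0("^", tag, ":", type, ":"), "", hit[1])
}

#' Read a pangenome graph from rGFA
#'
#' Parses GFA1 restricted to the rGFA dialect: `S` lines must carry `SN`
#' (stable name), `SO` (stable offset) and `SR` (rank) tags; `L` lines are
#' expected to have a trivial (`0M` or `*`) overlap.  Unknown line types are
#' skipped with a warning.
#'
#' @param input path to an rGFA file, or a character vector of rGFA lines
#' @return a [pangenome_graph()]
#' @export
parse_rgfa <- function(input) {
  lines <- if (length(input) == 1L && file.exists(input)) readLines(input) else input
  lines <- lines[nzchar(lines)]
  type <- substr(lines, 1L, 1L)
  unknown <- setdiff(unique(type), c("S", "L", "H"))
  if (length(unknown)) {
    warning("ignoring unknown GFA line type(s): ", paste(unknown, collapse = ", "))
  }
  s_idx <- which(type == "S")
  nodes <- do.call(rbind, lapply(s_idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("rGFA format error at line ", i, ": short S line")
    data.frame(
      node_id = f[2], sequence = f[3],
      stable_name = .parse_rgfa_tag(f, "SN", "Z", i),
      stable_offset = as.integer(.parse_rgfa_tag(f, "SO", "i", i)),
      rank = as.integer(.parse_rgfa_tag(f, "SR", "i", i)),
      stringsAsFactors = FALSE)
  }))
  if (is.null(nodes)) nodes <- data.frame(node_id = character(), sequence = character(),
                                          stable_name = character(),
                                          stable_offset = integer(), rank = integer())
  if (anyDuplicated(nodes$node_id)) {
    stop("rGFA format error: duplicate node_id ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "))
  }
  l_idx <- which(type == "L")
  edges <- do.call(rbind, lapply(l_idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) stop("rGFA format error at line ", i, ": short L line")
    data.frame(from = f[2], from_orient = f[3], to = f[4], to_orient = f[5],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) edges <- data.frame(from = character(), from_orient = character(),
                                          to = character(), to_orient = character())
  pangenome_graph(nodes, edges)
}

#' Write a pangenome graph as rGFA
#'
#' Emits GFA1 `S` lines with `LN`/`SN`/`SO`/`SR` tags and `L` lines with a
#' `0M` overlap.  Note that a graph whose stable names have been anonymized
#' (see [anonymize_nodes()]) loses the stable-name grouping that
#' [parse_rgfa()] uses to reconstruct backbone chains.
#'
#' @param graph a [pangenome_graph()]
#' @param path output file path
#' @export
write_rgfa <- function(graph, path) {
  n <- graph$nodes
  s <- sprintf("S\t%s\t%s\tLN:i:%d\tSN:Z:%s\tSO:i:%d\tSR:i:%d",
               n$node_id, n$sequence, nchar(n$sequence),
               n$stable_name, n$stable_offset, n$rank)
  e <- graph$edges
  l <- if (nrow(e)) sprintf("L\t%s\t%s\t%s\t%s\t0M",
                            e$from, e$from_orient, e$to, e$to_orient) else character()
  writeLines(c("H\tVN:Z:1.0", s, l), path)
  invisible(path)
}

#' Anonymize node provenance
#'
#' Replaces every node's stable name with the hex sha256 hash of the original
#' name concatenated to a fresh per-node random salt, so that nodes derived
#' from the same assembly can no longer be linked.  Topology, sequences,
#' offsets and ranks are unchanged, and the in-memory backbone chain is kept.
#'
#' @param graph a [pangenome_graph()]
#' @param seed integer seed for the salt generator; the same seed reproduces
#'   the same salts (and hence identical output) bit for bit
#' @return a [pangenome_graph()] with hashed stable names
#' @export
anonymize_nodes <- function(graph, seed) {
  n <- nrow(graph$nodes)
  if (n == 0L) return(graph)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  salts <- vapply(seq_len(n), function(i) {
    paste(sample(c(0:9, letters[1:6]), 32L, replace = TRUE), collapse = "")
  }, character(1))
  hashed <- vapply(seq_len(n), function(i) {
    digest::digest(paste0(graph$nodes$stable_name[i], salts[i]),
                   algo = "sha256", serialize = FALSE)
  }, character(1))
  out <- graph
  out$nodes$stable_name <- hashed
  out
}

#' Per-genome pangenome growth
#'
#' Counts the nodes (and base pairs) that each genome contributed to the
#' graph, using the rGFA rank as the genome's position in the augmentation
#' order.  The cumulative curve over the given order is non-decreasing by
#' construction.
#'
#' @param graph a [pangenome_graph()]
#' @param genome_order integer vector of ranks in augmentation order
#'   (typically `0:n_genomes`, 0 being the backbone)
#' @return data.frame with `rank`, `n_nodes`, `bp`, `cum_nodes`, `cum_bp`
#' @export
pangenome_growth <- function(graph, genome_order) {
  r <- graph$nodes$rank
  bad <- setdiff(unique(r), genome_order)
  if (length(bad)) stop("node rank(s) outside genome_order: ",
                        paste(bad, collapse = ", "))
  bp <- nchar(graph$nodes$sequence)
  out <- data.frame(rank = genome_order,
                    n_nodes = vapply(genome_order, function(g) sum(r == g), integer(1)),
                    bp = vapply(genome_order, function(g) sum(bp[r == g]), numeric(1)))
  out$cum_nodes <- cumsum(out$n_nodes)
  out$cum_bp <- cumsum(out$bp)
  out
}
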