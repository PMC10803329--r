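# Independent brute-force oracles used by the property suites.

# Random backbone-anchored variation graph: a rank-0 chain plus random
# detour paths between backbone positions.  Total node count stays <= 12.
random_bubble_graph <- function(max_nodes = 12L) {
  n_bb <- sample(3:6, 1L)
  nodes <- data.frame(node_id = paste0("b", seq_len(n_bb)),
                      sequence = vapply(seq_len(n_bb), function(i)
                        paste(sample(c("A", "C", "G", "T"), sample(3:8, 1L),
                                     replace = TRUE), collapse = ""),
                        character(1)),
                      stable_name = "chrZ", stable_offset = 0L, rank = 0L,
                      stringsAsFactors = FALSE)
  nodes$stable_offset <- cumsum(c(0L, head(nchar(nodes$sequence), -1L)))
  edges <- data.frame(from = paste0("b", seq_len(n_bb - 1L)), from_orient = "+",
                      to = paste0("b", seq_len(n_bb - 1L) + 1L), to_orient = "+",
                      stringsAsFactors = FALSE)
  n_det <- sample(1:4, 1L)
  extra <- 0L
  for (d in seq_len(n_det)) {
    ij <- sort(sample(n_bb, 2L))
    k <- sample(0:2, 1L)
    if (k == 0L && ij[2] - ij[1] < 2L) k <- 1L
    if (nrow(nodes) + k > max_nodes) next
    prev <- paste0("b", ij[1])
    for (x in seq_len(k)) {
      extra <- extra + 1L
      id <- paste0("d", extra)
      nodes <- rbind(nodes, data.frame(node_id = id,
                                       sequence = paste(sample(c("A", "C", "G", "T"),
                                                               sample(2:6, 1L), TRUE),
                                                        collapse = ""),
                                       stable_name = paste0("g", d),
                                       stable_offset = 0L, rank = d,
                                       stringsAsFactors = FALSE))
      edges <- rbind(edges, data.frame(from = prev, from_orient = "+", to = id,
                                       to_orient = "+", stringsAsFactors = FALSE))
      prev <- id
    }
    edges <- rbind(edges, data.frame(from = prev, from_orient = "+",
                                     to = paste0("b", ij[2]), to_orient = "+",
                                     stringsAsFactors = FALSE))
  }
  edges <- unique(edges)
  pangenome_graph(nodes, edges)
}

# Exhaustive bubble oracle: enumerate every end-to-end path, take as anchors
# the backbone nodes visited by all paths, and report every consecutive
# anchor interval traversed by more than one distinct subpath.
oracle_bubbles <- function(graph) {
  chain <- graph$backbone[[1]]
  adj <- split(graph$edges$to, graph$edges$from)
  paths <- list()
  walk <- function(node, acc) {
    acc <- c(acc, node)
    if (node == chain[length(chain)]) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible())
    }
    for (nb in adj[[node]]) walk(nb, acc)
  }
  walk(chain[1], character())
  anchors <- chain[vapply(chain, function(b)
    all(vapply(paths, function(p) b %in% p, logical(1))), logical(1))]
  out <- list()
  for (k in seq_len(length(anchors) - 1L)) {
    a <- anchors[k]; b <- anchors[k + 1L]
    subs <- unique(vapply(paths, function(p) {
      i <- match(a, p); j <- match(b, p)
      paste(p[i:j], collapse = "+")
    }, character(1)))
    if (length(subs) > 1L) {
      interior <- setdiff(unique(unlist(strsplit(subs, "+", fixed = TRUE))),
                          c(a, b))
      out[[length(out) + 1L]] <- list(source = a, sink = b,
                                      interior = sort(interior))
    }
  }
  out
}

# All-pairs breakpoint matching oracle: plain double loop over same-sample
# call pairs, gap distance computed arithmetically, nearest-first one-to-one
# assignment with leftmost tie-break.
oracle_match <- function(graph_calls, ref_calls, window_bp = 100L,
                         min_sv_bp = 50L) {
  ref <- ref_calls[ref_calls$svtype != "BND" & abs(ref_calls$svlen) > min_sv_bp, ,
                   drop = FALSE]
  cand <- list()
  for (i in seq_len(nrow(graph_calls))) {
    for (j in seq_len(nrow(ref))) {
      if (graph_calls$sample_id[i] != ref$sample_id[j]) next
      if (graph_calls$chrom[i] != ref$chrom[j]) next
      re <- max(ref$end[j], ref$start[j] + 1L)
      d <- max(ref$start[j] - graph_calls$end[i],
               graph_calls$start[i] - re, 0L)
      if (d <= window_bp) cand[[length(cand) + 1L]] <-
          data.frame(gi = i, rj = j, d = d,
                     rs = ref$start[j], gs = graph_calls$start[i])
    }
  }
  if (!length(cand)) return(data.frame(graph_id = character(), ref_id = character()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$d, cand$rs, cand$gs), , drop = FALSE]
  used_g <- logical(nrow(graph_calls)); used_r <- logical(nrow(ref))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (used_g[cand$gi[k]] || used_r[cand$rj[k]]) next
    used_g[cand$gi[k]] <- TRUE; used_r[cand$rj[k]] <- TRUE
    keep[k] <- TRUE
  }
  data.frame(graph_id = graph_calls$graph_id[cand$gi[keep]],
             ref_id = ref$call_id[cand$rj[keep]], stringsAsFactors = FALSE)
}

# Transitive-closure merging oracle: BFS over the pairwise merge predicate.
oracle_merge <- function(calls, min_size_bp = 50L, max_dist_frac = 0.10) {
  calls <- calls[abs(calls$svlen) >= min_size_bp, , drop = FALSE]
  n <- nrow(calls)
  if (!n) return(list())
  pred <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (calls$chrom[i] != calls$chrom[j] || calls$svtype[i] != calls$svtype[j]) next
    tol <- max_dist_frac * max(abs(calls$svlen[i]), abs(calls$svlen[j]))
    pred[i, j] <- abs(calls$start[i] - calls$start[j]) <= tol &&
      abs(calls$end[i] - calls$end[j]) <= tol
  }
  seen <- logical(n); comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    comp <- i; queue <- i; seen[i] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(pred[v, ] & !seen)
      seen[nb] <- TRUE; comp <- c(comp, nb); queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(calls$call_id[comp])
  }
  comps[order(vapply(comps, `[`, "", 1L))]
}

# Exhaustive Mendelian oracle: enumerate the transmissible copy sets.
oracle_mendel <- function(p, f, m) {
  trans <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  possible <- unique(outer(trans[[as.character(f)]], trans[[as.character(m)]],
                           `+`))
  if (p %in% possible) "consistent"
  else if (p < min(possible)) "false_negative"
  else "false_positive"
}
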