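#' Load a phenotype ontology with gene annotations
#'
#' Builds the term DAG (child to parents), propagates gene annotations to
#' ancestral closures, and computes each term's information content as
#' `-log2(annotation frequency)`, the annotation frequency being the
#' fraction of genes whose propagated annotation set contains the term.
#' The root (and any term annotated to every gene) has IC 0; a term's IC is
#' never smaller than any of its ancestors'.
#'
#' @param edges data.frame (or TSV path) with columns `term`, `parent`
#' @param annotations data.frame (or TSV path) with columns `gene`, `term`
#' @return object of class `pheno_ontology`
#' @export
load_ontology <- function(edges, annotations) {
  if (is.character(edges)) edges <- read.table(edges, header = TRUE, sep = "\t",
                                               stringsAsFactors = FALSE)
  if (is.character(annotations)) annotations <- read.table(annotations, header = TRUE,
                                                           sep = "\t",
                                                           stringsAsFactors = FALSE)
  terms <- unique(c(edges$term, edges$parent, annotations$term))
  parents <- split(edges$parent, factor(edges$term, levels = terms))
  # ancestral closure per term, with cycle detection
  closure <- setNames(vector("list", length(terms)), terms)
  visiting <- character()
  close_term <- function(t) {
    if (!is.null(closure[[t]])) return(closure[[t]])
    if (t %in% visiting) stop("ontology contains a cycle through term ", t)
    visiting <<- c(visiting, t)
    anc <- unique(unlist(lapply(parents[[t]], close_term)))
    visiting <<- setdiff(visiting, t)
    closure[[t]] <<- unique(c(t, anc))
    closure[[t]]
  }
  for (t in terms) close_term(t)
  genes <- unique(annotations$gene)
  gene_terms <- lapply(split(annotations$term, annotations$gene), function(ts) {
    unique(unlist(closure[ts]))
  })
  n_genes <- length(genes)
  freq <- vapply(terms, function(t) {
    sum(vapply(gene_terms, function(gt) t %in% gt, logical(1))) / n_genes
  }, numeric(1))
  ic <- ifelse(freq > 0, -log2(freq), Inf)
  structure(list(terms = terms, closure = closure, gene_terms = gene_terms,
                 ic = setNames(ic, terms), n_genes = n_genes),
            class = "pheno_ontology")
}

#' @export
print.pheno_ontology <- function(x, ...) {
  cat("pheno_ontology:", length(x$terms), "terms,", x$n_genes,
      "annotated genes; max IC =", round(max(x$ic[is.finite(x$ic)]), 2), "bits\n")
  invisible(x)
}

#' Ancestral closure of a term set
#'
#' @param ontology a `pheno_ontology`
#' @param terms character vector of term ids
#' @return character vector: the terms plus all their ancestors
#' @export
term_closure <- function(ontology, terms) {
  unknown <- setdiff(terms, ontology$terms)
  if (length(unknown)) stop("unknown ontology term(s): ",
                            paste(unknown, collapse = ", "))
  unique(unlist(ontology$closure[terms]))
}

#' Phenotype-fit score of a gene for a patient
#'
#' An information-content sum over the terms shared between the ancestral
#' closure of the patient's phenotype terms and the gene's propagated
#' annotation set (a Phrank-style score, in bits).  Zero when the closures
#' are disjoint or the gene is unannotated; adding a matching patient term
#' can only increase the score.
#'
#' @param patient_terms character vector of the patient's phenotype terms
#' @param gene gene id
#' @param ontology a `pheno_ontology`
#' @return non-negative score in bits
#' @export
pheno_score <- function(patient_terms, gene, ontology) {
  pc <- term_closure(ontology, patient_terms)
  gt <- ontology$gene_terms[[gene]]
  if (is.null(gt)) return(0)
  shared <- intersect(pc, gt)
  if (!length(shared)) return(0)
  sum(ontology$ic[shared])
}

#' Exons made "highly polymorphic" by common non-reference alleles
#'
#' An exon is flagged when the fraction of cohort haplotypes carrying any
#' non-reference allele overlapping it exceeds `cutoff`.
#'
#' @param records allele-frequency records with `bubble_id` and `frequency`
#' @param bubbles bubble table (for coordinates)
#' @param exons exon feature table
#' @param cutoff haplotype-fraction cutoff (default 0.05)
#' @return character vector of exon ids
#' @export
polymorphic_exons <- function(records, bubbles, exons, cutoff = 0.05) {
  proj <- project_allele(bubbles)$intervals
  i <- match(records$bubble_id, proj$bubble_id)
  out <- character()
  for (chrom in unique(exons$chrom)) {
    ei <- which(exons$chrom == chrom)
    ri <- which(proj$chrom[i] == chrom & !is.na(i))
    if (!length(ri)) next
    h <- IRanges::findOverlaps(.ir(exons$start[ei], exons$end[ei]),
                               .ir(proj$start[i][ri], proj$end[i][ri]))
    if (!length(h)) next
    load <- tapply(records$frequency[ri][S4Vectors::subjectHits(h)],
                   S4Vectors::queryHits(h), sum)
    out <- c(out, exons$exon_id[ei][as.integer(names(load))[load > cutoff]])
  }
  unique(out)
}

#' Split reference-based calls into concordant and discordant consensus sets
#'
#' Concordant reference calls are those matched by a graph call under the
#' benchmark matcher; discordant are the rest.  Both sets are also reported
#' restricted to the rare stratum (MAF below `maf_cutoff`).
#'
#' @param ref_calls reference-based calls (with a `maf` column)
#' @param graph_calls graph calls from [graph_calls_for_benchmark()]
#' @param window_bp,min_sv_bp matcher parameters (see [match_calls()])
#' @param maf_cutoff rare-stratum MAF cutoff (default 0.05)
#' @return list of class `consensus_sets` with `concordant`, `discordant`,
#'   `concordant_rare`, `discordant_rare`, `eligible`, `matches`
#' @export
build_consensus <- function(ref_calls, graph_calls, window_bp = 100L,
                            min_sv_bp = 50L, maf_cutoff = 0.05) {
  m <- match_calls(graph_calls, ref_calls, window_bp = window_bp,
                   min_sv_bp = min_sv_bp)
  eligible <- ref_calls[ref_calls$svtype != "BND" & abs(ref_calls$svlen) > min_sv_bp, ,
                        drop = FALSE]
  hit <- eligible$call_id %in% m$pairs$ref_id
  rare <- !is.na(eligible$maf) & eligible$maf < maf_cutoff
  structure(list(concordant = eligible[hit, , drop = FALSE],
                 discordant = eligible[!hit, , drop = FALSE],
                 concordant_rare = eligible[hit & rare, , drop = FALSE],
                 discordant_rare = eligible[!hit & rare, , drop = FALSE],
                 eligible = eligible, rare = eligible[rare, , drop = FALSE],
                 matches = m, maf_cutoff = maf_cutoff),
            class = "consensus_sets")
}

#' Replication precision of consensus sets against a third callset
#'
#' Treating an independent callset as the replication truth, reports the
#' fraction of each set's calls that it matches, for the reference-alone and
#' concordant sets in the `all` and `rare` strata.
#'
#' @param sets a `consensus_sets` object
#' @param third_calls independent callset (same table shape as `ref_calls`)
#' @param window_bp,min_sv_bp matcher parameters
#' @return data.frame with `set`, `stratum`, `n`, `n_matched`, `precision`
#'   (`NA` for empty sets)
#' @export
validation_precision <- function(sets, third_calls, window_bp = 100L,
                                 min_sv_bp = 50L) {
  third <- third_calls[third_calls$svtype != "BND" &
                         abs(third_calls$svlen) > min_sv_bp, , drop = FALSE]
  third$end <- ifelse(is.na(third$end), third$start + 1L,
                      pmax(third$end, third$start + 1L))
  prec <- function(set) {
    if (!nrow(set)) return(c(n = 0L, n_matched = 0L, precision = NA_real_))
    a <- data.frame(sample_id = set$sample_id, chrom = set$chrom,
                    start = set$start,
                    end = ifelse(is.na(set$end), set$start + 1L,
                                 pmax(set$end, set$start + 1L)))
    b <- third[, c("sample_id", "chrom", "start", "end")]
    m <- .match_interval_sets(a, b, window_bp)
    c(n = nrow(set), n_matched = nrow(m), precision = nrow(m) / nrow(set))
  }
  spec <- list(c("ref_alone", "all"), c("ref_alone", "rare"),
               c("concordant", "all"), c("concordant", "rare"))
  tabs <- list(sets$eligible, sets$rare, sets$concordant, sets$concordant_rare)
  out <- do.call(rbind, lapply(seq_along(spec), function(i) {
    p <- prec(tabs[[i]])
    data.frame(set = spec[[i]][1], stratum = spec[[i]][2],
               n = p[["n"]], n_matched = p[["n_matched"]],
               precision = p[["precision"]], stringsAsFactors = FALSE)
  }))
  out
}

#' Filter and rank rare exonic SV candidates by phenotype fit
#'
#' Candidates (already restricted to cohort-private, consensus-concordant,
#' exon-overlapping alleles) are scored per patient-gene pair, candidates
#' not exceeding `score_threshold` are dropped, the top-quartile rule is
#' applied in conjunction (AND) when `apply_quartile` is set, candidates in
#' highly polymorphic exons are dropped, and the remainder is sorted by
#' score (descending), then allele rarity, then position.
#'
#' @param candidates data.frame with `candidate_id`, `sample_id`, `gene`,
#'   `exon_id`, `frequency`, `chrom`, `start`
#' @param ontology a `pheno_ontology`
#' @param patient_terms named list mapping sample id to phenotype terms
#' @param scores optional externally computed scores (named by
#'   `candidate_id`); computed with [pheno_score()] when omitted
#' @param score_threshold absolute score cutoff, kept when strictly greater
#'   (default 5)
#' @param apply_quartile also require the score to reach the top quartile of
#'   candidate scores
#' @param polymorphic character vector of highly polymorphic exon ids to
#'   exclude (see [polymorphic_exons()])
#' @return the surviving candidates with `score` and `rank` columns,
#'   sorted; attribute `n_dropped` records the filter tallies
#' @export
rank_candidates <- function(candidates, ontology = NULL, patient_terms = NULL,
                            scores = NULL, score_threshold = 5,
                            apply_quartile = TRUE, polymorphic = character()) {
  if (is.null(scores)) {
    scores <- vapply(seq_len(nrow(candidates)), function(i) {
      pheno_score(patient_terms[[candidates$sample_id[i]]],
                  candidates$gene[i], ontology)
    }, numeric(1))
    names(scores) <- candidates$candidate_id
  }
  cand <- candidates
  cand$score <- unname(scores[cand$candidate_id])
  n0 <- nrow(cand)
  keep <- cand$score > score_threshold
  if (apply_quartile && any(!is.na(cand$score))) {
    keep <- keep & cand$score >= quantile(cand$score, 0.75, na.rm = TRUE)
  }
  n_below <- sum(!keep)
  cand <- cand[keep, , drop = FALSE]
  n_poly <- sum(cand$exon_id %in% polymorphic)
  cand <- cand[!cand$exon_id %in% polymorphic, , drop = FALSE]
  cand <- cand[order(-cand$score, cand$frequency, cand$chrom, cand$start), ,
               drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  attr(cand, "n_dropped") <- c(below_threshold = n_below,
                               polymorphic_exon = n_poly, input = n0)
  cand
}
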