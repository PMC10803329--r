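#' Configuration for the synthetic cohort generator
#'
#' Returns the default simulation configuration, optionally overridden.
#' The defaults define the study conditions emulated by the generator: two
#' 1 Mbp chromosomes, 200 SV loci with a rare-skewed Beta(0.2, 2) allele
#' frequency spectrum, a 30-sample cohort A (4 trios, 3 sibling-pair
#' families, 1 identical-twin pair, 10 unrelated probands; 60 haplotypes)
#' and a 10-sample unrelated cohort B (20 haplotypes), plus caller and
#' assembly-validity noise.  See the package vignette for the rationale
#' behind each value.
#'
#' @param seed mandatory integer seed; every downstream draw derives from it
#' @param ... named overrides of any default
#' @return a list of class `cohort_config`
#' @export
cohort_config <- function(seed, ...) {
  stopifnot(!missing(seed), is.numeric(seed))
  cfg <- list(
    seed = as.integer(seed),
    chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
    n_loci = 200L,
    n_trios = 4L, n_sibpairs = 3L, n_twinpairs = 1L,
    n_singlesA = 10L, n_samplesB = 10L,
    class_mix = c(insertion = 0.35, deletion = 0.35, complex = 0.20, tr = 0.10),
    beta_shape = c(0.2, 2),
    partition_probs = c(shared = 0.50, cohortA_only = 0.35, cohortB_only = 0.15),
    del_size = c(60L, 2000L), ins_size = c(60L, 2000L),
    complex_ref_size = c(50L, 500L), complex_alt_size = c(50L, 1500L),
    tr_motif_size = c(5L, 40L),
    te_fraction = 0.15, te_coverage = 0.9, te_decoy_coverage = 0.7,
    te_decoy_fraction = 0.25,
    missing_rate = 0.03,
    invalid_rate = 0.05,
    spurious_rate = 0.01, spurious_invalid_prob = 0.8,
    ref_caller = list(fp_rate = 0.05, fn_rate = 0.08, jitter_sd = 10),
    third_caller = list(fp_rate = 0.30, fn_rate = 0.15, jitter_sd = 20),
    n_genes_per_chrom = 15L, gene_bp = 8000L, n_exons_per_gene = 4L,
    exon_bp = 400L, omim_fraction = 0.3,
    causal = list(enabled = TRUE, deletion_bp = 800L),
    polymorphic_exon_freq = 0.4)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  rates <- c(cfg$class_mix, cfg$partition_probs, cfg$missing_rate,
             cfg$invalid_rate, cfg$spurious_rate, cfg$te_fraction)
  stopifnot(all(rates >= 0 & rates <= 1), all(cfg$chrom_lengths > 0))
  structure(cfg, class = "cohort_config")
}

# ---- internal builders -------------------------------------------------

.sim_samples <- function(cfg) {
  samples <- list(); fams <- list(); k <- 0L
  nxt <- function() { k <<- k + 1L; sprintf("A%03d", k) }
  ghost <- 0L
  gnxt <- function() { ghost <<- ghost + 1L; sprintf("P%03d", ghost) }
  for (t in seq_len(cfg$n_trios)) {
    fa <- nxt(); mo <- nxt(); pr <- nxt()
    fams[[length(fams) + 1L]] <- data.frame(
      family_id = sprintf("T%02d", t), sample_id = c(fa, mo, pr),
      father_id = c("0", "0", fa), mother_id = c("0", "0", mo),
      role = c("father", "mother", "proband"), type = "trio",
      sequenced = TRUE, stringsAsFactors = FALSE)
  }
  for (s in seq_len(cfg$n_sibpairs)) {
    fa <- gnxt(); mo <- gnxt(); c1 <- nxt(); c2 <- nxt()
    fams[[length(fams) + 1L]] <- data.frame(
      family_id = sprintf("S%02d", s),
      sample_id = c(fa, mo, c1, c2),
      father_id = c("0", "0", fa, fa), mother_id = c("0", "0", mo, mo),
      role = c("father", "mother", "sib", "sib"), type = "sibpair",
      sequenced = c(FALSE, FALSE, TRUE, TRUE), stringsAsFactors = FALSE)
  }
  for (w in seq_len(cfg$n_twinpairs)) {
    fa <- gnxt(); mo <- gnxt(); c1 <- nxt(); c2 <- nxt()
    fams[[length(fams) + 1L]] <- data.frame(
      family_id = sprintf("W%02d", w),
      sample_id = c(fa, mo, c1, c2),
      father_id = c("0", "0", fa, fa), mother_id = c("0", "0", mo, mo),
      role = c("father", "mother", "twin", "twin"), type = "twin",
      sequenced = c(FALSE, FALSE, TRUE, TRUE), stringsAsFactors = FALSE)
  }
  for (u in seq_len(cfg$n_singlesA)) {
    id <- nxt()
    fams[[length(fams) + 1L]] <- data.frame(
      family_id = paste0("U", id), sample_id = id, father_id = "0",
      mother_id = "0", role = "single", type = "single", sequenced = TRUE,
      stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, fams)
  ped$cohort <- "cohortA"
  b <- data.frame(family_id = paste0("U", sprintf("B%03d", seq_len(cfg$n_samplesB))),
                  sample_id = sprintf("B%03d", seq_len(cfg$n_samplesB)),
                  father_id = "0", mother_id = "0", role = "single",
                  type = "single", sequenced = TRUE, cohort = "cohortB",
                  stringsAsFactors = FALSE)
  rbind(ped, b)
}

.sim_features <- function(cfg) {
  genes <- list(); exons <- list()
  for (chrom in names(cfg$chrom_lengths)) {
    L <- cfg$chrom_lengths[[chrom]]
    n <- cfg$n_genes_per_chrom
    starts <- round(seq_len(n) * L / (n + 1))
    for (i in seq_len(n)) {
      gid <- sprintf("GENE%s_%02d", sub("chr", "", chrom), i)
      genes[[gid]] <- data.frame(gene_id = gid, chrom = chrom,
                                 start = starts[i], end = starts[i] + cfg$gene_bp,
                                 stringsAsFactors = FALSE)
      ew <- cfg$gene_bp %/% cfg$n_exons_per_gene
      for (j in seq_len(cfg$n_exons_per_gene)) {
        es <- starts[i] + (j - 1L) * ew
        exons[[paste0(gid, "_E", j)]] <- data.frame(
          exon_id = paste0(gid, "_E", j), gene_id = gid, chrom = chrom,
          start = es, end = es + cfg$exon_bp, stringsAsFactors = FALSE)
      }
    }
  }
  genes <- do.call(rbind, genes); rownames(genes) <- NULL
  exons <- do.call(rbind, exons); rownames(exons) <- NULL
  omim <- sort(sample(genes$gene_id, max(1L, round(cfg$omim_fraction * nrow(genes)))))
  genes$omim <- genes$gene_id %in% omim
  list(genes = genes, exons = exons, omim = omim)
}

.sim_loci <- function(cfg) {
  out <- list()
  per_chrom <- ceiling(cfg$n_loci / length(cfg$chrom_lengths))
  k <- 0L
  for (chrom in names(cfg$chrom_lengths)) {
    L <- cfg$chrom_lengths[[chrom]]
    n <- min(per_chrom, cfg$n_loci - k)
    if (n <= 0L) break
    margin <- 10000
    slot_w <- (L - 2 * margin) / n
    span_max <- floor(slot_w - 700)   # anchors of >= 300 bp around each locus
    if (span_max < 60L) {
      stop("locus capacity exceeded: ", n, " loci on a ", L,
           " bp chromosome leave no room for SV-sized reference spans")
    }
    for (i in seq_len(n)) {
      k <- k + 1L
      cls <- sample(names(cfg$class_mix), 1L, prob = cfg$class_mix)
      span <- switch(cls,
        insertion = 0L,
        deletion = sample(cfg$del_size[1]:min(cfg$del_size[2], span_max), 1L),
        complex = sample(cfg$complex_ref_size[1]:min(cfg$complex_ref_size[2], span_max), 1L),
        tr = NA_integer_)
      motif_len <- if (cls == "tr") sample(cfg$tr_motif_size[1]:cfg$tr_motif_size[2], 1L) else NA_integer_
      ref_copies <- if (cls == "tr") sample(3:6, 1L) else NA_integer_
      if (cls == "tr") {
        ref_copies <- min(ref_copies, max(1L, span_max %/% motif_len))
        span <- motif_len * ref_copies
      }
      slot_start <- margin + (i - 1L) * slot_w
      start <- round(slot_start + 300 + runif(1) * (slot_w - span - 600))
      out[[k]] <- data.frame(locus_id = sprintf("L%04d", k), chrom = chrom,
                             start = as.integer(start),
                             end = as.integer(start + span), class = cls,
                             motif_len = motif_len, ref_copies = ref_copies,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

.sim_alleles <- function(cfg, loci) {
  recs <- list(); seqs <- list()
  sine_cons <- .random_dna(300L); line_cons <- .random_dna(6000L)
  mutate <- function(seq, rate = 0.05) {
    s <- strsplit(seq, "")[[1]]
    i <- runif(length(s)) < rate
    s[i] <- sample(c("A", "C", "G", "T"), sum(i), replace = TRUE)
    paste(s, collapse = "")
  }
  for (r in seq_len(nrow(loci))) {
    lc <- loci[r, ]
    n_alt <- switch(lc$class, insertion = 1L, deletion = 1L,
                    complex = sample(2:4, 1L), tr = sample(2:6, 1L))
    for (a in seq_len(n_alt)) {
      aid <- sprintf("%s.a%d", lc$locus_id, a)
      te <- "none"; te_planted_cov <- NA_real_
      if (lc$class == "deletion") {
        len <- 0L; seq <- ""
      } else if (lc$class == "insertion") {
        if (runif(1) < cfg$te_fraction) {
          if (runif(1) < 0.8) {
            te <- "SINE"; seq <- mutate(sine_cons)
            len <- nchar(seq)
          } else {
            te <- "LINE"
            seq <- mutate(substr(line_cons, 1L, sample(5200:6000, 1L)))
            len <- nchar(seq)
          }
          te_planted_cov <- if (runif(1) < cfg$te_decoy_fraction)
            cfg$te_decoy_coverage else cfg$te_coverage
        } else {
          len <- sample(cfg$ins_size[1]:cfg$ins_size[2], 1L)
          seq <- .random_dna(len)
        }
      } else if (lc$class == "tr") {
        seq <- strrep(.random_dna(lc$motif_len), lc$ref_copies + 2L)
        len <- nchar(seq)   # placeholder; rebuilt per locus below
      } else {
        # complex alt: net length change vs the reference span stays >= 60 bp
        # (alleles below the SV size threshold are out of scope)
        repeat {
          len <- sample(cfg$complex_alt_size[1]:cfg$complex_alt_size[2], 1L)
          if (abs(len - (lc$end - lc$start)) >= 60L) break
        }
        seq <- .random_dna(len)
      }
      partition <- sample(names(cfg$partition_probs), 1L, prob = cfg$partition_probs)
      freq <- rbeta(1, cfg$beta_shape[1], cfg$beta_shape[2])
      recs[[aid]] <- data.frame(allele_id = aid, locus_id = lc$locus_id,
                                class = lc$class, length_bp = len,
                                partition = partition, freq = freq,
                                te = te, te_planted_cov = te_planted_cov,
                                stringsAsFactors = FALSE)
      seqs[[aid]] <- seq
    }
  }
  alleles <- do.call(rbind, recs); rownames(alleles) <- NULL
  # tandem-repeat alleles of one locus must share the motif: rebuild per locus
  for (lid in unique(alleles$locus_id[alleles$class == "tr"])) {
    lc <- loci[loci$locus_id == lid, ]
    motif <- .random_dna(lc$motif_len)
    ai <- which(alleles$locus_id == lid)
    # copy-number jumps of at least 60 bp so every allele is SV-sized
    d_min <- ceiling(60 / lc$motif_len)
    deltas <- c(d_min:(d_min + 5L), -(d_min:(d_min + 5L)))
    deltas <- deltas[lc$ref_copies + deltas >= 1L]
    used <- integer()
    for (i in ai) {
      cand <- setdiff(deltas, used)
      dd <- if (length(cand)) cand[sample.int(length(cand), 1L)] else
        max(deltas) + abs(used[1])
      used <- c(used, dd)
      cp <- lc$ref_copies + dd
      seqs[[alleles$allele_id[i]]] <- strrep(motif, cp)
      alleles$length_bp[i] <- nchar(seqs[[alleles$allele_id[i]]])
    }
  }
  list(alleles = alleles, seqs = seqs,
       consensus = list(SINE = sine_cons, LINE = line_cons))
}

# population + family carriage: returns matrix loci x haplotypes of allele
# ids ("ref" for the reference path)
.sim_carriage <- function(cfg, loci, alleles, ped) {
  seq_samp <- ped$sample_id[ped$sequenced]
  all_samp <- ped$sample_id
  haps <- as.vector(t(outer(all_samp, c(".h1", ".h2"), paste0)))
  cohort <- setNames(ped$cohort, ped$sample_id)
  founders <- ped$sample_id[ped$father_id == "0"]
  children <- ped$sample_id[ped$father_id != "0"]

  carr <- matrix("ref", nrow = nrow(loci), ncol = length(haps),
                 dimnames = list(loci$locus_id, haps))
  f_haps <- as.vector(t(outer(founders, c(".h1", ".h2"), paste0)))
  f_cohort <- cohort[sub("\\.h[12]$", "", f_haps)]
  for (r in seq_len(nrow(loci))) {
    ai <- which(alleles$locus_id == loci$locus_id[r])
    aid <- alleles$allele_id[ai]
    f <- alleles$freq[ai]
    part <- alleles$partition[ai]
    for (co in c("cohortA", "cohortB")) {
      hsel <- f_haps[f_cohort == co]
      allowed <- part == "shared" | part == paste0(co, "_only")
      p <- f * allowed
      if (sum(p) > 0.95) p <- p * 0.95 / sum(p)
      carr[r, hsel] <- sample(c(aid, "ref"), length(hsel), replace = TRUE,
                              prob = c(p, 1 - sum(p)))
    }
  }
  # children inherit whole parental haplotypes, per chromosome
  chrom_of <- loci$chrom
  for (ch in children) {
    fa <- ped$father_id[ped$sample_id == ch]
    mo <- ped$mother_id[ped$sample_id == ch]
    for (chrom in unique(chrom_of)) {
      li <- chrom_of == chrom
      carr[li, paste0(ch, ".h1")] <- carr[li, paste0(fa, ".h", sample(1:2, 1L))]
      carr[li, paste0(ch, ".h2")] <- carr[li, paste0(mo, ".h", sample(1:2, 1L))]
    }
  }
  # identical twins: second twin copies the first
  for (fam in unique(ped$family_id[ped$type == "twin"])) {
    tw <- ped$sample_id[ped$family_id == fam & ped$role == "twin"]
    carr[, paste0(tw[2], ".h1")] <- carr[, paste0(tw[1], ".h1")]
    carr[, paste0(tw[2], ".h2")] <- carr[, paste0(tw[1], ".h2")]
  }
  carr[, as.vector(t(outer(seq_samp, c(".h1", ".h2"), paste0))), drop = FALSE]
}

# build the rGFA graph from reference + observed alleles
.sim_graph <- function(cfg, ref_seqs, loci, alleles, seqs, carriers, hap_rank) {
  nodes <- list(); edges <- list(); nid <- 0L
  new_id <- function() { nid <<- nid + 1L; paste0("s", nid) }
  locus_nodes <- list()   # locus_id -> list(src, snk, ref_node, alt nodes)
  for (chrom in names(cfg$chrom_lengths)) {
    L <- cfg$chrom_lengths[[chrom]]
    lc <- loci[loci$chrom == chrom, , drop = FALSE]
    lc <- lc[order(lc$start), , drop = FALSE]
    cuts <- c(0L)
    for (r in seq_len(nrow(lc))) cuts <- c(cuts, lc$start[r], lc$end[r])
    cuts <- c(cuts, as.integer(L))
    seg_ids <- character(); chain <- character()
    prev <- NULL
    for (i in seq_len(length(cuts) - 1L)) {
      s <- cuts[i]; e <- cuts[i + 1L]
      if (e == s) next   # insertion point: zero-width cut
      id <- new_id()
      nodes[[id]] <- data.frame(node_id = id,
                                sequence = substr(ref_seqs[[chrom]], s + 1L, e),
                                stable_name = chrom, stable_offset = s,
                                rank = 0L, stringsAsFactors = FALSE)
      chain <- c(chain, id)
      if (!is.null(prev)) edges[[length(edges) + 1L]] <- c(prev, id)
      prev <- id
      seg_ids <- c(seg_ids, id)
    }
    seg_start <- vapply(seg_ids, function(id) nodes[[id]]$stable_offset, numeric(1))
    seg_end <- seg_start + vapply(seg_ids, function(id) nchar(nodes[[id]]$sequence), numeric(1))
    for (r in seq_len(nrow(lc))) {
      s <- lc$start[r]; e <- lc$end[r]
      src <- seg_ids[which(seg_end == s)[1]]
      snk <- seg_ids[which(seg_start == e)[1]]
      ref_node <- if (e > s) seg_ids[which(seg_start == s & seg_end == e)[1]] else NULL
      alt_ids <- character()
      ai <- which(alleles$locus_id == lc$locus_id[r])
      for (j in ai) {
        aid <- alleles$allele_id[j]
        carr <- carriers[[aid]]
        if (!length(carr)) { alt_ids <- c(alt_ids, NA_character_); next }
        if (alleles$class[j] == "deletion") {
          edges[[length(edges) + 1L]] <- c(src, snk)
          alt_ids <- c(alt_ids, "")   # direct edge, no node
        } else {
          id <- new_id()
          intro <- carr[which.min(hap_rank[carr])]
          nodes[[id]] <- data.frame(node_id = id, sequence = seqs[[aid]],
                                    stable_name = intro, stable_offset = 0L,
                                    rank = unname(hap_rank[intro]),
                                    stringsAsFactors = FALSE)
          edges[[length(edges) + 1L]] <- c(src, id)
          edges[[length(edges) + 1L]] <- c(id, snk)
          alt_ids <- c(alt_ids, id)
        }
      }
      locus_nodes[[lc$locus_id[r]]] <- list(src = src, snk = snk,
                                            ref_node = ref_node,
                                            alt_nodes = setNames(alt_ids, alleles$allele_id[ai]))
    }
  }
  nodes <- do.call(rbind, nodes); rownames(nodes) <- NULL
  ed <- unique(do.call(rbind, edges))
  edges <- data.frame(from = ed[, 1], from_orient = "+", to = ed[, 2],
                      to_orient = "+", stringsAsFactors = FALSE)
  list(graph = pangenome_graph(nodes, edges), locus_nodes = locus_nodes)
}

.allele_key_of <- function(locus_nodes, lid, aid_or_ref) {
  ln <- locus_nodes[[lid]]
  if (identical(aid_or_ref, "ref")) {
    return(paste(c(ln$src, ln$ref_node, ln$snk), collapse = "+"))
  }
  alt <- ln$alt_nodes[[aid_or_ref]]
  if (is.na(alt)) return(NA_character_)
  if (alt == "") paste(c(ln$src, ln$snk), collapse = "+")
  else paste(c(ln$src, alt, ln$snk), collapse = "+")
}

# Emulate a reference-based SV caller.  Scope: loci that are biallelic in
# the cohort (reference path plus exactly one observed alternate).  The
# caller reports carriers of the minor of the two alleles, mirroring the
# minor-allele (ALT) convention of the graph benchmark, so that with zero
# planted error the two callsets correspond exactly and planted FP/FN rates
# are the only source of discordance.
.emulate_caller <- function(cfg, rates, loci, alleles, carr, samples, prefix,
                            exempt = NULL, n_haps_total = NULL) {
  obs_alt <- alleles[alleles$n_carriers > 0L, , drop = FALSE]
  tab <- table(obs_alt$locus_id)
  bial <- loci[loci$locus_id %in% names(tab)[tab == 1L], , drop = FALSE]
  hap_samp <- sub("\\.h[12]$", "", colnames(carr))
  alt_id <- vapply(bial$locus_id, function(l) {
    obs_alt$allele_id[obs_alt$locus_id == l]
  }, character(1))
  alt_m <- carr[bial$locus_id, , drop = FALSE] == alt_id
  alt_count <- rowSums(alt_m)
  minor_is_alt <- alt_count <= ncol(carr) - alt_count   # ties: alt is minor
  carrier_m <- alt_m
  carrier_m[!minor_is_alt, ] <- !alt_m[!minor_is_alt, , drop = FALSE]
  ind <- outer(hap_samp, samples, `==`) + 0
  cn_m <- carrier_m %*% ind   # loci x samples copy numbers of the minor allele
  colnames(cn_m) <- samples
  hit <- which(cn_m > 0L, arr.ind = TRUE)
  freq <- rowSums(carrier_m) / ncol(carr)
  li <- hit[, 1]; si <- hit[, 2]
  is_exempt <- if (!is.null(exempt)) {
    bial$locus_id[li] == exempt$locus_id & samples[si] %in% exempt$samples
  } else rep(FALSE, length(li))
  is_fn <- !is_exempt & runif(length(li)) < rates$fn_rate
  fn <- data.frame(sample_id = samples[si][is_fn],
                   locus_id = bial$locus_id[li][is_fn],
                   stringsAsFactors = FALSE)
  li2 <- li[!is_fn]; si2 <- si[!is_fn]; ex2 <- is_exempt[!is_fn]
  jit <- as.integer(round(rnorm(length(li2), 0, rates$jitter_sd)))
  jit[ex2] <- 0L
  pos <- pmax(1L, bial$start[li2] + 1L + jit)
  span <- bial$end[li2] - bial$start[li2]
  alt_len <- alleles$length_bp[match(alt_id[li2], alleles$allele_id)]
  # net length of the minor allele relative to the major one
  net <- ifelse(minor_is_alt[li2], alt_len - span, span - alt_len)
  is_del <- net < 0L
  k <- length(li2)
  calls <- if (k) data.frame(
    call_id = sprintf("%s%05d", prefix, seq_len(k)),
    sample_id = samples[si2], chrom = bial$chrom[li2],
    pos = pos, start = pos - 1L,
    end = ifelse(is_del, pos - net, pos),
    svtype = ifelse(is_del, "DEL", "INS"),
    svlen = net,
    cn = as.integer(cn_m[cbind(li2, si2)]),
    maf = freq[li2], truth = "TP", locus_id = bial$locus_id[li2],
    stringsAsFactors = FALSE) else NULL
  # false positives: random events away from any real locus
  n_true <- if (is.null(calls)) 0L else nrow(calls)
  n_fp_total <- rbinom(1L, n_true, rates$fp_rate)
  fp <- list()
  if (n_fp_total > 0L) {
    fp_samples <- sample(samples, n_fp_total, replace = TRUE)
    for (i in seq_len(n_fp_total)) {
      repeat {
        chrom <- sample(names(cfg$chrom_lengths), 1L)
        pos <- sample.int(cfg$chrom_lengths[[chrom]] - 3000L, 1L) + 500L
        d <- abs(loci$start[loci$chrom == chrom] - pos)
        if (all(d > 3000L)) break
      }
      k <- k + 1L
      svtype <- sample(c("DEL", "INS"), 1L)
      svlen <- sample(60:1500, 1L) * ifelse(svtype == "DEL", -1L, 1L)
      fp[[i]] <- data.frame(call_id = sprintf("%s%05d", prefix, k),
                            sample_id = fp_samples[i], chrom = chrom, pos = pos,
                            start = pos - 1L,
                            end = ifelse(svtype == "DEL", pos + abs(svlen), pos),
                            svtype = svtype, svlen = svlen, cn = 1L,
                            maf = 1 / (n_haps_total %||% ncol(carr)),
                            truth = "FP", locus_id = NA_character_,
                            stringsAsFactors = FALSE)
    }
  }
  calls <- rbind(calls, if (length(fp)) do.call(rbind, fp))
  if (is.null(calls)) {
    calls <- data.frame(call_id = character(), sample_id = character(),
                        chrom = character(), pos = integer(), start = integer(),
                        end = integer(), svtype = character(), svlen = numeric(),
                        cn = integer(), maf = numeric(), truth = character(),
                        locus_id = character(), stringsAsFactors = FALSE)
  }
  list(calls = calls[order(calls$chrom, calls$pos, calls$sample_id), , drop = FALSE],
       fn_events = fn)
}

#' Simulate a complete synthetic pangenome-SV cohort
#'
#' Generates, from a single seed, a toy study in which every downstream
#' operation of the package has a known truth: a random reference genome, SV
#' loci with planted alleles and a rare-skewed frequency spectrum shared
#' between or private to two sub-cohorts, family structure with Mendelian
#' transmission (including an identical twin pair), an rGFA pangenome graph
#' containing every observed allele as a bubble path, per-haplotype call
#' tracks with planted assembly-validity noise and spurious calls, two
#' independent noisy reference-based callers, gene/exon/OMIM annotations, a
#' toy phenotype ontology, and one planted causal exonic deletion in a
#' phenotype-matched OMIM gene carried by the first trio's proband
#' (maternally inherited).
#'
#' @param config a [cohort_config()]
#' @param dir optional directory: when given, all cohort files (reference
#'   FASTA, rGFA, call tracks, validity BEDs, VCFs, PED, GFF3, ontology
#'   TSVs, truth JSON) are written there
#' @return a list of class `synthetic_cohort`; see the vignette for the
#'   component inventory
#' @export
simulate_cohort <- function(config, dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)

  ped <- .sim_samples(cfg)
  features <- .sim_features(cfg)
  ref_seqs <- lapply(cfg$chrom_lengths, function(L) .random_dna(L))
  loci <- .sim_loci(cfg)
  sim_all <- .sim_alleles(cfg, loci)
  alleles <- sim_all$alleles

  ## choose the causal locus: a deletion in an OMIM-gene exon on chr1
  causal <- NULL
  if (isTRUE(cfg$causal$enabled)) {
    c1 <- which(loci$chrom == "chr1")
    pick <- c1[which.min(abs(loci$start[c1] - cfg$chrom_lengths[[1]] / 2))]
    loci$class[pick] <- "deletion"
    loci$end[pick] <- loci$start[pick] + cfg$causal$deletion_bp
    ai <- which(alleles$locus_id == loci$locus_id[pick])
    extra <- setdiff(ai, ai[1])
    if (length(extra)) alleles <- alleles[-extra, , drop = FALSE]
    ai <- which(alleles$locus_id == loci$locus_id[pick])
    alleles$class[ai] <- "deletion"; alleles$length_bp[ai] <- 0L
    alleles$partition[ai] <- "cohortA_only"; alleles$freq[ai] <- 0
    alleles$te[ai] <- "none"
    sim_all$seqs[[alleles$allele_id[ai]]] <- ""
    ## shift the nearest chr1 OMIM gene so its second exon overlaps the locus
    og <- which(features$genes$omim & features$genes$chrom == "chr1")
    gi <- og[which.min(abs(features$genes$start[og] - loci$start[pick]))]
    gid <- features$genes$gene_id[gi]
    ew <- cfg$gene_bp %/% cfg$n_exons_per_gene
    new_start <- loci$start[pick] - ew - 50L
    features$genes$start[gi] <- new_start
    features$genes$end[gi] <- new_start + cfg$gene_bp
    ei <- which(features$exons$gene_id == gid)
    features$exons$start[ei] <- new_start + (seq_along(ei) - 1L) * ew
    features$exons$end[ei] <- features$exons$start[ei] + cfg$exon_bp
    causal <- list(locus_id = loci$locus_id[pick],
                   allele_id = alleles$allele_id[ai],
                   gene = gid, exon_id = paste0(gid, "_E2"),
                   proband = "A003", mother = "A002", father = "A001")
  }
  ## one planted common exonic insertion (the "highly polymorphic exon" case)
  poly <- NULL
  ins_loci <- which(loci$class == "insertion")
  if (length(ins_loci)) {
    ex <- features$exons[features$exons$gene_id != (causal$gene %||% ""), ]
    pick <- ins_loci[which.min(vapply(ins_loci, function(r) {
      min(abs(ex$start[ex$chrom == loci$chrom[r]] - loci$start[r]))
    }, numeric(1)))]
    exc <- ex[ex$chrom == loci$chrom[pick], ]
    near <- exc[which.min(abs(exc$start - loci$start[pick])), ]
    loci$start[pick] <- as.integer(near$start + cfg$exon_bp %/% 2L)
    loci$end[pick] <- loci$start[pick]
    ai <- which(alleles$locus_id == loci$locus_id[pick])[1]
    alleles$partition[ai] <- "shared"
    alleles$freq[ai] <- cfg$polymorphic_exon_freq
    alleles$te[ai] <- "none"; alleles$te_planted_cov[ai] <- NA
    poly <- list(locus_id = loci$locus_id[pick], allele_id = alleles$allele_id[ai],
                 exon_id = near$exon_id)
  }

  carr <- .sim_carriage(cfg, loci, alleles, ped)
  ## plant the causal deletion: mother hap2 carries, proband inherits hap2
  if (!is.null(causal)) {
    li <- causal$locus_id
    carr[li, ] <- "ref"
    carr[li, paste0(causal$mother, ".h2")] <- causal$allele_id
    ci <- loci$chrom == loci$chrom[loci$locus_id == li]
    carr[ci, paste0(causal$proband, ".h2")] <-
      carr[ci, paste0(causal$mother, ".h2")]
  }

  hap_ids <- colnames(carr)
  hap_rank <- setNames(match(hap_ids, sort(hap_ids)), hap_ids)
  carriers <- lapply(setNames(alleles$allele_id, alleles$allele_id), function(a) {
    hap_ids[carr[alleles$locus_id[match(a, alleles$allele_id)], ] == a]
  })
  gsim <- .sim_graph(cfg, ref_seqs, loci, alleles, sim_all$seqs, carriers, hap_rank)

  alleles$n_carriers <- lengths(carriers)[alleles$allele_id]
  alleles$in_graph <- alleles$n_carriers > 0L
  alleles$allele_key <- vapply(seq_len(nrow(alleles)), function(i) {
    .allele_key_of(gsim$locus_nodes, alleles$locus_id[i], alleles$allele_id[i])
  }, character(1))
  loci$ref_allele_key <- vapply(loci$locus_id, function(l) {
    .allele_key_of(gsim$locus_nodes, l, "ref")
  }, character(1))
  loci$bubble_id <- sprintf("bub_%s_%d_%d", loci$chrom, loci$start, loci$end)
  ## a locus is an observed bubble only if some haplotype carries an alt path
  loci$observed <- loci$locus_id %in% alleles$locus_id[alleles$in_graph]

  ## truth incidence matrix over observed alleles (reference paths included)
  tm_rows <- list()
  for (r in which(loci$observed)) {
    lid <- loci$locus_id[r]
    ref_carr <- hap_ids[carr[lid, ] == "ref"]
    if (length(ref_carr)) {
      tm_rows[[paste0(lid, ".ref")]] <- list(
        bubble_id = loci$bubble_id[r], chrom = loci$chrom[r],
        start = loci$start[r], end = loci$end[r],
        allele_key = loci$ref_allele_key[r], is_reference = TRUE,
        allele_id = paste0(lid, ".ref"), carriers = ref_carr)
    }
    for (j in which(alleles$locus_id == lid & alleles$in_graph)) {
      tm_rows[[alleles$allele_id[j]]] <- list(
        bubble_id = loci$bubble_id[r], chrom = loci$chrom[r],
        start = loci$start[r], end = loci$end[r],
        allele_key = alleles$allele_key[j], is_reference = FALSE,
        allele_id = alleles$allele_id[j],
        carriers = carriers[[alleles$allele_id[j]]])
    }
  }
  tm_meta <- data.frame(
    allele_id = vapply(tm_rows, `[[`, "", "allele_id"),
    bubble_id = vapply(tm_rows, `[[`, "", "bubble_id"),
    allele_key = vapply(tm_rows, `[[`, "", "allele_key"),
    chrom = vapply(tm_rows, `[[`, "", "chrom"),
    start = vapply(tm_rows, function(x) x$start, numeric(1)),
    end = vapply(tm_rows, function(x) x$end, numeric(1)),
    is_reference = vapply(tm_rows, `[[`, TRUE, "is_reference"),
    stringsAsFactors = FALSE)
  ord <- order(tm_meta$chrom, tm_meta$start, tm_meta$allele_key)
  tm_meta <- tm_meta[ord, , drop = FALSE]; tm_rows <- tm_rows[ord]
  truth_matrix <- matrix(0L, nrow = nrow(tm_meta), ncol = length(hap_ids),
                         dimnames = list(paste(tm_meta$bubble_id, tm_meta$allele_key,
                                               sep = ":"), sort(hap_ids)))
  for (i in seq_along(tm_rows)) truth_matrix[i, tm_rows[[i]]$carriers] <- 1L

  ## per-haplotype call tracks with planted noise
  exempt_haps <- c(outer(if (!is.null(causal))
    c(causal$proband, causal$mother, causal$father) else character(),
    c(".h1", ".h2"), paste0))
  obs_r <- which(loci$observed)
  grid_h <- rep(hap_ids, each = length(obs_r))
  grid_r <- rep(obs_r, times = length(hap_ids))
  lid <- loci$locus_id[grid_r]
  is_exempt <- if (!is.null(causal)) {
    lid == causal$locus_id & grid_h %in% exempt_haps
  } else rep(FALSE, length(lid))
  keep <- is_exempt | runif(length(lid)) >= cfg$missing_rate
  grid_h <- grid_h[keep]; grid_r <- grid_r[keep]
  lid <- lid[keep]; is_exempt <- is_exempt[keep]
  n <- length(lid)
  a <- carr[cbind(grid_r, match(grid_h, colnames(carr)))]
  # the planted causal locus stays a clean biallelic deletion: no spurious
  # private alleles are fabricated there (the scenario models a rare variant
  # with unambiguous assembly support)
  spur_ok <- if (!is.null(causal)) lid != causal$locus_id else rep(TRUE, n)
  spurious <- !is_exempt & spur_ok & runif(n) < cfg$spurious_rate
  src <- vapply(gsim$locus_nodes[lid], `[[`, "", "src")
  snk <- vapply(gsim$locus_nodes[lid], `[[`, "", "snk")
  key <- ifelse(a == "ref", loci$ref_allele_key[grid_r],
                alleles$allele_key[match(a, alleles$allele_id)])
  key[spurious] <- paste0(src[spurious], "+x_", grid_h[spurious], "_",
                          lid[spurious], "+", snk[spurious])
  bad_labels <- c("error", "collapsed", "duplicated")
  invalid <- ifelse(spurious, runif(n) < cfg$spurious_invalid_prob,
                    !is_exempt & runif(n) < cfg$invalid_rate)
  validity <- rep("haploid", n)
  validity[invalid] <- sample(bad_labels, sum(invalid), replace = TRUE)
  calls <- data.frame(
    hap_id = grid_h, sample_id = sub("\\.h[12]$", "", grid_h),
    haplotype = as.integer(sub("^.*\\.h", "", grid_h)),
    bubble_id = loci$bubble_id[grid_r], allele_key = key,
    chrom = loci$chrom[grid_r], start = loci$start[grid_r],
    end = loci$end[grid_r],
    support_contig = paste0(grid_h, "_", loci$chrom[grid_r]),
    support_start = pmax(0L, loci$start[grid_r] - 20L),
    support_end = loci$end[grid_r] + 20L,
    validity = validity, spurious = spurious,
    is_ref_allele = !spurious & a == "ref",
    stringsAsFactors = FALSE)

  ## validity tracks: invalid support intervals + haploid complement
  validity_tracks <- list()
  for (h in hap_ids) {
    for (chrom in names(cfg$chrom_lengths)) {
      ctg <- paste0(h, "_", chrom)
      cc <- calls[calls$support_contig == ctg, , drop = FALSE]
      bad <- cc[cc$validity != "haploid", , drop = FALSE]
      L <- cfg$chrom_lengths[[chrom]] + 50L
      segs <- if (nrow(bad)) {
        data.frame(contig = ctg, start = bad$support_start,
                   end = bad$support_end, label = bad$validity,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(contig = character(), start = integer(), end = integer(),
                   label = character(), stringsAsFactors = FALSE)
      }
      gaps <- IRanges::setdiff(.ir(0L, L),
                               if (nrow(bad)) .ir(bad$support_start, bad$support_end)
                               else IRanges::IRanges())
      hapl <- data.frame(contig = ctg, start = IRanges::start(gaps) - 1L,
                         end = IRanges::end(gaps), label = "haploid",
                         stringsAsFactors = FALSE)
      validity_tracks[[ctg]] <- rbind(hapl, segs)
    }
  }
  validity_tracks <- do.call(rbind, validity_tracks)
  rownames(validity_tracks) <- NULL

  ## reference-based caller emulations
  seq_samples <- ped$sample_id[ped$sequenced]
  exempt <- if (!is.null(causal)) {
    list(locus_id = causal$locus_id,
         samples = c(causal$proband, causal$mother, causal$father))
  } else NULL
  refc <- .emulate_caller(cfg, cfg$ref_caller, loci, alleles, carr,
                          seq_samples, "rc", exempt, length(hap_ids))
  thirdc <- .emulate_caller(cfg, cfg$third_caller, loci, alleles, carr,
                            seq_samples, "tc", exempt, length(hap_ids))

  ## CMA intervals for trio probands; sequencing depth per sample
  coverage <- setNames(round(runif(length(seq_samples), 15, 40)), seq_samples)
  probands <- ped$sample_id[ped$role == "proband"]
  coverage[probands] <- pmax(coverage[probands], 21)
  cma <- list()
  for (s in probands) {
    own <- which(vapply(seq_len(nrow(loci)), function(r) {
      lc <- loci[r, ]
      if (lc$class != "deletion") return(FALSE)
      aid <- alleles$allele_id[alleles$locus_id == lc$locus_id][1]
      any(carr[lc$locus_id, paste0(s, c(".h1", ".h2"))] == aid)
    }, logical(1)))
    own <- head(own, 5L)
    if (!length(own)) next
    hit <- data.frame(sample_id = s, chrom = loci$chrom[own],
                      start = pmax(0L, loci$start[own] - 500L),
                      end = loci$end[own] + 500L, truth_overlap = TRUE,
                      stringsAsFactors = FALSE)
    miss <- data.frame(sample_id = s, chrom = "chr1",
                       start = c(1000L, 3000L), end = c(1400L, 3400L),
                       truth_overlap = FALSE, stringsAsFactors = FALSE)
    cma[[s]] <- rbind(hit, miss)
  }
  cma <- if (length(cma)) do.call(rbind, cma) else NULL
  if (!is.null(cma)) rownames(cma) <- NULL

  ## repeat hits on graph nodes (TE insertions, decoys, TR simple repeats)
  rh <- list()
  for (j in which(alleles$te != "none" & alleles$in_graph)) {
    aid <- alleles$allele_id[j]
    node <- gsim$locus_nodes[[alleles$locus_id[j]]]$alt_nodes[[aid]]
    len <- alleles$length_bp[j]
    covlen <- round(alleles$te_planted_cov[j] * len)
    s0 <- (len - covlen) %/% 2L
    rh[[aid]] <- data.frame(target = node, start = s0, end = s0 + covlen,
                            family = ifelse(alleles$te[j] == "SINE", "AluY", "L1HS"),
                            class = alleles$te[j], allele_id = aid,
                            stringsAsFactors = FALSE)
  }
  for (j in which(alleles$class == "tr" & alleles$in_graph)) {
    aid <- alleles$allele_id[j]
    node <- gsim$locus_nodes[[alleles$locus_id[j]]]$alt_nodes[[aid]]
    rh[[aid]] <- data.frame(target = node, start = 0L, end = alleles$length_bp[j],
                            family = "(TA)n", class = "simple", allele_id = aid,
                            stringsAsFactors = FALSE)
  }
  repeat_hits <- if (length(rh)) do.call(rbind, rh) else
    data.frame(target = character(), start = integer(), end = integer(),
               family = character(), class = character(), allele_id = character())
  rownames(repeat_hits) <- NULL

  ## phenotype ontology and patient terms
  onto <- .sim_ontology(cfg, features, causal, ped)

  haplotypes <- data.frame(hap_id = hap_ids,
                           sample_id = sub("\\.h[12]$", "", hap_ids),
                           haplotype = as.integer(sub("^.*\\.h", "", hap_ids)),
                           stringsAsFactors = FALSE)
  haplotypes$cohort <- ped$cohort[match(haplotypes$sample_id, ped$sample_id)]
  haplotypes$rank <- unname(hap_rank[haplotypes$hap_id])

  cohort <- structure(list(
    config = cfg, ped = ped, haplotypes = haplotypes,
    cohorts = setNames(ped$cohort[ped$sequenced], ped$sample_id[ped$sequenced]),
    reference = ref_seqs, graph = gsim$graph, locus_nodes = gsim$locus_nodes,
    loci = loci, alleles = alleles, allele_seqs = sim_all$seqs,
    carriage = carr, carriers = carriers,
    truth_matrix = truth_matrix, truth_meta = tm_meta,
    calls = calls, validity_tracks = validity_tracks,
    ref_calls = refc$calls, ref_fn = refc$fn_events,
    third_calls = thirdc$calls, third_fn = thirdc$fn_events,
    cma = cma, coverage = coverage,
    features = features, repeat_hits = repeat_hits,
    ontology_edges = onto$edges, gene_annotations = onto$annotations,
    patient_terms = onto$patient_terms,
    causal = causal, polymorphic = poly,
    reference_gaps = data.frame(chrom = names(cfg$chrom_lengths),
                                start = unname(cfg$chrom_lengths) - 5000L,
                                end = unname(cfg$chrom_lengths) - 4800L)),
    class = "synthetic_cohort")
  if (!is.null(dir)) cohort$paths <- write_cohort(cohort, dir)
  cohort
}

.sim_ontology <- function(cfg, features, causal, ped) {
  branches <- list(
    neuro = c("HP:0001250", "HP:0001263", "HP:0000252", "HP:0001252"),
    growth = c("HP:0001507", "HP:0004322", "HP:0000098"),
    immune = c("HP:0002715", "HP:0004313"),
    cardio = c("HP:0001626", "HP:0001629"))
  branch_ids <- c(neuro = "HP:0012638", growth = "HP:0001519",
                  immune = "HP:0010978", cardio = "HP:0030680")
  edges <- rbind(
    data.frame(term = "HP:0000118", parent = "HP:0000001"),
    data.frame(term = unname(branch_ids), parent = "HP:0000118"),
    do.call(rbind, lapply(names(branches), function(b) {
      data.frame(term = branches[[b]], parent = branch_ids[[b]])
    })))
  causal_terms <- c("HP:0001263", "HP:0001252")   # dev delay + hypotonia-like
  genes <- features$genes$gene_id
  pool <- setdiff(unlist(branches), causal_terms)
  ann <- do.call(rbind, lapply(genes, function(g) {
    if (!is.null(causal) && g == causal$gene) {
      data.frame(gene = g, term = causal_terms, stringsAsFactors = FALSE)
    } else {
      data.frame(gene = g, term = sample(pool, sample(1:3, 1L)),
                 stringsAsFactors = FALSE)
    }
  }))
  pts <- lapply(setNames(ped$sample_id[ped$sequenced], ped$sample_id[ped$sequenced]),
                function(s) sample(pool, sample(2:3, 1L)))
  if (!is.null(causal)) {
    pts[[causal$proband]] <- c(causal_terms, sample(pool, 1L))
  }
  list(edges = edges, annotations = ann, patient_terms = pts)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort (seed", x$config$seed, "):",
      nrow(x$loci), "loci,", sum(x$alleles$in_graph), "observed alt alleles,",
      nrow(x$haplotypes), "haplotypes (",
      paste(sprintf("%s=%d", names(table(x$haplotypes$cohort)),
                    table(x$haplotypes$cohort)), collapse = ", "), ")\n")
  if (!is.null(x$causal)) {
    cat("  causal deletion:", x$causal$allele_id, "in", x$causal$gene,
        "exon 2, proband", x$causal$proband, "\n")
  }
  invisible(x)
}
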