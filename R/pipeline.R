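#' Genotype a synthetic cohort into a genotype matrix
#'
#' Convenience pipeline step: takes the cohort's per-haplotype calls (with
#' their validity labels) and builds the binary allele-by-haplotype matrix.
#' With `use_truth_validity = FALSE` the labels are recomputed from the
#' emitted validity tracks via [apply_validity()] (slower but exercises the
#' full path; the two routes agree by construction of the tracks).
#'
#' @param cohort a `synthetic_cohort`
#' @param keep_only_valid passed to [build_matrix()]
#' @param use_truth_validity use the generator's validity labels directly
#' @return a `genotype_matrix`
#' @export
cohort_matrix <- function(cohort, keep_only_valid = TRUE,
                          use_truth_validity = TRUE) {
  calls <- cohort$calls
  if (!use_truth_validity) {
    calls$validity <- "unknown"
    calls <- apply_validity(calls, cohort$validity_tracks)
  }
  bubbles <- data.frame(bubble_id = cohort$loci$bubble_id,
                        chrom = cohort$loci$chrom, start = cohort$loci$start,
                        end = cohort$loci$end,
                        ref_allele_key = cohort$loci$ref_allele_key,
                        stringsAsFactors = FALSE)
  build_matrix(calls, cohort$cohorts, keep_only_valid = keep_only_valid,
               bubbles = bubbles)
}

#' Per-sample backbone intervals of carried non-reference alleles
#'
#' @param gm a `genotype_matrix`
#' @return data.frame `sample_id`, `chrom`, `start`, `end` (one row per
#'   carried non-reference allele locus)
#' @export
sample_sv_intervals <- function(gm) {
  nonref <- which(!gm$alleles$is_reference)
  out <- list()
  for (r in nonref) {
    haps <- colnames(gm$geno)[gm$geno[r, ] > 0L]
    if (!length(haps)) next
    samp <- unique(gm$samples$sample_id[match(haps, gm$samples$hap_id)])
    out[[length(out) + 1L]] <- data.frame(
      sample_id = samp, chrom = gm$alleles$chrom[r],
      start = gm$alleles$start[r],
      end = max(gm$alleles$end[r], gm$alleles$start[r] + 1L),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Assemble rare cohort-private exonic candidate SVs
#'
#' Implements the candidate definition used for phenotype-driven
#' prioritization: alleles private to cohort A, whose bubble was replicated
#' by the reference-based caller for the carrier sample (consensus
#' concordance), and whose backbone locus overlaps an exon.  One candidate
#' row per (allele, carrier sample, overlapped exon's gene), preferring the
#' OMIM exon when several exons are hit.
#'
#' @param gm a `genotype_matrix`
#' @param records allele-frequency records from [partition_and_spectrum()]
#' @param consensus a `consensus_sets` object built from this cohort
#' @param features feature list (`genes`, `exons`)
#' @param cohort_label cohort whose private alleles are candidates
#' @param maf_cutoff rare cutoff on allele frequency (default 0.05)
#' @return candidate data.frame for [rank_candidates()]
#' @export
rare_exonic_candidates <- function(gm, records, consensus, features,
                                   cohort_label = "cohortA", maf_cutoff = 0.05) {
  priv <- records[records$partition == paste0(cohort_label, "_only") &
                    records$frequency < maf_cutoff, , drop = FALSE]
  if (!nrow(priv)) return(data.frame())
  iv <- data.frame(row_id = priv$row_id, chrom = priv$chrom,
                   start = priv$start,
                   end = pmax(priv$end, priv$start + 1L),
                   stringsAsFactors = FALSE)
  ov <- overlap_features(iv, features)
  exonic <- lengths(ov$exons) > 0L
  matched_graph <- unique(consensus$matches$pairs$graph_id)
  out <- list()
  for (i in which(exonic)) {
    r <- priv[i, ]
    haps <- colnames(gm$geno)[gm$geno[match(r$row_id, gm$alleles$row_id), ] > 0L]
    samps <- unique(gm$samples$sample_id[match(haps, gm$samples$hap_id)])
    ex <- ov$omim_exons[[i]]
    if (!length(ex)) ex <- ov$exons[[i]]
    exon_id <- ex[1]
    gene <- features$exons$gene_id[match(exon_id, features$exons$exon_id)]
    for (s in samps) {
      gid <- paste0(r$bubble_id, "@", s)
      if (!gid %in% matched_graph) next   # not replicated by the reference caller
      out[[length(out) + 1L]] <- data.frame(
        candidate_id = paste0(r$row_id, "@", s),
        sample_id = s, gene = gene, exon_id = exon_id,
        frequency = r$frequency, chrom = r$chrom, start = r$start,
        bubble_id = r$bubble_id, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plant Mendelian-violation errors into a cohort's reference callset
#'
#' Adds `n_fp` spurious proband-only calls (at positions away from any real
#' locus, hence impossible given the parents) and plants `n_fn` detectable
#' false negatives: for a locus the proband carries, one parent's genotype
#' is raised to homozygous and the proband's record is deleted, so the
#' proband's observed copy number falls below the Mendelian minimum.  The
#' planted labels are recorded in `$mendelian_spike`.
#'
#' @param cohort a `synthetic_cohort` with at least one trio
#' @param n_fp,n_fn numbers of planted false positives / false negatives
#' @param seed integer seed
#' @return the modified cohort
#' @export
spike_mendelian_violations <- function(cohort, n_fp, n_fn, seed = 1L) {
  trio_fams <- unique(cohort$ped$family_id[cohort$ped$type == "trio"])
  if (!length(trio_fams)) stop("cohort has no trio")
  fam <- cohort$ped[cohort$ped$family_id == trio_fams[1], ]
  proband <- fam$sample_id[fam$role == "proband"]
  father <- fam$sample_id[fam$role == "father"]
  mother <- fam$sample_id[fam$role == "mother"]
  set.seed(seed)
  rc <- cohort$ref_calls
  spike <- list()

  ## planted false negatives: make father homozygous, drop the proband call
  pro_tp <- which(rc$sample_id == proband & rc$truth == "TP")
  usable <- pro_tp[!is.na(rc$locus_id[pro_tp])]
  if (length(usable) < n_fn) {
    stop("insufficient inherited calls to drop: have ", length(usable),
         ", need ", n_fn)
  }
  drop_idx <- if (n_fn > 0L) sample(usable, n_fn) else integer()
  for (i in drop_idx) {
    lid <- rc$locus_id[i]
    fi <- which(rc$sample_id == father & rc$locus_id == lid)
    if (length(fi)) {
      rc$cn[fi[1]] <- 2L
    } else {
      newrow <- rc[i, ]
      newrow$sample_id <- father
      newrow$cn <- 2L
      newrow$call_id <- paste0(newrow$call_id, "f")
      rc <- rbind(rc, newrow)
    }
    spike[[length(spike) + 1L]] <- data.frame(type = "false_negative",
                                              locus_id = lid,
                                              pos = rc$pos[i],
                                              stringsAsFactors = FALSE)
  }
  if (length(drop_idx)) rc <- rc[-drop_idx, , drop = FALSE]

  ## planted false positives: proband-only calls in empty regions
  for (j in seq_len(n_fp)) {
    repeat {
      chrom <- sample(names(cohort$config$chrom_lengths), 1L)
      pos <- sample.int(cohort$config$chrom_lengths[[chrom]] - 20000L, 1L) + 5000L
      d1 <- abs(cohort$loci$start[cohort$loci$chrom == chrom] - pos)
      d2 <- abs(rc$pos[rc$chrom == chrom] - pos)
      if (all(d1 > 5000L) && all(d2 > 5000L)) break
    }
    svlen <- -sample(200:800, 1L)
    rc <- rbind(rc, data.frame(call_id = sprintf("mvfp%03d", j),
                               sample_id = proband, chrom = chrom, pos = pos,
                               start = pos - 1L, end = pos - svlen,
                               svtype = "DEL", svlen = svlen, cn = 1L,
                               maf = 0.01, truth = "FP",
                               locus_id = NA_character_,
                               stringsAsFactors = FALSE))
    spike[[length(spike) + 1L]] <- data.frame(type = "false_positive",
                                              locus_id = NA_character_,
                                              pos = pos, stringsAsFactors = FALSE)
  }
  cohort$ref_calls <- rc[order(rc$chrom, rc$pos, rc$sample_id), , drop = FALSE]
  cohort$mendelian_spike <- if (length(spike)) do.call(rbind, spike) else
    data.frame(type = character(), locus_id = character(), pos = integer())
  cohort$spike_trio <- c(proband = proband, father = father, mother = mother)
  cohort
}
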