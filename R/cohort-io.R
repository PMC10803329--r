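#' Write all synthetic cohort files to a directory
#'
#' Emits the cohort in the standard interchange formats: reference FASTA,
#' rGFA graph, per-haplotype call tracks (BED-like TSV), per-assembly
#' validity BEDs, two SV VCFs, reference-gap BED, CMA BED, 6-column PED,
#' GFF3 gene models plus an OMIM gene list, a RepeatMasker-style .out
#' table, ontology/annotation/phenotype TSVs, and the truth set as JSON.
#'
#' @param cohort a `synthetic_cohort`
#' @param dir output directory (created if needed)
#' @return named list of the written paths
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "calls"), showWarnings = FALSE)
  dir.create(file.path(dir, "validity"), showWarnings = FALSE)
  p <- list()

  p$reference <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(cohort$reference)), p$reference)

  p$graph <- file.path(dir, "graph.gfa")
  write_rgfa(cohort$graph, p$graph)

  p$calls <- character()
  for (h in unique(cohort$calls$hap_id)) {
    f <- file.path(dir, "calls", paste0(h, ".bed"))
    write_call_track(cohort$calls[cohort$calls$hap_id == h, ], cohort$loci, f)
    p$calls[h] <- f
  }

  p$validity <- character()
  vt <- cohort$validity_tracks
  for (h in unique(cohort$haplotypes$hap_id)) {
    f <- file.path(dir, "validity", paste0(h, ".bed"))
    sel <- startsWith(vt$contig, paste0(h, "_"))
    write.table(vt[sel, c("contig", "start", "end", "label")], f, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    p$validity[h] <- f
  }

  p$ref_vcf <- file.path(dir, "ref_calls.vcf")
  write_sv_vcf(cohort$ref_calls, names(cohort$cohorts),
               cohort$config$chrom_lengths, p$ref_vcf)
  p$third_vcf <- file.path(dir, "third_calls.vcf")
  write_sv_vcf(cohort$third_calls, names(cohort$cohorts),
               cohort$config$chrom_lengths, p$third_vcf)

  p$gaps <- file.path(dir, "reference_gaps.bed")
  write.table(cohort$reference_gaps, p$gaps, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(cohort$cma)) {
    p$cma <- file.path(dir, "cma.bed")
    write.table(cohort$cma[, c("chrom", "start", "end", "sample_id")], p$cma,
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }

  p$ped <- file.path(dir, "pedigree.ped")
  pedA <- cohort$ped[cohort$ped$cohort == "cohortA", , drop = FALSE]
  write.table(data.frame(pedA$family_id, pedA$sample_id, pedA$father_id,
                         pedA$mother_id, 0L, ifelse(pedA$role == "proband", 2L, 1L)),
              p$ped, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)

  p$gff3 <- file.path(dir, "genes.gff3")
  write_features_gff3(cohort$features, p$gff3)
  p$omim <- file.path(dir, "omim_genes.txt")
  writeLines(cohort$features$omim, p$omim)

  p$repeats <- file.path(dir, "repeats.out")
  write_repeatmasker_out(cohort$repeat_hits, p$repeats)

  p$ontology <- file.path(dir, "ontology.tsv")
  write.table(cohort$ontology_edges, p$ontology, sep = "\t", quote = FALSE,
              row.names = FALSE)
  p$annotations <- file.path(dir, "gene_annotations.tsv")
  write.table(cohort$gene_annotations, p$annotations, sep = "\t", quote = FALSE,
              row.names = FALSE)
  p$phenotypes <- file.path(dir, "phenotypes.tsv")
  ph <- data.frame(sample_id = rep(names(cohort$patient_terms),
                                   lengths(cohort$patient_terms)),
                   term = unlist(cohort$patient_terms, use.names = FALSE))
  write.table(ph, p$phenotypes, sep = "\t", quote = FALSE, row.names = FALSE)

  p$truth <- file.path(dir, "truth.json")
  truth <- list(seed = cohort$config$seed,
                loci = cohort$loci,
                alleles = cohort$alleles,
                causal = cohort$causal,
                polymorphic = cohort$polymorphic,
                coverage = as.list(cohort$coverage))
  jsonlite::write_json(truth, p$truth, auto_unbox = TRUE, digits = NA,
                       na = "null")
  p
}

#' Write a per-haplotype call track in the package's BED-like dialect
#'
#' @param calls call rows for one haplotype (generator truth shape)
#' @param loci cohort locus table (for reference-allele detection)
#' @param path output path
#' @export
write_call_track <- function(calls, loci, path) {
  ref_key <- loci$ref_allele_key[match(calls$bubble_id, loci$bubble_id)]
  pathstr <- ifelse(calls$allele_key == ref_key, ".",
                    paste0(">", gsub("+", ">", calls$allele_key, fixed = TRUE)))
  df <- data.frame(calls$chrom, calls$start, calls$end, pathstr,
                   sprintf("%s:%d-%d", calls$support_contig,
                           calls$support_start, calls$support_end))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write SV calls as a multi-sample VCF 4.2
#'
#' One record per (event, carrier sample); INFO carries SVTYPE, SVLEN, END
#' and the cohort MAF; FORMAT is GT only.
#'
#' @param calls call table (`call_id`, `sample_id`, `chrom`, `pos`, `end`,
#'   `svtype`, `svlen`, `cn`, `maf`)
#' @param samples all sample ids (VCF columns)
#' @param contigs named vector of contig lengths
#' @param path output path
#' @export
write_sv_vcf <- function(calls, samples, contigs, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   as.integer(contigs)),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Cohort minor allele frequency\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(calls)), function(i) {
    gt <- rep("./.", length(samples))
    gt[samples == calls$sample_id[i]] <- if (calls$cn[i] >= 2L) "1/1" else "0/1"
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d;MAF=%.6g", calls$svtype[i],
                    as.integer(calls$svlen[i]), as.integer(calls$end[i]),
                    calls$maf[i])
    paste(c(calls$chrom[i], calls$pos[i], calls$call_id[i], "N",
            paste0("<", calls$svtype[i], ">"), ".", "PASS", info, "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write gene models as GFF3
#' @param features feature list (`genes`, `exons`)
#' @param path output path
#' @export
write_features_gff3 <- function(features, path) {
  g <- features$genes; e <- features$exons
  lines <- c("##gff-version 3",
             sprintf("%s\tpansv\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     g$chrom, g$start + 1L, g$end, g$gene_id),
             sprintf("%s\tpansv\texon\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
                     e$chrom, e$start + 1L, e$end, e$exon_id, e$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Write repeat hits in the RepeatMasker .out dialect
#' @param hits data.frame `target`, `start`, `end`, `family`, `class`
#' @param path output path
#' @export
write_repeatmasker_out <- function(hits, path) {
  cls <- c(SINE = "SINE/Alu", LINE = "LINE/L1", simple = "Simple_repeat",
           satellite = "Satellite", LTR = "LTR/ERV", DNA = "DNA/hAT",
           other = "Unknown")
  hdr <- c("   SW  perc perc perc  query    position in query     matching repeat",
           "score  div. del. ins.  sequence begin end (left)      repeat class/family begin end (left) ID",
           "")
  body <- sprintf("%5d %5.1f %4.1f %4.1f  %s %d %d (0) + %s %s 1 %d (0) %d",
                  1000L, 5.0, 0.5, 0.5, hits$target, hits$start + 1L, hits$end,
                  hits$family, unname(cls[hits$class]), hits$end - hits$start,
                  seq_len(nrow(hits)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a 4-column validity BED (contig, start, end, label)
#' @param path file path
#' @export
read_validity_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("contig", "start", "end", "label")
  df
}

#' Read a 3+-column BED of intervals
#' @param path file path
#' @param sample_col optional 4th-column name (e.g. `"sample_id"`)
#' @export
read_bed <- function(path, sample_col = NULL) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(sample_col) && ncol(df) >= 4L) names(df)[4] <- sample_col
  df
}

#' Read a patient phenotype TSV (sample_id, term)
#' @param path file path
#' @return named list mapping sample id to its term vector
#' @export
read_phenotypes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  split(df$term, df$sample_id)
}
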