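make_bubbles <- function() {
  data.frame(bubble_id = c("bubA", "bubB"), chrom = "chr1",
             start = c(100L, 500L), end = c(100L, 700L),
             ref_allele_key = c("s1+s2", "s2+r1+s3"),
             stringsAsFactors = FALSE)
}

test_that("ingest_calls maps path tokens, reference dots and support intervals", {
  bub <- make_bubbles()
  lines <- c("chr1\t100\t100\t>s1>x>s2\tS1.h1_chr1:80-120",
             "chr1\t500\t700\t.\tS1.h1_chr1:480-720")
  calls <- ingest_calls(lines, "S1", 1L, bub)
  expect_equal(calls$allele_key, c("s1+x+s2", "s2+r1+s3"))
  expect_equal(calls$bubble_id, c("bubA", "bubB"))
  expect_equal(calls$hap_id, rep("S1.h1", 2))
  expect_equal(calls$support_start, c(80L, 480L))
  expect_error(ingest_calls("chr1\t100\t100\tgarbage\tc:1-2", "S1", 1, bub),
               "line 1")
  expect_error(ingest_calls("chr1\t1\t2\t.\tc:1-2", "S1", 1, bub),
               "does not correspond")
})

test_that("generator call tracks round-trip through ingest_calls to the truth", {
  co <- fixture_cohort("small_noiseless")
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  h <- co$haplotypes$hap_id[1]
  bub <- data.frame(bubble_id = co$loci$bubble_id, chrom = co$loci$chrom,
                    start = co$loci$start, end = co$loci$end,
                    ref_allele_key = co$loci$ref_allele_key,
                    stringsAsFactors = FALSE)
  got <- ingest_calls(file.path(dir, "calls", paste0(h, ".bed")),
                      sub("\\.h[12]$", "", h), 1L, bub)
  want <- co$calls[co$calls$hap_id == h, ]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$allele_key, want$allele_key)
  expect_equal(got$bubble_id, want$bubble_id)
})

test_that("apply_validity uses within-haploid and worst-overlap rules", {
  track <- data.frame(contig = "c1",
                      start = c(0L, 1000L, 2000L),
                      end = c(1000L, 2000L, 3000L),
                      label = c("haploid", "collapsed", "haploid"),
                      stringsAsFactors = FALSE)
  calls <- data.frame(hap_id = "S1.h1", sample_id = "S1", haplotype = 1L,
                      bubble_id = c("b1", "b2", "b3"), allele_key = "k",
                      chrom = "chr1", start = 1L, end = 2L,
                      support_contig = "c1",
                      support_start = c(100L, 900L, 1500L),
                      support_end = c(200L, 1100L, 1600L),
                      validity = "unknown", stringsAsFactors = FALSE)
  out <- apply_validity(calls, track)
  expect_equal(out$validity, c("haploid", "collapsed", "collapsed"))
  # worst-label precedence: error beats collapsed
  track2 <- rbind(track, data.frame(contig = "c1", start = 900L, end = 950L,
                                    label = "error"))
  out2 <- apply_validity(calls, track2)
  expect_equal(out2$validity[2], "error")
  expect_warning(
    apply_validity(transform(calls, support_contig = "absent"), track),
    "absent")
})

test_that("generator validity tracks reproduce the planted labels exactly", {
  co <- fixture_cohort("default")
  calls <- co$calls
  calls$validity <- "unknown"
  out <- apply_validity(calls, co$validity_tracks)
  expect_equal(out$validity, co$calls$validity)
  # planted invalid fraction is recovered on non-spurious calls
  q <- mean(out$validity[!out$spurious] != "haploid")
  expect_lt(abs(q - co$config$invalid_rate), 0.01)
})

test_that("build_matrix produces the binary matrix with per-bubble exclusivity", {
  bub <- make_bubbles()
  calls <- rbind(
    data.frame(hap_id = "S1.h1", sample_id = "S1", haplotype = 1L,
               bubble_id = "bubA", allele_key = "s1+x+s2", chrom = "chr1",
               start = 100L, end = 100L, support_contig = "c", support_start = 1L,
               support_end = 2L, validity = "haploid"),
    data.frame(hap_id = "S2.h1", sample_id = "S2", haplotype = 1L,
               bubble_id = "bubA", allele_key = "s1+s2", chrom = "chr1",
               start = 100L, end = 100L, support_contig = "c", support_start = 1L,
               support_end = 2L, validity = "haploid"))
  gm <- build_matrix(calls, c(S1 = "cohortA", S2 = "cohortB"), bubbles = bub)
  expect_equal(dim(gm$geno), c(2L, 2L))
  expect_equal(sort(unname(colSums(gm$geno))), c(1L, 1L))
  expect_true(all(colSums(gm$geno) <= 1L))   # one allele per bubble per haplotype
  expect_equal(gm$alleles$is_reference, c("s1+s2", "s1+x+s2") ==
                 bub$ref_allele_key[1])
  # an invalid call is masked out and its private row disappears
  calls2 <- calls; calls2$validity[1] <- "error"
  gm2 <- build_matrix(calls2, c(S1 = "cohortA", S2 = "cohortB"), bubbles = bub)
  expect_equal(nrow(gm2$geno), 1L)
  expect_false(gm2$mask["bubA", "S1.h1"])
  # conflicting duplicate calls are an error
  calls3 <- rbind(calls, transform(calls[1, ], allele_key = "s1+y+s2"))
  expect_error(build_matrix(calls3, c(S1 = "cohortA", S2 = "cohortB")),
               "conflicting")
})

test_that("noiseless genotyping reproduces the planted truth incidence matrix", {
  co <- fixture_cohort("noiseless")
  gm <- cohort_matrix(co)
  expect_identical(dim(gm$geno), dim(co$truth_matrix))
  expect_identical(rownames(gm$geno), rownames(co$truth_matrix))
  expect_identical(colnames(gm$geno), colnames(co$truth_matrix))
  expect_true(all(gm$geno == co$truth_matrix))
})

test_that("partition and spectrum conserve counts and respect cohort privacy", {
  gm <- fixture_matrix("default")
  ps <- partition_and_spectrum(gm)
  s <- ps$summary
  expect_equal(s$shared + s$cohortA_only + s$cohortB_only, s$n_total)
  expect_equal(sum(ps$spectrum$n), s$n_total)
  expect_true(all(ps$records$frequency > 0 & ps$records$frequency <= 1))
  expect_true(all(ps$records$is_singleton == (ps$records$count == 1L)))
  # partition labels check out against carriage
  co <- fixture_cohort("default")
  recA <- ps$records[ps$records$partition == "cohortA_only", ]
  hapB <- gm$samples$hap_id[gm$samples$cohort == "cohortB"]
  expect_true(all(rowSums(gm$geno[recA$row_id, hapB, drop = FALSE]) == 0))
})

test_that("adding a haplotype never decreases allele counts (monotonicity)", {
  co <- fixture_cohort("small_noiseless")
  gm <- cohort_matrix(co)
  full <- partition_and_spectrum(gm)
  drop_hap <- colnames(gm$geno)[5]
  gm2 <- gm
  keep <- colnames(gm$geno) != drop_hap
  gm2$geno <- gm2$geno[, keep, drop = FALSE]
  gm2$mask <- gm2$mask[, keep, drop = FALSE]
  gm2$samples <- gm2$samples[gm2$samples$hap_id != drop_hap, ]
  red <- partition_and_spectrum(gm2)
  common <- intersect(red$records$row_id, full$records$row_id)
  expect_true(all(full$records$count[match(common, full$records$row_id)] >=
                    red$records$count[match(common, red$records$row_id)]))
})

test_that("frequency spectrum recovers the planted Beta draws within binomial CIs", {
  co <- simulate_cohort(cohort_config(
    seed = 505L, n_loci = 1000L, n_trios = 0L, n_sibpairs = 0L,
    n_twinpairs = 0L, n_singlesA = 70L, n_samplesB = 30L,
    causal = list(enabled = FALSE),
    missing_rate = 0, invalid_rate = 0, spurious_rate = 0))
  gm <- cohort_matrix(co)
  ps <- partition_and_spectrum(gm)
  rec <- ps$records
  truth <- co$alleles[match(sub("^.*:", "", rec$allele_key), co$alleles$allele_key), ]
  truth <- co$alleles[match(rec$allele_key, co$alleles$allele_key), ]
  ok <- !is.na(truth$freq) & truth$partition == "shared"
  n <- rec$n_data[ok]
  # planted carriage probability (rescaled when a locus saturates)
  p <- pmin(truth$freq[ok], 0.95)
  ci_lo <- qbinom(0.025, n, p); ci_hi <- qbinom(0.975, n, p)
  inside <- rec$count[ok] >= ci_lo & rec$count[ok] <= ci_hi
  expect_gt(mean(inside), 0.90)
})

test_that("per-haplotype and diploid SV counts follow the union bound", {
  co <- fixture_cohort("noiseless")
  gm <- cohort_matrix(co)
  cnt <- genotyped_sv_counts(gm)
  truth_nonref <- co$truth_matrix[!co$truth_meta$is_reference, , drop = FALSE]
  expect_equal(cnt$per_haplotype$n_sv,
               unname(colSums(truth_nonref))[match(cnt$per_haplotype$hap_id,
                                                   colnames(truth_nonref))])
  for (i in seq_len(5)) {
    s <- cnt$per_sample$sample_id[i]
    haps <- gm$samples$hap_id[gm$samples$sample_id == s]
    expect_lte(cnt$per_sample$n_sv[i],
               sum(cnt$per_haplotype$n_sv[cnt$per_haplotype$hap_id %in% haps]))
  }
})

test_that("singleton calls are rejected by validity filtering more than common ones", {
  co <- fixture_cohort("default")
  rb <- rejection_by_count(co$calls)
  sing <- rb[rb$class == "singleton", ]
  comm <- rb[rb$class == "common", ]
  expect_gt(sing$pct_rejected, comm$pct_rejected)
})
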