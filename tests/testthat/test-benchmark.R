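test_that("SV VCFs round-trip through the writer and vcfR-based reader", {
  co <- fixture_cohort("default")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(co$ref_calls, names(co$cohorts), co$config$chrom_lengths, path)
  got <- read_sv_vcf(path)
  want <- co$ref_calls
  i <- match(paste0(want$call_id, "@", want$sample_id), got$call_id)
  expect_false(anyNA(i))
  expect_equal(got$pos[i], want$pos)
  expect_equal(got$svtype[i], want$svtype)
  expect_equal(got$svlen[i], want$svlen)
  expect_equal(got$cn[i], want$cn)
  expect_equal(got$maf[i], want$maf, tolerance = 1e-5)
})

test_that("benchmark call derivation keeps biallelic bubbles and flags star deletions", {
  co <- fixture_cohort("noiseless")
  gm <- cohort_matrix(co)
  gc <- graph_calls_for_benchmark(gm)
  tab <- table(gm$alleles$bubble_id)
  expect_true(all(tab[unique(gc$bubble_id)] == 2L))
  # multi-allelic bubbles are excluded
  multi <- names(tab)[tab > 2L]
  expect_false(any(gc$bubble_id %in% multi))
  # the star flag marks exactly the calls whose ALT is the direct edge
  key_nodes <- function(b, s) {
    rows <- gm$alleles[gm$alleles$bubble_id == b, ]
    cols <- gm$samples$hap_id[gm$samples$cohort != "reference"]
    counts <- rowSums(gm$geno[rows$row_id, cols, drop = FALSE])
    alt <- if (counts[1] != counts[2]) which.min(counts) else
      which(!rows$is_reference)
    lengths(strsplit(rows$allele_key[alt], "+", fixed = TRUE))
  }
  for (k in sample(seq_len(nrow(gc)), 25L)) {
    expect_equal(gc$is_star_deletion[k],
                 key_nodes(gc$bubble_id[k]) == 2L)
  }
})

test_that("calls near reference gaps are excluded", {
  co <- fixture_cohort("noiseless")
  gm <- cohort_matrix(co)
  bub <- gm$alleles$bubble_id[1]
  rows <- gm$alleles[gm$alleles$bubble_id == bub, ]
  gaps <- data.frame(chrom = rows$chrom[1],
                     start = rows$end[1] + 50L, end = rows$end[1] + 60L)
  gc_all <- graph_calls_for_benchmark(gm)
  gc_gap <- graph_calls_for_benchmark(gm, reference_gaps = gaps)
  expect_true(bub %in% gc_all$bubble_id)
  expect_false(bub %in% gc_gap$bubble_id)
  # a gap farther than 100 bp does not exclude
  far <- data.frame(chrom = rows$chrom[1], start = rows$end[1] + 150L,
                    end = rows$end[1] + 160L)
  expect_true(bub %in% graph_calls_for_benchmark(gm, reference_gaps = far)$bubble_id)
})

test_that("breakpoint matching obeys the window boundary", {
  g <- data.frame(graph_id = "g1", bubble_id = "b", sample_id = "S",
                  chrom = "chr1", start = 1000L, end = 1100L, cn = 1L,
                  is_star_deletion = TRUE, maf = 0.1)
  mk_ref <- function(start) data.frame(call_id = "r1", sample_id = "S",
                                       chrom = "chr1", pos = start + 1L,
                                       start = start, end = start + 100L,
                                       svtype = "DEL", svlen = -100,
                                       cn = 1L, maf = 0.1)
  expect_equal(match_calls(g, mk_ref(1000L))$n_matched, 1L)   # identical
  expect_equal(match_calls(g, mk_ref(1200L))$n_matched, 1L)   # gap 100
  expect_equal(match_calls(g, mk_ref(1201L))$n_matched, 0L)   # gap 101
  # short and BND reference calls are ignored
  short <- mk_ref(1000L); short$svlen <- -50
  expect_equal(match_calls(g, short)$n_ref, 0L)
  bnd <- mk_ref(1000L); bnd$svtype <- "BND"
  expect_equal(match_calls(g, bnd)$n_ref, 0L)
})

test_that("matching equals the all-pairs oracle on random planted call sets", {
  set.seed(77)
  for (rep in 1:20) {
    n_g <- sample(5:60, 1); n_r <- sample(5:60, 1)
    g <- data.frame(graph_id = paste0("g", 1:n_g), bubble_id = "b",
                    sample_id = sample(c("S1", "S2"), n_g, TRUE),
                    chrom = sample(c("chr1", "chr2"), n_g, TRUE),
                    start = sample.int(20000L, n_g), cn = 1L,
                    is_star_deletion = FALSE, maf = 0.1)
    g$end <- g$start + sample(50:500, n_g, TRUE)
    r <- data.frame(call_id = paste0("r", 1:n_r),
                    sample_id = sample(c("S1", "S2"), n_r, TRUE),
                    chrom = sample(c("chr1", "chr2"), n_r, TRUE),
                    start = sample.int(20000L, n_r),
                    svtype = sample(c("DEL", "INS", "BND"), n_r, TRUE,
                                    prob = c(.45, .45, .1)),
                    svlen = sample(30:800, n_r) * sample(c(-1, 1), n_r, TRUE),
                    cn = 1L, maf = 0.1)
    r$pos <- r$start + 1L
    r$end <- r$start + abs(r$svlen)
    got <- match_calls(g, r)$pairs
    want <- oracle_match(g, r)
    expect_equal(nrow(got), nrow(want), info = paste("rep", rep))
    expect_setequal(paste(got$graph_id, got$ref_id),
                    paste(want$graph_id, want$ref_id))
    # invariance to input order
    got2 <- match_calls(g[sample.int(n_g), ], r[sample.int(n_r), ])$pairs
    expect_setequal(paste(got$graph_id, got$ref_id),
                    paste(got2$graph_id, got2$ref_id))
  }
})

test_that("recall/precision ratios and their undefined cases", {
  rp <- recall_precision(5, n_graph = 5, n_ref = 5)
  expect_equal(rp$R, 1); expect_equal(rp$P, 1)
  expect_true(is.na(recall_precision(0, n_graph = 3, n_ref = 0)$R))
  expect_true(is.na(recall_precision(0, n_graph = 0, n_ref = 3)$P))
})

test_that("noiseless generator gives R = P = 1 exactly", {
  co <- fixture_cohort("noiseless")
  gm <- cohort_matrix(co)
  gc <- graph_calls_for_benchmark(gm, reference_gaps = co$reference_gaps)
  m <- match_calls(gc, co$ref_calls)
  rp <- recall_precision(m)
  expect_equal(rp$R, 1)
  expect_equal(rp$P, 1)
})

test_that("planted FP and FN rates are recovered from the benchmark metrics", {
  co <- simulate_cohort(cohort_config(
    seed = 404L, missing_rate = 0, invalid_rate = 0, spurious_rate = 0,
    ref_caller = list(fp_rate = 0.06, fn_rate = 0.10, jitter_sd = 0)))
  gm <- cohort_matrix(co)
  gc <- graph_calls_for_benchmark(gm, reference_gaps = co$reference_gaps)
  m <- match_calls(gc, co$ref_calls)
  rp <- recall_precision(m)
  # the reference caller's misses lower the graph set's precision metric;
  # its spurious calls lower the recall metric (truth bookkeeping)
  n_tp <- sum(co$ref_calls$truth == "TP")
  n_fp <- sum(co$ref_calls$truth == "FP")
  n_fn <- nrow(co$ref_fn)
  expect_equal(m$n_matched, n_tp)
  expect_equal(rp$R, n_tp / (n_tp + n_fp))
  expect_equal(rp$P, n_tp / (n_tp + n_fn))
  expect_lt(abs((1 - rp$P) - 0.10), 0.03)
  expect_lt(abs((1 - rp$R) - 0.06 / 1.06), 0.03)
})

test_that("precision and recall degrade monotonically with breakpoint jitter", {
  rps <- lapply(c(0, 60, 300), function(j) {
    co <- simulate_cohort(cohort_config(
      seed = 550L, n_loci = 120L, missing_rate = 0, invalid_rate = 0,
      spurious_rate = 0,
      ref_caller = list(fp_rate = 0, fn_rate = 0, jitter_sd = j)))
    gm <- cohort_matrix(co)
    gc <- graph_calls_for_benchmark(gm, reference_gaps = co$reference_gaps)
    recall_precision(match_calls(gc, co$ref_calls))
  })
  expect_true(rps[[1]]$R >= rps[[2]]$R && rps[[2]]$R > rps[[3]]$R)
  expect_true(rps[[1]]$P >= rps[[2]]$P && rps[[2]]$P > rps[[3]]$P)
})

test_that("region-stratified averages only use regions with both callers", {
  co <- fixture_cohort("noiseless")
  gm <- cohort_matrix(co)
  gc <- graph_calls_for_benchmark(gm, reference_gaps = co$reference_gaps)
  m <- match_calls(gc, co$ref_calls)
  br <- benchmark_by_region(m, gc, co$ref_calls)
  expect_equal(br$mean_R, 1)
  expect_equal(br$mean_P, 1)
  both <- br$per_region$n_graph > 0 & br$per_region$n_ref > 0
  expect_true(all(!is.na(br$per_region$R[both])))
})

test_that("CMA recall reports per-sample overlap fractions over covered samples", {
  co <- fixture_cohort("default")
  skip_if(is.null(co$cma))
  gm <- cohort_matrix(co)
  sv <- sample_sv_intervals(gm)
  cr <- cma_recall(co$cma, sv, coverage = co$coverage, min_depth = 20)
  expect_true(all(cr$per_sample$fraction >= 0 & cr$per_sample$fraction <= 1))
  # planted truth: intervals marked truth_overlap were built around carried
  # deletions, the others around empty regions
  for (s in cr$per_sample$sample_id) {
    tr <- co$cma[co$cma$sample_id == s, ]
    expect_equal(cr$per_sample$n_intervals[cr$per_sample$sample_id == s],
                 nrow(tr))
  }
  # degenerate cases
  one <- data.frame(sample_id = "X", chrom = "chr1", start = 0L, end = 10L)
  svx <- data.frame(sample_id = "X", chrom = "chr1", start = 5L, end = 8L)
  expect_equal(cma_recall(one, svx)$per_sample$fraction, 1)
  expect_equal(cma_recall(one, svx[0, ])$per_sample$fraction, 0)
})
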