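test_that("allele classification follows bubble path topology", {
  ref_del <- c("s", "r1", "r2", "t")   # reference with interior
  expect_equal(classify_allele(c("s", "t"), ref_del), "deletion")
  expect_equal(classify_allele(c("s", "a", "t"), c("s", "t")), "insertion")
  expect_equal(classify_allele(c("s", "a", "t"), ref_del), "complex")
  expect_equal(classify_allele(ref_del, ref_del), "reference")
  expect_error(classify_allele(c("x", "a", "t"), ref_del), "source/sink")
})

test_that("generator allele classes are recovered from the graph topology", {
  co <- fixture_cohort("small_noiseless")
  b <- detect_bubbles(co$graph)
  obs <- co$alleles[co$alleles$in_graph, ]
  i <- match(co$loci$bubble_id[match(obs$locus_id, co$loci$locus_id)],
             b$bubble_id)
  got <- vapply(seq_len(nrow(obs)), function(k) {
    path <- strsplit(obs$allele_key[k], "+", fixed = TRUE)[[1]]
    classify_allele(path, b$ref_path[[i[k]]])
  }, character(1))
  want <- ifelse(obs$class %in% c("tr", "complex"), "complex", obs$class)
  expect_equal(got, want)
})

test_that("full-length TE calls need >80% merged coverage and the length window", {
  hits <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(start = m[, 1], end = m[, 2], class = "SINE")
  }
  expect_equal(full_length_te(300L, hits(0, 255)), "SINE")       # 85%
  expect_equal(full_length_te(300L, hits(0, 240)), "none")       # exactly 80%
  expect_equal(full_length_te(300L, hits(0, 150, 100, 255)), "SINE")  # merged
  expect_equal(full_length_te(450L, hits(0, 440)), "none")       # too long
  h <- hits(0, 5400); h$class <- "LINE"
  expect_equal(full_length_te(6000L, h), "LINE")                 # 90%
  expect_equal(full_length_te(4000L, h), "none")                 # below window
})

test_that("planted TE cassettes are recalled and decoys rejected", {
  co <- fixture_cohort("default")
  te <- co$alleles[co$alleles$te != "none" & co$alleles$in_graph, ]
  skip_if(nrow(te) == 0, "no TE insertions drawn in fixture")
  node_of <- function(i) {
    co$locus_nodes[[te$locus_id[i]]]$alt_nodes[[te$allele_id[i]]]
  }
  for (i in seq_len(nrow(te))) {
    hits <- co$repeat_hits[co$repeat_hits$target == node_of(i),
                           c("start", "end", "class")]
    got <- full_length_te(te$length_bp[i], hits)
    if (te$te_planted_cov[i] > 0.8 &&
        ((te$te[i] == "SINE" && te$length_bp[i] >= 250 && te$length_bp[i] <= 400) ||
         (te$te[i] == "LINE" && te$length_bp[i] >= 5000 && te$length_bp[i] <= 10000))) {
      expect_equal(got, te$te[i])
    } else {
      expect_equal(got, "none")
    }
  }
})

test_that("RepeatMasker .out round-trips through the writer and reader", {
  co <- fixture_cohort("default")
  path <- withr::local_tempfile(fileext = ".out")
  write_repeatmasker_out(co$repeat_hits, path)
  got <- read_repeatmasker_out(path)
  expect_equal(got$target, co$repeat_hits$target)
  expect_equal(got$start, co$repeat_hits$start)
  expect_equal(got$end, co$repeat_hits$end)
  expect_equal(got$class, co$repeat_hits$class)
})

test_that("projection anchors insertions at 1 bp and tallies unplaced bubbles", {
  bub <- data.frame(bubble_id = c("b1", "b2", "b3"),
                    chrom = c("chr1", "chr1", NA),
                    start = c(1000L, 1000L, NA), end = c(1001L, 1500L, NA))
  pr <- project_allele(bub)
  expect_equal(pr$intervals$end - pr$intervals$start, c(1L, 500L))
  expect_equal(pr$n_unplaced, 1L)
  ins <- data.frame(bubble_id = "b4", chrom = "chr1", start = 2000L, end = 2000L)
  expect_equal(project_allele(ins)$intervals$end, 2001L)
})

test_that("compartments are assigned by the most specific overlap", {
  features <- list(
    genes = data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                       start = c(1000L, 5000L), end = c(2000L, 6000L),
                       omim = c(TRUE, FALSE)),
    exons = data.frame(exon_id = c("G1_E1", "G2_E1"), gene_id = c("G1", "G2"),
                       chrom = "chr1", start = c(1100L, 5100L),
                       end = c(1200L, 5200L)))
  iv <- data.frame(id = paste0("a", 1:4), chrom = "chr1",
                   start = c(1150L, 5150L, 1500L, 3000L),
                   end = c(1160L, 5160L, 1510L, 3010L))
  ov <- overlap_features(iv, features)
  expect_equal(ov$compartment,
               c("omim_exonic", "exonic", "genic", "intergenic"))
  # partition property: every interval gets exactly one compartment
  expect_equal(sum(table(ov$compartment)), nrow(iv))
})

test_that("alleles-per-gene densities reproduce the published worked examples", {
  expect_equal(allele_gene_density(73982, 7644), 9.68)
  expect_equal(allele_gene_density(1383, 275), 5.03)
  expect_equal(allele_gene_density(51733, 6638), 7.79)
  expect_equal(allele_gene_density(978, 242), 4.04)
})

test_that("singleton fractions per compartment use one-decimal percentages", {
  records <- data.frame(bubble_id = c("b1", "b2", "b3"),
                        is_singleton = c(TRUE, TRUE, FALSE))
  comp <- data.frame(bubble_id = c("b1", "b2", "b3"),
                     compartment = "exonic")
  out <- singleton_fraction_by_compartment(records, comp)
  expect_equal(out$pct_singleton[out$compartment == "exonic"], 66.7)
  expect_true(is.na(out$pct_singleton[out$compartment == "genic"]))
})

test_that("uniform allele frequencies give equal singleton fractions across compartments", {
  set.seed(11)
  n <- 4000
  records <- data.frame(bubble_id = paste0("b", seq_len(n)),
                        is_singleton = runif(n) < 0.3)
  comp <- data.frame(bubble_id = records$bubble_id,
                     compartment = sample(c("intergenic", "genic", "exonic"),
                                          n, replace = TRUE))
  out <- singleton_fraction_by_compartment(records, comp)
  fr <- out$pct_singleton[out$compartment %in% c("intergenic", "genic", "exonic")]
  expect_lt(max(fr) - min(fr), 6)   # within sampling error of each other
})

test_that("novel-sequence accounting matches a per-base brute-force mask", {
  # threshold rules from the worked examples
  one <- function(len, rep, aln) {
    nodes <- data.frame(node_id = "n", length = len)
    rh <- if (is.null(rep)) data.frame(target = character(), start = integer(),
                                       end = integer()) else
      data.frame(target = "n", start = rep[1], end = rep[2])
    al <- if (is.null(aln)) data.frame(target = character(), start = integer(),
                                       end = integer()) else
      data.frame(target = "n", start = aln[1], end = aln[2])
    novel_sequence_accounting(nodes, rh, al)$per_node$novel_bp
  }
  expect_equal(one(200L, c(0L, 200L), NULL), 0L)            # fully masked
  expect_equal(one(200L, c(0L, 100L), c(90L, 195L)), 0L)    # 5 bp < 10 discarded
  expect_equal(one(200L, c(0L, 100L), NULL), 100L)
  # randomized equivalence with a per-base mask
  set.seed(99)
  for (i in 1:25) {
    len <- sample(120:1000, 1)
    nr <- sample(0:4, 1); na <- sample(0:4, 1)
    mk <- function(n) {
      if (n == 0) return(data.frame(target = character(), start = integer(),
                                    end = integer()))
      s <- sample(0:(len - 2L), n, replace = TRUE)
      data.frame(target = "n", start = s,
                 end = pmin(len, s + sample(5:300, n, replace = TRUE)))
    }
    rh <- mk(nr); al <- mk(na)
    got <- novel_sequence_accounting(data.frame(node_id = "n", length = len),
                                     rh, al)$per_node
    mask <- rep(FALSE, len)
    for (k in seq_len(nrow(rh))) mask[(rh$start[k] + 1):rh$end[k]] <- TRUE
    for (k in seq_len(nrow(al))) mask[(al$start[k] + 1):al$end[k]] <- TRUE
    runs <- rle(!mask)
    novel <- sum(runs$lengths[runs$values & runs$lengths >= 10])
    expect_equal(got$novel_bp, novel, info = paste("case", i))
  }
})

test_that("hotspot detection flags concentrated windows and not uniform ones", {
  expect_error(detect_hotspots(data.frame(), c(chr1 = 1e6), window_bp = 0),
               "positive")
  sizes <- c(chr1 = 1e6)
  # zero alleles: zero hotspots
  none <- detect_hotspots(data.frame(chrom = character(), start = integer(),
                                     end = integer()), sizes, window_bp = 5e4)
  expect_equal(sum(none$is_hotspot), 0L)
  # everything in one window: exactly one hotspot
  iv <- data.frame(chrom = "chr1", start = sample(1000:4000, 50, TRUE))
  iv$end <- iv$start + 10L
  hs <- detect_hotspots(iv, sizes, window_bp = 5e4)
  expect_equal(sum(hs$is_hotspot), 1L)
  expect_true(hs$is_hotspot[1])
  # uniform placement: about a decile of nonzero windows exceeds the cutoff
  set.seed(21)
  iv2 <- data.frame(chrom = "chr1", start = sample.int(1e6 - 100L, 3000))
  iv2$end <- iv2$start + 10L
  hs2 <- detect_hotspots(iv2, sizes, window_bp = 5e4, percentile = 90)
  expect_lte(sum(hs2$is_hotspot), ceiling(0.12 * nrow(hs2)))
})

test_that("GFF3 features and the OMIM list round-trip through the readers", {
  co <- fixture_cohort("small_noiseless")
  dir <- withr::local_tempdir()
  write_features_gff3(co$features, file.path(dir, "genes.gff3"))
  writeLines(co$features$omim, file.path(dir, "omim.txt"))
  om <- read_omim_list(file.path(dir, "omim.txt"))
  ft <- read_features_gff3(file.path(dir, "genes.gff3"), om)
  expect_equal(ft$genes$gene_id, co$features$genes$gene_id)
  expect_equal(ft$genes$start, co$features$genes$start)
  expect_equal(ft$genes$omim, co$features$genes$omim)
  expect_equal(ft$exons$exon_id, co$features$exons$exon_id)
  expect_equal(ft$exons$gene_id, co$features$exons$gene_id)
})
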