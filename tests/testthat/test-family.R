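mk_calls <- function(start, svlen, sample, svtype = "DEL", chrom = "chr1",
                     id = NULL) {
  n <- length(start)
  data.frame(call_id = id %||% sprintf("c%03d", seq_len(n)),
             sample_id = rep_len(sample, n), chrom = rep_len(chrom, n),
             svtype = rep_len(svtype, n), start = start,
             end = start + abs(svlen), svlen = svlen, cn = 1L,
             stringsAsFactors = FALSE)
}

test_that("PED parsing and sibling-pair extraction", {
  co <- fixture_cohort("small_noiseless")
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  ped <- read_ped(file.path(dir, "pedigree.ped"))
  expect_true(all(c("family_id", "sample_id", "father_id", "mother_id") %in%
                    names(ped)))
  sp <- sibling_pairs(ped)
  expect_true(all(sp$sample1 != sp$sample2))
  want <- sum(vapply(split(ped, paste(ped$father_id, ped$mother_id)),
                     function(d) if (d$father_id[1] == "0") 0L else
                       choose(nrow(d), 2L), numeric(1)))
  expect_equal(nrow(sp), as.integer(want))
})

test_that("reference-call merging follows the size and fractional-distance rules", {
  # identical calls in two samples merge
  calls <- mk_calls(c(1000L, 1000L), c(-500, -500), c("S1", "S2"))
  cl <- merge_ref_calls(calls)
  expect_equal(nrow(cl), 1L)
  expect_setequal(cl$samples[[1]], c("S1", "S2"))
  # 51 bp apart exceeds 10% of a 500 bp deletion: two clusters
  calls2 <- mk_calls(c(1000L, 1051L), c(-500, -500), c("S1", "S2"))
  expect_equal(nrow(merge_ref_calls(calls2)), 2L)
  # 49 bp apart is within tolerance
  calls3 <- mk_calls(c(1000L, 1049L), c(-500, -500), c("S1", "S2"))
  expect_equal(nrow(merge_ref_calls(calls3)), 1L)
  # sub-50 bp calls are discarded before merging
  calls4 <- mk_calls(c(1000L, 1000L), c(-40, -500), c("S1", "S2"))
  cl4 <- merge_ref_calls(calls4)
  expect_equal(sum(cl4$n_members), 1L)
  # different svtypes never merge
  calls5 <- mk_calls(c(1000L, 1000L), c(500, 500), c("S1", "S2"),
                     svtype = c("DEL", "INS"))
  expect_equal(nrow(merge_ref_calls(calls5)), 2L)
})

test_that("merging equals the transitive-closure oracle on random call sets", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(10:100, 1)
    calls <- data.frame(
      call_id = sprintf("c%03d", seq_len(n)),
      sample_id = sample(paste0("S", 1:4), n, TRUE),
      chrom = sample(c("chr1", "chr2"), n, TRUE),
      svtype = sample(c("DEL", "INS"), n, TRUE),
      start = sample.int(5000L, n, TRUE),
      svlen = sample(30:900, n, TRUE) * sample(c(-1, 1), n, TRUE),
      cn = 1L, stringsAsFactors = FALSE)
    calls$end <- calls$start + abs(calls$svlen)
    got <- merge_ref_calls(calls)
    got_sets <- unname(lapply(got$members, sort))
    got_sets <- got_sets[order(vapply(got_sets, `[`, "", 1L))]
    want <- oracle_merge(calls)
    expect_equal(length(got_sets), length(want), info = paste("rep", rep))
    expect_identical(got_sets, want)
  }
})

test_that("graph-call merging clusters all non-reference alleles of a bubble", {
  gm <- fixture_matrix("noiseless")
  cl <- merge_graph_calls(gm)
  nonref <- gm$alleles[!gm$alleles$is_reference, ]
  expect_equal(sort(cl$cluster_id), sort(unique(nonref$bubble_id)))
  tab <- table(nonref$bubble_id)
  expect_equal(cl$n_members, as.integer(tab[cl$cluster_id]))
})

test_that("allele sharing is a symmetric bounded ratio with NA when undefined", {
  clusters <- data.frame(cluster_id = c("m1", "m2", "m3"))
  clusters$samples <- list(c("S1", "S2"), "S1", "S3")
  sh <- allele_sharing(c("S1", "S2"), clusters)
  expect_equal(sh$n_shared, 1L); expect_equal(sh$n_total, 2L)
  expect_equal(sh$fraction, 0.5)
  sh2 <- allele_sharing(c("S2", "S1"), clusters)
  expect_equal(sh$fraction, sh2$fraction)
  expect_true(is.na(allele_sharing(c("X", "Y"), clusters)$fraction))
  # identical and disjoint call sets
  cl2 <- data.frame(cluster_id = "m1"); cl2$samples <- list(c("A", "B"))
  expect_equal(allele_sharing(c("A", "B"), cl2)$fraction, 1)
  cl3 <- data.frame(cluster_id = c("m1", "m2"))
  cl3$samples <- list("A", "B")
  expect_equal(allele_sharing(c("A", "B"), cl3)$fraction, 0)
})

test_that("published twin counts reproduce their printed percentages", {
  expect_equal(sharing_percent(19547, 23516), 83.12)
  expect_equal(sharing_percent(25456, 29964), 84.96)
})

test_that("a twin pair with zero planted error shares every cluster", {
  co <- fixture_cohort("noiseless")
  gm <- cohort_matrix(co)
  tw <- co$ped$sample_id[co$ped$role == "twin"]
  gcl <- merge_graph_calls(gm)
  expect_equal(allele_sharing(tw, gcl)$fraction, 1)
  rcl <- merge_ref_calls(co$ref_calls)
  expect_equal(allele_sharing(tw, rcl)$fraction, 1)
})

test_that("permutation null breaks true pairs, is seeded, and sits below truth", {
  co <- fixture_cohort("default")
  rcl <- merge_ref_calls(co$ref_calls)
  sibs <- sibling_pairs(co$ped)[, c("sample1", "sample2")]
  p1 <- permute_sharing(sibs, rcl, n_permutations = 10, seed = 5)
  p2 <- permute_sharing(sibs, rcl, n_permutations = 10, seed = 5)
  expect_identical(p1, p2)
  expect_equal(dim(p1$perm), c(10L, nrow(sibs)))
  expect_gt(p1$true_mean, p1$perm_mean)   # heritable SVs: sibs share more
  # two pairs force the single derangement (a swap)
  two <- sibs[1:2, ]
  swap <- permute_sharing(two, rcl, n_permutations = 3, seed = 1)
  manual <- c(allele_sharing(c(two$sample1[1], two$sample2[2]), rcl)$fraction,
              allele_sharing(c(two$sample1[2], two$sample2[1]), rcl)$fraction)
  for (r in 1:3) expect_equal(unname(swap$perm[r, ]), manual)
})

test_that("mendelian_verdict agrees with the exhaustive 27-case oracle", {
  grid <- expand.grid(p = 0:2, f = 0:2, m = 0:2)
  got <- mendelian_verdict(grid$p, grid$f, grid$m)
  want <- vapply(seq_len(nrow(grid)), function(i)
    oracle_mendel(grid$p[i], grid$f[i], grid$m[i]), character(1))
  expect_equal(got, want)
  # the worked rule instances
  expect_equal(mendelian_verdict(2L, 2L, 2L), "consistent")
  expect_equal(mendelian_verdict(0L, 2L, 0L), "false_negative")
  expect_equal(mendelian_verdict(2L, 0L, 0L), "false_positive")
  expect_error(mendelian_verdict(3L, 0L, 0L), "copy numbers")
})

test_that("planted Mendelian violations are recovered as verdict counts", {
  co <- fixture_cohort("noiseless")
  co <- spike_mendelian_violations(co, n_fp = 5L, n_fn = 3L, seed = 8L)
  tv <- trio_verdicts(co$ref_calls, co$spike_trio[["proband"]],
                      co$spike_trio[["father"]], co$spike_trio[["mother"]])
  expect_equal(sum(tv$verdict == "false_positive"), 5L)
  expect_equal(sum(tv$verdict == "false_negative"), 3L)
  # zero spikes, zero violations
  co0 <- fixture_cohort("noiseless")
  co0 <- spike_mendelian_violations(co0, n_fp = 0L, n_fn = 0L, seed = 8L)
  tv0 <- trio_verdicts(co0$ref_calls, co0$spike_trio[["proband"]],
                       co0$spike_trio[["father"]], co0$spike_trio[["mother"]])
  expect_equal(sum(tv0$verdict != "consistent"), 0L)
  # different seeds plant different positions but the same counts
  coA <- spike_mendelian_violations(fixture_cohort("noiseless"), 4L, 2L, seed = 1L)
  coB <- spike_mendelian_violations(fixture_cohort("noiseless"), 4L, 2L, seed = 2L)
  expect_equal(nrow(coA$mendelian_spike), nrow(coB$mendelian_spike))
  expect_false(identical(sort(coA$mendelian_spike$pos),
                         sort(coB$mendelian_spike$pos)))
})

test_that("sharing under planted sibling false positives matches the closed form", {
  # With FP rate f in both siblings and true sharing s0 over n0 clusters,
  # spurious singleton clusters enter the union but never the intersection:
  # E[sharing] = s0 * n0 / (n0 + 2 f n0) = s0 / (1 + 2 f).
  set.seed(61)
  n0 <- 400L; s0 <- 0.6; f <- 0.25
  reps <- vapply(1:40, function(r) {
    shared <- runif(n0) < s0
    calls <- list()
    add <- function(sample, start, id) {
      mk_calls(start, rep(-300, length(start)), sample, id = id)
    }
    starts <- seq(1000L, by = 5000L, length.out = n0)
    calls[[1]] <- add("S1", starts, sprintf("a%04d", seq_len(n0)))
    calls[[2]] <- add("S2", starts[shared], sprintf("b%04d", which(shared)))
    nf1 <- rbinom(1, n0, f); nf2 <- rbinom(1, n0, f)
    # sample-specific false-positive grids so spurious calls never co-cluster
    fp1 <- sample(seq(2500L, by = 5000L, length.out = n0), nf1)
    fp2 <- sample(seq(3600L, by = 5000L, length.out = n0), nf2)
    calls[[3]] <- add("S1", fp1, sprintf("f%04d", seq_len(nf1)))
    calls[[4]] <- add("S2", fp2, sprintf("g%04d", seq_len(nf2)))
    cl <- merge_ref_calls(do.call(rbind, calls))
    allele_sharing(c("S1", "S2"), cl)$fraction
  }, numeric(1))
  want <- s0 * n0 / (n0 + 2 * f * n0)   # FP clusters at half-offset positions
  # the S1 original calls are all shared-or-not with S2; union = n0 + FPs
  expect_lt(abs(mean(reps) - want), 0.02)
})
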