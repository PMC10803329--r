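# Shared, lazily built cohort fixtures (one generator run reused across
# test files).

.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function(name) {
  if (!is.null(.fixture_env[[name]])) return(.fixture_env[[name]])
  co <- switch(name,
    default = simulate_cohort(cohort_config(seed = 101L)),
    noiseless = simulate_cohort(cohort_config(
      seed = 202L, missing_rate = 0, invalid_rate = 0, spurious_rate = 0,
      ref_caller = list(fp_rate = 0, fn_rate = 0, jitter_sd = 0),
      third_caller = list(fp_rate = 0, fn_rate = 0, jitter_sd = 0))),
    small_noiseless = simulate_cohort(cohort_config(
      seed = 303L, n_loci = 60L, chrom_lengths = c(chr1 = 4e5, chr2 = 4e5),
      n_trios = 2L, n_sibpairs = 1L, n_singlesA = 4L, n_samplesB = 4L,
      missing_rate = 0, invalid_rate = 0, spurious_rate = 0,
      ref_caller = list(fp_rate = 0, fn_rate = 0, jitter_sd = 0),
      third_caller = list(fp_rate = 0, fn_rate = 0, jitter_sd = 0))),
    stop("unknown fixture: ", name))
  .fixture_env[[name]] <- co
  co
}

fixture_matrix <- function(name) {
  key <- paste0(name, "_gm")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- cohort_matrix(fixture_cohort(name))
  }
  .fixture_env[[key]]
}

# a tiny hand-built diamond graph used by several unit tests
diamond_graph <- function() {
  nodes <- data.frame(
    node_id = c("s1", "s2", "s3", "a", "b"),
    sequence = c("AAAA", "CCCC", "GGGG", "TTT", "ATAGG"),
    stable_name = c("chr1", "chr1", "chr1", "g1", "g2"),
    stable_offset = c(0L, 4L, 8L, 0L, 0L),
    rank = c(0L, 0L, 0L, 1L, 2L),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    from = c("s1", "s2", "s1", "a", "s1", "b"),
    from_orient = "+",
    to = c("s2", "s3", "a", "s3", "b", "s3"),
    to_orient = "+",
    stringsAsFactors = FALSE)
  pangenome_graph(nodes, edges)
}
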