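test_that("pool counting gives exact multiset counts from FASTA and FASTQ", {
  p <- count_pool(c("AC", "AC", "GT"), cycle_index = 0L)
  expect_equal(p$counts[["AC"]], 2L)
  expect_equal(p$counts[["GT"]], 1L)
  expect_equal(p$total, 3L)

  dir <- withr::local_tempdir()
  reads <- c("ACGTACGT", "ACGTACGT", "TTGGCCAA", "ACGTACGA")
  fa <- file.path(dir, "reads.fasta")
  writeLines(as.vector(rbind(sprintf(">r%d", seq_along(reads)), reads)), fa)
  fq <- file.path(dir, "reads.fastq")
  writeLines(as.vector(rbind(sprintf("@r%d", seq_along(reads)), reads,
                             "+", strrep("I", 8))), fq)
  pa <- count_pool(fa, 1L)
  pq <- count_pool(fq, 1L)
  expect_identical(pa$counts, pq$counts)
  expect_equal(pa$total, 4L)
})

test_that("reads containing N are dropped and reported", {
  p <- count_pool(c("ACGT", "ACNT", "ACGT", "NNNN"), 0L)
  expect_equal(p$total, 2L)
  expect_equal(p$n_dropped, 2L)
  expect_error(count_pool(c("NNNN"), 0L), class = "affinitylm_invalid_argument")
  expect_error(count_pool(character(0), 0L), class = "affinitylm_invalid_argument")
})

test_that("fold-enrichment relative affinities match hand computation", {
  mk_pool <- function(counts, cycle) {
    structure(list(cycle_index = cycle, counts = counts,
                   total = sum(counts), n_dropped = 0L), class = "cycle_pool")
  }
  # equal frequencies in both cycles -> all affinities 1 after normalisation
  eq <- mk_pool(c(AAAA = 10L, CCCC = 10L, GGGG = 10L), 0L)
  eq2 <- mk_pool(c(AAAA = 20L, CCCC = 20L, GGGG = 20L), 1L)
  aff <- estimate_relative_affinity(eq, eq2)
  expect_true(all(aff$affinities == 1))

  # toy: totals equal, counts 10->40 vs 10->10
  earlier <- mk_pool(c(AAAA = 10L, CCCC = 10L, TTTT = 30L), 0L)
  later <- mk_pool(c(AAAA = 40L, CCCC = 10L), 1L)
  # pseudocount 0: enrichments (40/50)/(10/50) = 4 and 1 -> affinities 1, 0.25
  a0 <- estimate_relative_affinity(earlier, later, pseudocount = 0)
  expect_equal(a0$affinities[a0$sequences == "AAAA"], 1.0)
  expect_equal(a0$affinities[a0$sequences == "CCCC"], 0.25)
  # pseudocount 0.5: (40.5/10.5) / (10.5/10.5) scaled by the max
  a5 <- estimate_relative_affinity(earlier, later, pseudocount = 0.5)
  expect_equal(a5$affinities[a5$sequences == "CCCC"], (10.5 / 10.5) / (40.5 / 10.5),
               tolerance = 1e-12)
  expect_error(estimate_relative_affinity(later, earlier),
               class = "affinitylm_invalid_argument")
  # exact invariance to uniform scaling of both totals (pseudocount 0)
  e10 <- mk_pool(earlier$counts * 10L, 0L)
  l10 <- mk_pool(later$counts * 10L, 1L)
  expect_equal(estimate_relative_affinity(e10, l10, pseudocount = 0)$affinities,
               a0$affinities, tolerance = 1e-12)
})

test_that("bin edges tile the affinity range with the last bin closed", {
  bs <- binning_spec(0, 1, 10L)
  expect_equal(bs$vbin, 0.1)
  expect_equal(bs$edges, seq(0, 1, by = 0.1))
  # values at vmax fall in the last bin; interior edges open on the right
  expect_equal(affinitylm:::bin_index(c(0, 0.05, 0.1, 0.95, 1.0), bs),
               c(1L, 1L, 2L, 10L, 10L))
  expect_error(binning_spec(1, 1, 10L), class = "affinitylm_invalid_argument")
})

test_that("binned sampling yields disjoint size-exact splits", {
  withr::with_seed(15, {
    ds <- affinity_dataset(random_dna(2000, 12, seed = 16),
                           c(runif(1990), rep(0.999, 10)))
  })
  sp <- bin_and_sample(ds, 1000L, seed = 4L)
  expect_length(sp$finetune_idx, 1000L)
  expect_length(sp$valid_idx, 100L)
  expect_length(sp$test_idx, 100L)
  all_idx <- c(sp$finetune_idx, sp$valid_idx, sp$test_idx)
  expect_false(anyDuplicated(all_idx) > 0)
  expect_true(all(all_idx %in% seq_len(ds$N)))
  # reproducible
  sp2 <- bin_and_sample(ds, 1000L, seed = 4L)
  expect_identical(sp$finetune_idx, sp2$finetune_idx)

  const <- affinity_dataset(random_dna(1300, 12, seed = 17), rep(0.5, 1300))
  expect_error(bin_and_sample(const, 1000L), class = "affinitylm_invalid_argument")
  short <- affinity_dataset(random_dna(1100, 12, seed = 18), runif(1100))
  err <- expect_error(bin_and_sample(short, 1000L),
                      class = "affinitylm_insufficient")
  expect_match(conditionMessage(err), "short by 100")
})

test_that("simulated SELEX enrichment recovers true motif scores", {
  spec <- planted_motif_spec(noise_sd = 0)
  sim <- generate_selex_cycles(n_per_cycle = 50000L, read_length = 20L,
                               cycles = 3L, beta = 1, spec = spec, seed = 19L)
  k <- length(sim$pools)
  est <- estimate_relative_affinity(sim$pools[[k - 1L]], sim$pools[[k]])
  truth <- sim$truth[match(est$sequences, sim$candidates)]
  pcc <- pearson_correlation(est$affinities, truth)
  expect_gt(pcc, 0.8)
})

test_that("cross-test manifests enforce metric/label compatibility", {
  m <- build_cross_test_manifest("tf1_d1", c("a.tsv", "b.tsv", "c.tsv"),
                                 kind = "cross_experiment")
  expect_equal(nrow(m), 3L)
  expect_true(all(m$metric == "pcc"))
  m2 <- build_cross_test_manifest("tf1_d1", "chip.tsv", kind = "in_vivo")
  expect_identical(m2$metric, "auroc")
  expect_error(build_cross_test_manifest("tf1_d1", "chip.tsv", kind = "in_vivo",
                                         label_type = "affinity"),
               class = "affinitylm_invalid_argument")
  expect_error(build_cross_test_manifest("tf1_d1", "pbm.tsv",
                                         kind = "cross_platform",
                                         label_type = "binary"),
               class = "affinitylm_invalid_argument")
})
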