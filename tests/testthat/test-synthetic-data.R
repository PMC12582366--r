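test_that("pure background matches the requested GC content", {
  spec <- planted_motif_spec(plant_rate = 0, background_gc = 0.41)
  g <- generate_corpus(10000, 50, spec, seed = 51)
  expect_true(all(is.na(g$truth$position)))
  chars <- strsplit(paste(g$corpus$sequences, collapse = ""), "")[[1]]
  gc <- mean(chars %in% c("G", "C"))
  expect_lt(abs(gc - 0.41), 0.01)
})

test_that("plant bookkeeping and determinism hold", {
  spec <- planted_motif_spec(plant_rate = 1)
  g <- generate_corpus(200, 40, spec, seed = 52)
  expect_true(all(g$truth$planted))
  expect_true(all(!is.na(g$truth$position)))
  W <- ncol(spec$pwm)
  expect_true(all(g$truth$position >= 1 & g$truth$position <= 40 - W + 1))
  g2 <- generate_corpus(200, 40, spec, seed = 52)
  expect_identical(g$corpus$sequences, g2$corpus$sequences)
  expect_error(generate_corpus(10, 5, spec), class = "affinitylm_invalid_argument")
})

test_that("noiseless affinities equal the true min-max scores exactly", {
  spec <- planted_motif_spec(noise_sd = 0)
  g <- generate_affinity_dataset(500, 30, spec, seed = 53)
  expect_identical(g$data$affinities, g$truth)
  expect_true(all(g$truth >= 0 & g$truth <= 1))
  # noisy observation stays well correlated with the truth
  spec_n <- planted_motif_spec(noise_sd = 0.1)
  gn <- generate_affinity_dataset(5000, 30, spec_n, seed = 54)
  pcc <- pearson_correlation(gn$data$affinities, gn$truth)
  expect_gt(pcc, 0.8)
  expect_lt(pcc, 1.0)
  # all-background sequences have low-variance scores
  bg <- generate_affinity_dataset(2000, 30,
                                  planted_motif_spec(plant_rate = 0, noise_sd = 0),
                                  seed = 55)
  pl <- generate_affinity_dataset(2000, 30,
                                  planted_motif_spec(plant_rate = 0.8, noise_sd = 0),
                                  seed = 55)
  expect_lt(sd(bg$truth), sd(pl$truth))
})

test_that("neutral selection leaves cycle frequencies unchanged", {
  sim <- generate_selex_cycles(n_per_cycle = 20000L, read_length = 16L,
                               cycles = 3L, beta = 0,
                               spec = planted_motif_spec(noise_sd = 0),
                               candidate_pool_size = 200L, seed = 56L)
  expect_true(all(vapply(sim$pools, `[[`, numeric(1), "total") == 20000L))
  first <- sim$pools[[1]]$counts[sim$candidates]
  last <- sim$pools[[3]]$counts[sim$candidates]
  first[is.na(first)] <- 0L; last[is.na(last)] <- 0L
  keep <- first + last > 0
  suppressWarnings(
    ch <- chisq.test(cbind(first[keep], last[keep]))
  )
  expect_gt(ch$p.value, 0.01)
})

test_that("positive selection enriches high-affinity candidates every cycle", {
  sim <- generate_selex_cycles(n_per_cycle = 20000L, read_length = 20L,
                               cycles = 4L, beta = 1,
                               spec = planted_motif_spec(noise_sd = 0),
                               candidate_pool_size = 500L, seed = 57L)
  mean_score <- vapply(sim$pools, function(p) {
    sc <- sim$truth[match(names(p$counts), sim$candidates)]
    sum(sc * p$counts) / p$total
  }, numeric(1))
  expect_true(all(diff(mean_score) > 0))
})

test_that("SELEX FASTA export round-trips through pool counting", {
  sim <- generate_selex_cycles(n_per_cycle = 500L, read_length = 12L,
                               cycles = 2L, candidate_pool_size = 50L,
                               seed = 58L)
  dir <- withr::local_tempdir()
  paths <- write_selex_fasta(sim$pools, dir)
  back <- count_pool(paths[2], cycle_index = 1L)
  expect_identical(back$counts[order(names(back$counts))],
                   sim$pools[[2]]$counts[order(names(sim$pools[[2]]$counts))])
})

test_that("binary test sets label by score threshold", {
  spec <- planted_motif_spec(noise_sd = 0)
  b <- generate_binary_testset(2000, 30, spec, score_threshold = 0.5, seed = 59L)
  expect_setequal(unique(b$table$label), c(0L, 1L))
  expect_equal(b$class_balance, mean(b$table$label))
  # the truth itself separates the labels perfectly
  expect_equal(auroc(b$truth, b$table$label), 1.0)
  # an independent random score is uninformative
  withr::with_seed(60, {
    expect_lt(abs(auroc(runif(2000), b$table$label) - 0.5), 0.05)
  })
  # threshold below the minimum: everything labelled 1 (and warned about)
  expect_warning(
    all1 <- generate_binary_testset(100, 30, spec, score_threshold = -1, seed = 61L),
    "single-class")
  expect_true(all(all1$table$label == 1L))
})
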