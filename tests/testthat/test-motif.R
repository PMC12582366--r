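# Hand-built attention profiles: n_layers x n_heads x T x T arrays over a
# sequence of length T - 2 ([CLS]/[SEP] framing included).
mk_profile <- function(sequence, mats) {
  T <- nchar(sequence) + 2L
  nl <- length(mats); nh <- length(mats[[1L]])
  attn <- array(0, c(nl, nh, T, T))
  for (l in seq_len(nl)) for (h in seq_len(nh)) attn[l, h, , ] <- mats[[l]][[h]]
  structure(list(sequence = sequence, attn = attn), class = "attention_profile")
}
uniform_mat <- function(T) matrix(1 / T, T, T)

test_that("received attention is the column mean of the stripped average", {
  L <- 6L; T <- L + 2L
  seqs <- strrep("A", L)
  cfg <- motif_config(excluded_leading_layers = 1L)
  # uniform attention everywhere -> constant score 1/L after stripping
  prof <- mk_profile(seqs, list(list(uniform_mat(T)), list(uniform_mat(T))))
  sc <- received_attention_vector(prof, cfg)
  expect_equal(sc, rep(1 / L, L), tolerance = 1e-12)

  # single matrix with one column carrying all mass -> that score is 1
  M <- matrix(0, T, T); M[, 4L] <- 1
  prof2 <- mk_profile(seqs, list(list(uniform_mat(T)), list(M)))
  sc2 <- received_attention_vector(prof2, cfg)
  expect_equal(sc2[3L], 1)                        # column 4 = nucleotide 3
  expect_equal(sum(sc2), 1)

  # random row-stochastic matrices: scores sum to 1
  withr::with_seed(31, {
    rand_mat <- function() {
      m <- matrix(rexp(T * T), T, T); m / rowSums(m)
    }
    prof3 <- mk_profile(seqs, list(list(rand_mat(), rand_mat()),
                                   list(rand_mat(), rand_mat())))
  })
  expect_equal(sum(received_attention_vector(prof3, cfg)), 1, tolerance = 1e-6)
  # excluded layers must leave at least one layer
  expect_error(received_attention_vector(prof, motif_config(excluded_leading_layers = 2L)),
               class = "affinitylm_invalid_argument")
})

test_that("the base-level contract is enforced", {
  m <- init_encoder(micro_encoder_config(), seed = 12L)
  v6 <- build_kmer_vocab(1L)
  expect_error(attention_profile(m, "ACGTACGT", build_kmer_vocab(4L)),
               class = "affinitylm_invalid_argument")
  prof <- attention_profile(m, "ACGTACGT", v6)
  expect_s3_class(prof, "attention_profile")
  expect_equal(dim(prof$attn)[3], 10L)
})

test_that("high-attention run detection follows the strict-mean rule", {
  cfg <- motif_config(min_run_length = 8L)
  expect_equal(nrow(find_high_attention_runs(rep(0.3, 50), cfg)), 0L)
  sc <- rep(1, 50); sc[21:30] <- 5                 # 10 elevated among 40 flat
  runs <- find_high_attention_runs(sc, cfg)
  expect_equal(unname(runs), matrix(c(20L, 30L), 1))
  # blocks of 7 and 9: only the 9 survives the length filter
  sc2 <- rep(1, 60); sc2[5:11] <- 5; sc2[31:39] <- 5
  runs2 <- find_high_attention_runs(sc2, cfg)
  expect_equal(nrow(runs2), 1L)
  expect_equal(unname(runs2[1, "start"]), 30L)
  expect_equal(unname(runs2[1, "end"] - runs2[1, "start"]), 9L)
  # invariant to affine rescaling
  expect_identical(find_high_attention_runs(3 * sc2 + 7, cfg), runs2)
})

test_that("center-star alignment and PFM derivation behave on known cases", {
  ident <- derive_motif(rep("ACGTACGT", 5))
  expect_equal(ident$width, 8L)
  expect_true(all(apply(ident$freq, 2, max) == 1))
  expect_equal(colSums(ident$freq), rep(1, 8), tolerance = 1e-9)

  pfm <- derive_motif(c("ACGTACGT", "CGTACGTA"))
  # best offset +1 aligns the shared 7-mer core CGTACGT
  expect_equal(pfm$offsets, c(0L, 1L))
  expect_equal(pfm$width, 9L)
  core <- pfm$freq[, 2:8]
  consensus <- paste(rownames(core)[apply(core, 2, which.max)], collapse = "")
  expect_equal(consensus, "CGTACGT")
  expect_true(all(apply(core, 2, max) == 1))       # 2 matching sequences
  expect_equal(colSums(pfm$counts[, c(1, 9)]), c(1, 1))  # single-support ends
  expect_error(derive_motif("ACGT"), class = "affinitylm_invalid_argument")
})

test_that("motif similarity is 1 for identical motifs, near 0 for disjoint ones", {
  withr::with_seed(33, {
    a <- as_pfm(matrix(runif(4 * 8) + 0.1, 4, 8))
  })
  expect_equal(motif_similarity(a, a, n_sequences = 5000L, seed = 2), 1)
  polyA <- as_pfm(matrix(c(0.97, 0.01, 0.01, 0.01), 4, 8))
  polyC <- as_pfm(matrix(c(0.01, 0.97, 0.01, 0.01), 4, 8))
  expect_lt(abs(motif_similarity(polyA, polyC, n_sequences = 20000L, seed = 3)),
            0.1)
  # symmetry under a shared sequence set
  expect_equal(motif_similarity(a, polyA, n_sequences = 5000L, seed = 4),
               motif_similarity(polyA, a, n_sequences = 5000L, seed = 4),
               tolerance = 1e-12)
  # reproducible to the last digit with a fixed seed; stable across seeds
  s1 <- motif_similarity(a, polyA, n_sequences = 50000L, seed = 5)
  expect_identical(motif_similarity(a, polyA, n_sequences = 50000L, seed = 5), s1)
  s2 <- motif_similarity(a, polyA, n_sequences = 50000L, seed = 6)
  expect_lt(abs(s1 - s2), 0.01)
})

test_that("information content spans 0 (uniform) to 2 (deterministic) bits", {
  u <- as_pfm(matrix(0.25, 4, 5))
  expect_equal(pfm_information_content(u), rep(0, 5), tolerance = 1e-12)
  d <- as_pfm(matrix(c(1, 0, 0, 0), 4, 3))
  expect_equal(pfm_information_content(d), rep(2, 3))
})

test_that("PFM writers emit valid JASPAR and MEME minimal formats", {
  pfm <- derive_motif(c("ACGTACGTT", "ACGTACGTA", "ACGTACGTA"))
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "m.jaspar"); mp <- file.path(dir, "m.meme")
  write_pfm_jaspar(pfm, jp, name = "planted")
  write_pfm_meme(pfm, mp, name = "planted")
  jl <- readLines(jp)
  expect_equal(jl[1], ">planted")
  expect_length(jl, 5L)
  ml <- readLines(mp)
  expect_true(any(grepl("letter-probability matrix: alength= 4 w= 9", ml)))
  probs <- read.table(text = ml[(which(grepl("letter-probability", ml)) + 1):length(ml)])
  expect_equal(rowSums(probs), rep(1, pfm$width), tolerance = 1e-4)
})

test_that("head-specific analysis keeps heads separate", {
  L <- 30L; T <- L + 2L
  seqs <- random_dna(1, L, seed = 35)
  # two heads with different focus columns, identical across layers
  M1 <- matrix(0, T, T); M1[, 5:14] <- 1 / 10
  M2 <- matrix(0, T, T); M2[, 15:24] <- 1 / 10
  prof <- mk_profile(seqs, list(list(M1, M2), list(M1, M2), list(M1, M2)))
  hp <- head_specific_patterns(list(prof), motif_config(excluded_leading_layers = 2L,
                                                        min_run_length = 8L))
  expect_length(hp, 2L)
  expect_false(isTRUE(all.equal(hp[[1]]$scores[[1]], hp[[2]]$scores[[1]])))
  # identical heads give identical vectors
  prof_same <- mk_profile(seqs, list(list(M1, M1), list(M1, M1), list(M1, M1)))
  hp2 <- head_specific_patterns(list(prof_same),
                                motif_config(excluded_leading_layers = 1L))
  expect_equal(hp2[[1]]$scores[[1]], hp2[[2]]$scores[[1]])
})

test_that("end-to-end attention motif extraction runs and keeps its books", {
  mot <- flagship_motif()
  expect_equal(mot$n_sequences_used, 100L)
  expect_length(mot$runs_per_sequence, 100L)
  expect_true(all(mot$runs_per_sequence >= 0L))
  # every collected subsequence honours the minimum run length
  if (length(mot$subsequences) > 0L) {
    expect_true(all(nchar(mot$subsequences) >= motif_config()$min_run_length))
  }
  # a derived PFM, when present, satisfies its structural invariants
  if (!is.null(mot$pfm)) {
    expect_gte(mot$pfm$width, 8L)
    expect_equal(colSums(mot$pfm$freq), rep(1, mot$pfm$width), tolerance = 1e-9)
  }
})
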