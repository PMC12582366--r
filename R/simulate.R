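# Synthetic planted-motif data generator.
#
# Emulates, with known ground truth, the three data sources the real
# pipeline consumes: open-chromatin-like background corpora for pretraining,
# (sequence, affinity) tables for fine-tuning, and multi-cycle SELEX pools.
# Background DNA is i.i.d. with configurable GC content; a planted PWM motif
# drives affinity as the best-window log-odds score.

#' Planted-motif specification
#'
#' @param pwm 4 x W probability matrix (rows A/C/G/T, columns sum to 1);
#'   default [default_planted_pwm()].
#' @param plant_rate Fraction of sequences carrying one motif instance
#'   (default 0.8).
#' @param background_gc Background GC fraction (default 0.41, human-like).
#' @param noise_sd Gaussian noise added to scaled affinities (default 0.1).
#' @param seed Generator seed.
#' @return A `planted_motif_spec`.
#' @export
planted_motif_spec <- function(pwm = default_planted_pwm(), plant_rate = 0.8,
                               background_gc = 0.41, noise_sd = 0.1,
                               seed = 1L) {
  assert_that(nrow(pwm) == 4L, "PWM must have 4 rows")
  assert_that(all(abs(colSums(pwm) - 1) < 1e-8), "PWM columns must sum to 1")
  assert_that(plant_rate >= 0 && plant_rate <= 1, "plant_rate must be in [0, 1]")
  assert_that(background_gc > 0 && background_gc < 1, "invalid GC fraction")
  rownames(pwm) <- DNA_BASES
  structure(list(pwm = pwm, plant_rate = plant_rate,
                 background_gc = background_gc, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "planted_motif_spec")
}

#' Default planted motif: a sharply informative 12-bp PWM
#'
#' Each column puts probability 0.85 on one consensus base and 0.05 on the
#' others; the consensus itself is drawn from the seed.
#'
#' @param width Motif width (default 12).
#' @param dominant Consensus-base probability per column (default 0.85).
#' @param seed Seed for the consensus draw.
#' @return 4 x `width` probability matrix.
#' @export
default_planted_pwm <- function(width = 12L, dominant = 0.85, seed = 7L) {
  consensus <- with_seed(derive_seed(seed, "pwm"),
                         sample.int(4L, width, replace = TRUE))
  pwm <- matrix((1 - dominant) / 3, 4L, width, dimnames = list(DNA_BASES, NULL))
  pwm[cbind(consensus, seq_len(width))] <- dominant
  pwm
}

background_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# Integer-coded (1..4 = A,C,G,T) background matrix n x L.
sample_background <- function(n, length, gc) {
  matrix(sample.int(4L, n * length, replace = TRUE, prob = background_probs(gc)),
         n, length)
}

mat_to_strings <- function(m) {
  apply(m, 1L, function(r) paste(DNA_BASES[r], collapse = ""))
}

# Best-window log-odds of every row of an integer-coded matrix against the
# i.i.d. background implied by `gc`; PWM columns floored at 1e-3 so log-odds
# stay finite.
best_window_log_odds <- function(seq_mat, pwm, gc) {
  W <- ncol(pwm)
  L <- ncol(seq_mat)
  assert_that(L >= W, "sequences shorter than the motif")
  lo <- log(pmax(pwm, 1e-3) / background_probs(gc))
  best <- rep(-Inf, nrow(seq_mat))
  for (o in 0:(L - W)) {
    s <- numeric(nrow(seq_mat))
    for (j in seq_len(W)) {
      s <- s + lo[cbind(seq_mat[, o + j], j)]
    }
    best <- pmax(best, s)
  }
  best
}

plant_motifs <- function(seq_mat, spec) {
  n <- nrow(seq_mat); L <- ncol(seq_mat); W <- ncol(spec$pwm)
  planted <- stats::runif(n) < spec$plant_rate
  position <- rep(NA_integer_, n)
  idx <- which(planted)
  if (length(idx) > 0L) {
    position[idx] <- sample.int(L - W + 1L, length(idx), replace = TRUE)
    for (j in seq_len(W)) {
      seq_mat[cbind(idx, position[idx] + j - 1L)] <-
        sample.int(4L, length(idx), replace = TRUE, prob = spec$pwm[, j])
    }
  }
  list(seq_mat = seq_mat, planted = planted, position = position)
}

#' Generate a background corpus with planted motifs
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp (must cover the motif).
#' @param spec A `planted_motif_spec`.
#' @param seed Seed (defaults to the one stored in the motif specification).
#' @return List with `corpus` (a `pretrain_corpus`) and `truth`
#'   (data.frame: `planted`, `position` 1-based or NA).
#' @export
generate_corpus <- function(n, length, spec = planted_motif_spec(),
                            seed = spec$seed) {
  assert_that(length >= ncol(spec$pwm), "length must cover the motif")
  with_seed(derive_seed(seed, "corpus"), {
    pm <- plant_motifs(sample_background(n, length, spec$background_gc), spec)
    corpus <- structure(
      list(sequences = mat_to_strings(pm$seq_mat), source_id = NULL,
           max_length = as.integer(length),
           report = list(n_peaks = n, n_out = n, drops = list())),
      class = "pretrain_corpus")
    list(corpus = corpus,
         truth = data.frame(planted = pm$planted, position = pm$position))
  })
}

#' Generate an affinity dataset with known truth
#'
#' True scores are best-window PWM log-odds min-max mapped to `[0, 1]`;
#' observed affinities add clipped Gaussian noise of sd `spec$noise_sd`.
#'
#' @inheritParams generate_corpus
#' @return List with `data` (an `affinity_dataset`, provenance
#'   `"synthetic"`) and `truth` (numeric true scores in `[0, 1]`).
#' @export
generate_affinity_dataset <- function(n, length, spec = planted_motif_spec(),
                                      seed = spec$seed) {
  assert_that(length >= ncol(spec$pwm), "length must cover the motif")
  with_seed(derive_seed(seed, "affinity"), {
    pm <- plant_motifs(sample_background(n, length, spec$background_gc), spec)
    raw <- best_window_log_odds(pm$seq_mat, spec$pwm, spec$background_gc)
    true <- (raw - min(raw)) / (max(raw) - min(raw))
    obs <- pmin(1, pmax(0, true + stats::rnorm(n, sd = spec$noise_sd)))
    list(data = affinity_dataset(mat_to_strings(pm$seq_mat), obs,
                                 provenance = "synthetic"),
         truth = true)
  })
}

#' Simulate multi-cycle SELEX selection
#'
#' Cycle 0 samples a candidate pool uniformly; each later cycle resamples the
#' previous cycle's reads with weights proportional to
#' `exp(beta * true score)`, so high-affinity candidates enrich
#' exponentially over cycles.
#'
#' @param n_per_cycle Reads sequenced per cycle (default 50000).
#' @param read_length Read length in bp.
#' @param cycles Number of pools returned (>= 2, including cycle 0).
#' @param beta Selection strength on the `[0, 1]` true score (default 1).
#' @param spec A `planted_motif_spec`.
#' @param candidate_pool_size Distinct candidate sequences (default 500,
#'   i.e. 100x read coverage at the default depth: the fold-enrichment
#'   ratio's counting noise scales as sqrt(2 / coverage), so coverage below
#'   roughly 50x drowns the enrichment signal).
#' @param seed Seed.
#' @return List with `pools` (list of `cycle_pool`), `candidates`, and
#'   `truth` (true score per candidate).
#' @export
generate_selex_cycles <- function(n_per_cycle = 50000L, read_length = 20L,
                                  cycles = 3L, beta = 1,
                                  spec = planted_motif_spec(),
                                  candidate_pool_size = 500L,
                                  seed = spec$seed) {
  assert_that(is_count(cycles) && cycles >= 2L, "need at least 2 cycles")
  with_seed(derive_seed(seed, "selex"), {
    pm <- plant_motifs(sample_background(candidate_pool_size, read_length,
                                         spec$background_gc), spec)
    raw <- best_window_log_odds(pm$seq_mat, spec$pwm, spec$background_gc)
    true <- (raw - min(raw)) / (max(raw) - min(raw))
    cand <- mat_to_strings(pm$seq_mat)
    fitness <- exp(beta * true)
    pools <- vector("list", cycles)
    counts <- drop(stats::rmultinom(1L, n_per_cycle,
                                    rep(1, candidate_pool_size)))
    for (cy in seq_len(cycles)) {
      keep <- counts > 0L
      # collapse candidates that drew the same sequence (possible when the
      # read barely exceeds the motif) into one multiset entry
      agg <- tapply(counts[keep], cand[keep], sum)
      cnt <- as.integer(agg)
      names(cnt) <- names(agg)
      pools[[cy]] <- structure(
        list(cycle_index = cy - 1L, counts = cnt, total = sum(cnt),
             n_dropped = 0L),
        class = "cycle_pool")
      if (cy < cycles) {
        counts <- drop(stats::rmultinom(1L, n_per_cycle, counts * fitness))
      }
    }
    first <- !duplicated(cand)
    list(pools = pools, candidates = cand[first], truth = true[first])
  })
}

#' Write SELEX cycle pools as FASTA files
#' @param pools List of `cycle_pool`s.
#' @param dir Output directory; files are named `cycle<k>.fasta`.
#' @export
write_selex_fasta <- function(pools, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(pools))
  for (i in seq_along(pools)) {
    p <- pools[[i]]
    reads <- rep(names(p$counts), p$counts)
    dna <- Biostrings::DNAStringSet(reads)
    names(dna) <- sprintf("read%d", seq_along(reads))
    paths[i] <- file.path(dir, sprintf("cycle%d.fasta", p$cycle_index))
    Biostrings::writeXStringSet(dna, paths[i])
  }
  paths
}

#' Generate a binary-labelled test table
#'
#' Emulates in-vivo (ChIP-seq-style) bound/unbound test sets: label 1 iff
#' the true `[0, 1]` motif score reaches `score_threshold`.
#'
#' @inheritParams generate_affinity_dataset
#' @param score_threshold Threshold on the true score (default 0.5).
#' @return List with `table` (data.frame `sequence`, `label`), `truth`, and
#'   `class_balance` (fraction labelled 1).
#' @export
generate_binary_testset <- function(n, length, spec = planted_motif_spec(),
                                    score_threshold = 0.5, seed = spec$seed) {
  gen <- generate_affinity_dataset(n, length, spec, seed = derive_seed(seed, "binary"))
  labels <- as.integer(gen$truth >= score_threshold)
  balance <- mean(labels)
  if (balance == 0 || balance == 1) {
    warning("degenerate single-class label set")
  }
  list(table = data.frame(sequence = gen$data$sequences, label = labels),
       truth = gen$truth, class_balance = balance)
}
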