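# Attention-based motif derivation and PFM tooling.
#
# Works at base-level tokenization only (nucleotide == token), so attention
# columns map one-to-one onto sequence positions.  The received-attention
# score of a nucleotide is the column mean of the layer/head-averaged
# attention matrix after dropping the first two encoder layers (which carry
# broad, position-generic attention) and removing/renormalising the
# [CLS]/[SEP]/[PAD] rows and columns.

#' Motif extraction configuration
#'
#' @param top_n_sequences Sequences (ranked by predicted affinity) used for
#'   motif derivation (default 1000).
#' @param excluded_leading_layers Leading encoder layers dropped from the
#'   attention average (default 2).
#' @param min_run_length Minimum consecutive high-attention nucleotides
#'   (default 8).
#' @return A `motif_config`.
#' @export
motif_config <- function(top_n_sequences = 1000L, excluded_leading_layers = 2L,
                         min_run_length = 8L) {
  structure(list(top_n_sequences = as.integer(top_n_sequences),
                 excluded_leading_layers = as.integer(excluded_leading_layers),
                 min_run_length = as.integer(min_run_length),
                 threshold_rule = "mean"),
            class = "motif_config")
}

#' Attention profile of one sequence
#'
#' Runs the encoder at base level and packages the full per-layer-per-head
#' attention tensor with the sequence.
#'
#' @param params An `affinity_lm`.
#' @param sequence One DNA string.
#' @param vocab A base-level (`single_base`) `token_vocab`.
#' @return An `attention_profile`: list with `sequence` and `attn`
#'   (`[layer, head, T, T]`, T = length + 2 for `[CLS]`/`[SEP]`).
#' @export
attention_profile <- function(params, sequence, vocab) {
  assert_that(vocab$kind == "single_base",
              "nucleotide-level attention requires base-level tokenization")
  enc <- encode(params, sequence, vocab, need_attn = TRUE)
  structure(list(sequence = sequence, attn = enc$attention[[1L]]),
            class = "attention_profile")
}

#' Per-nucleotide received-attention scores
#'
#' Drops the leading `excluded_leading_layers` layers, removes special-token
#' rows/columns and renormalises each remaining row, averages the matrices
#' elementwise across layers and heads, and returns the column means: the
#' attention each nucleotide receives from all others.  Scores sum to 1.
#'
#' @param profile An `attention_profile` (base-level).
#' @param config A `motif_config`.
#' @param heads Optional head subset to average over (used for head-specific
#'   analysis); default all heads.
#' @return Numeric score vector, one entry per nucleotide.
#' @export
received_attention_vector <- function(profile, config = motif_config(),
                                      heads = NULL) {
  stopifnot(inherits(profile, "attention_profile"))
  dims <- dim(profile$attn)
  n_layers <- dims[1L]; n_heads <- dims[2L]; T <- dims[3L]
  L <- nchar(profile$sequence)
  assert_that(T == L + 2L,
              "profile is not base-level: one token per nucleotide required")
  assert_that(config$excluded_leading_layers < n_layers,
              "cannot exclude all encoder layers")
  layers <- (config$excluded_leading_layers + 1L):n_layers
  if (is.null(heads)) heads <- seq_len(n_heads)
  keep <- 2L:(T - 1L)                       # strip [CLS] and [SEP]
  acc <- matrix(0, L, L)
  for (l in layers) {
    for (h in heads) {
      A <- profile$attn[l, h, keep, keep]
      A <- A / rowSums(A)                   # renormalise after stripping
      acc <- acc + A
    }
  }
  colMeans(acc / (length(layers) * length(heads)))
}

#' Find high-attention runs
#'
#' Positions scoring strictly above the mean are "high"; maximal runs of at
#' least `min_run_length` consecutive high positions are returned as 0-based
#' half-open intervals.  Strict comparison means a constant score vector
#' yields no runs; the rule is invariant to affine rescaling of the scores.
#'
#' @param scores Numeric vector (e.g. from [received_attention_vector()]).
#' @param config A `motif_config`.
#' @return Integer matrix with columns `start`, `end` (0-based half-open).
#' @export
find_high_attention_runs <- function(scores, config = motif_config()) {
  assert_that(length(scores) > 0L, "empty score vector")
  high <- scores > mean(scores)
  r <- rle(high)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= config$min_run_length
  cbind(start = starts[keep] - 1L, end = ends[keep])
}

# Center-star offset alignment: the longest subsequence is the star; every
# other sequence takes the ungapped offset maximising exact matches (ties:
# smaller |offset|, then smaller offset).  Returns per-sequence offsets in
# star coordinates (star at offset 0).
align_center_star <- function(subsequences) {
  lens <- nchar(subsequences)
  star_i <- which.max(lens)
  star <- strsplit(subsequences[star_i], "")[[1L]]
  offsets <- integer(length(subsequences))
  for (i in seq_along(subsequences)) {
    if (i == star_i) next
    s <- strsplit(subsequences[i], "")[[1L]]
    cand <- (-(length(s) - 1L)):(length(star) - 1L)
    matches <- vapply(cand, function(o) {
      pos <- seq_len(length(star))
      ok <- pos - o >= 1L & pos - o <= length(s)
      sum(star[ok] == s[pos[ok] - o])
    }, numeric(1))
    best <- max(matches)
    tied <- cand[matches == best]
    tied <- tied[order(abs(tied), tied)]
    offsets[i] <- tied[1L]
  }
  list(offsets = offsets, star = star_i)
}

#' Derive a position frequency matrix from subsequences
#'
#' Aligns the subsequences by center-star offset alignment (overhangs become
#' leading/trailing gaps), counts bases per aligned column with gaps
#' excluded, and normalises each column over its non-gap counts.
#'
#' @param subsequences Character vector (>= 2) of A/C/G/T subsequences.
#' @return A `pfm`: list with `counts` and `freq` (4 x W matrices, rows
#'   A/C/G/T), `support` (number of subsequences), `offsets`.
#' @export
derive_motif <- function(subsequences) {
  assert_that(length(subsequences) >= 2L, "need at least 2 subsequences")
  al <- align_center_star(subsequences)
  lens <- nchar(subsequences)
  first <- min(al$offsets)                 # leftmost occupied star coordinate
  width <- max(al$offsets + lens - 1L) - first + 1L
  counts <- matrix(0, 4L, width, dimnames = list(DNA_BASES, NULL))
  for (i in seq_along(subsequences)) {
    chars <- strsplit(subsequences[i], "")[[1L]]
    cols <- (al$offsets[i] - first) + seq_along(chars)
    for (j in seq_along(chars)) {
      counts[chars[j], cols[j]] <- counts[chars[j], cols[j]] + 1L
    }
  }
  covered <- colSums(counts) > 0
  if (!all(covered)) {
    warning(sprintf("dropping %d all-gap column(s)", sum(!covered)))
    counts <- counts[, covered, drop = FALSE]
  }
  new_pfm(counts, support = length(subsequences), offsets = al$offsets)
}

new_pfm <- function(counts, support = NA_integer_, offsets = NULL) {
  freq <- sweep(counts, 2L, colSums(counts), "/")
  structure(list(counts = counts, freq = freq, width = ncol(counts),
                 support = support, offsets = offsets),
            class = "pfm")
}

#' Build a `pfm` from a probability (or count) matrix
#' @param mat 4 x W matrix, rows A/C/G/T.
#' @export
as_pfm <- function(mat) {
  assert_that(nrow(mat) == 4L, "PFM must have 4 rows (A, C, G, T)")
  rownames(mat) <- DNA_BASES
  new_pfm(mat)
}

#' @export
print.pfm <- function(x, ...) {
  cons <- paste(DNA_BASES[apply(x$freq, 2L, which.max)], collapse = "")
  cat(sprintf("<pfm: width %d, support %s, consensus %s>\n",
              x$width, x$support, cons))
  invisible(x)
}

#' Per-column information content (bits) of a PFM
#' @param pfm A `pfm`.
#' @return Numeric vector: `2 - Shannon entropy` per column.
#' @export
pfm_information_content <- function(pfm) {
  apply(pfm$freq, 2L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

# Sum-over-windows PFM score of integer-coded sequences (n x L, values 1..4),
# forward strand: score(s) = sum_w prod_j freq[s[w+j], j].
pfm_score_matrix <- function(pfm, seq_mat) {
  W <- pfm$width
  L <- ncol(seq_mat)
  assert_that(L >= W, "sequences shorter than the motif")
  total <- numeric(nrow(seq_mat))
  for (o in 0:(L - W)) {
    p <- rep(1, nrow(seq_mat))
    for (j in seq_len(W)) {
      p <- p * pfm$freq[cbind(seq_mat[, o + j], j)]
    }
    total <- total + p
  }
  total
}

#' Motif similarity by score correlation over random sequences
#'
#' Generates `n_sequences` random uniform sequences, scores each under both
#' motifs (sum over all forward-strand windows of the product of column
#' frequencies), and returns the Pearson correlation between the two score
#' vectors.
#'
#' @param a,b `pfm` objects.
#' @param n_sequences Number of random sequences (default 50000).
#' @param seq_length Sequence length; must cover the wider motif (default:
#'   wider motif width + 10).
#' @param seed Integer seed.
#' @param both_strands Also score the reverse complement and sum (default
#'   `FALSE`, forward strand only).
#' @return Correlation in `[-1, 1]`.
#' @export
motif_similarity <- function(a, b, n_sequences = 50000L, seq_length = NULL,
                             seed = 1L, both_strands = FALSE) {
  stopifnot(inherits(a, "pfm"), inherits(b, "pfm"))
  if (is.null(seq_length)) seq_length <- max(a$width, b$width) + 10L
  assert_that(seq_length >= max(a$width, b$width),
              "seq_length must cover both motifs")
  with_seed(derive_seed(seed, "motif_similarity"), {
    seq_mat <- matrix(sample.int(4L, n_sequences * seq_length, replace = TRUE),
                      n_sequences, seq_length)
    score <- function(p) {
      s <- pfm_score_matrix(p, seq_mat)
      if (both_strands) {
        rc <- matrix(5L - seq_mat[, seq_length:1], n_sequences, seq_length)
        s <- s + pfm_score_matrix(p, rc)
      }
      s
    }
    sa <- score(a); sb <- score(b)
    if (stats::sd(sa) == 0 || stats::sd(sb) == 0) {
      abort_invalid("zero-variance motif scores: similarity undefined",
                    class = "affinitylm_undefined_metric")
    }
    stats::cor(sa, sb)
  })
}

#' End-to-end attention-based motif extraction
#'
#' Ranks `sequences` by predicted affinity, keeps the top
#' `config$top_n_sequences`, computes received-attention scores per sequence,
#' cuts out high-attention runs, and derives one PFM from all collected
#' subsequences.
#'
#' @param params A fine-tuned `affinity_lm`.
#' @param sequences Candidate pool (e.g. a hold-out test set).
#' @param vocab Base-level `token_vocab`.
#' @param config A `motif_config`.
#' @return List with `pfm` (or `NULL` if fewer than 2 runs were found),
#'   `subsequences`, `n_sequences_used`, and `runs_per_sequence`.
#' @export
extract_motifs <- function(params, sequences, vocab, config = motif_config()) {
  pred <- predict_affinity(params, sequences, vocab, rescale = FALSE)
  top <- order(pred, decreasing = TRUE)[
    seq_len(min(config$top_n_sequences, length(sequences)))]
  subs <- character(0)
  n_runs <- integer(0)
  for (i in top) {
    prof <- attention_profile(params, sequences[i], vocab)
    sc <- received_attention_vector(prof, config)
    runs <- find_high_attention_runs(sc, config)
    n_runs <- c(n_runs, nrow(runs))
    if (nrow(runs) > 0L) {
      subs <- c(subs, substring(sequences[i], runs[, "start"] + 1L,
                                runs[, "end"]))
    }
  }
  pfm <- if (length(subs) >= 2L) derive_motif(subs) else NULL
  list(pfm = pfm, subsequences = subs, n_sequences_used = length(top),
       runs_per_sequence = n_runs)
}

#' Head-specific attention patterns
#'
#' Averages attention over (non-excluded) layers separately per head, giving
#' one received-attention vector per head per sequence; run detection and
#' PFM derivation are then restricted to each head's own high-attention
#' regions.
#'
#' @param profiles List of `attention_profile`s.
#' @param config A `motif_config`.
#' @return List of length `num_heads`; each element holds `scores` (list of
#'   per-sequence vectors), `subsequences`, and `pfm` (or `NULL`).
#' @export
head_specific_patterns <- function(profiles, config = motif_config()) {
  assert_that(length(profiles) >= 1L, "need at least one profile")
  n_heads <- dim(profiles[[1L]]$attn)[2L]
  lapply(seq_len(n_heads), function(h) {
    scores <- lapply(profiles, received_attention_vector, config = config,
                     heads = h)
    subs <- character(0)
    for (i in seq_along(profiles)) {
      runs <- find_high_attention_runs(scores[[i]], config)
      if (nrow(runs) > 0L) {
        subs <- c(subs, substring(profiles[[i]]$sequence,
                                  runs[, "start"] + 1L, runs[, "end"]))
      }
    }
    list(head = h, scores = scores, subsequences = subs,
         pfm = if (length(subs) >= 2L) derive_motif(subs) else NULL)
  })
}

#' Write a PFM in JASPAR plain-text format
#' @param pfm A `pfm`.
#' @param path Output file.
#' @param name Motif identifier line.
#' @export
write_pfm_jaspar <- function(pfm, path, name = "motif1") {
  lines <- c(paste0(">", name),
             vapply(DNA_BASES, function(b) {
               sprintf("%s  [ %s ]", b,
                       paste(format(pfm$counts[b, ], trim = TRUE), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a PFM in MEME minimal motif format
#' @inheritParams write_pfm_jaspar
#' @export
write_pfm_meme <- function(pfm, path, name = "motif1") {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "Background letter frequencies", "A 0.25 C 0.25 G 0.25 T 0.25", "",
             paste("MOTIF", name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= %s E= 0",
                     pfm$width, pfm$support),
             apply(pfm$freq, 2L, function(p) paste(sprintf("%.6f", p), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Plot a sequence logo from a PFM
#'
#' Letter heights are per-column information content (2 - Shannon entropy in
#' bits) split by base frequency, drawn as stacked bars with base-standard
#' colours.  Requires ggplot2.
#'
#' @param pfm A `pfm`.
#' @return A ggplot object.
#' @export
plot_logo <- function(pfm) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort_invalid("ggplot2 is required for logo plotting")
  }
  ic <- pfm_information_content(pfm)
  df <- do.call(rbind, lapply(seq_len(pfm$width), function(j) {
    o <- order(pfm$freq[, j])
    h <- pfm$freq[o, j] * ic[j]
    data.frame(pos = j, base = rownames(pfm$freq)[o], height = h,
               bottom = cumsum(c(0, h[-4L])))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, ymin = .data$bottom,
                                   ymax = .data$bottom + .data$height,
                                   fill = .data$base)) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$pos - 0.45,
                                    xmax = .data$pos + 0.45)) +
    ggplot2::geom_text(ggplot2::aes(x = .data$pos,
                                    y = .data$bottom + .data$height / 2,
                                    label = .data$base), size = 3) +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                          G = "#F7B32B", T = "#D62839")) +
    ggplot2::labs(x = "position", y = "information (bits)") +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}
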