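# Byte-pair encoding over the DNA alphabet.
#
# Training: classic pair-merge BPE on the raw base stream (no whitespace or
# case normalisation; sequences never merge across their boundaries).
# Segmentation of new sequences uses greedy longest-match against the trained
# vocabulary; the four single bases are always members, so segmentation is
# total and lossless on A/C/G/T input.

#' Train a BPE vocabulary on a sequence corpus
#'
#' Iteratively merges the most frequent adjacent token pair (ties broken by
#' first occurrence in the pair table) until `target_size` non-special tokens
#' exist.  The resulting vocabulary has `target_size + 5` entries: the five
#' special tokens, the four single bases, and `target_size - 4` merged pieces.
#'
#' @param corpus Character vector of A/C/G/T/N sequences (N segments are
#'   skipped during training).
#' @param target_size Number of non-special tokens (default 4096).
#' @param seed Integer seed (merging itself is deterministic; the seed is
#'   recorded for provenance).
#' @return A `token_vocab` of kind `"bpe"` with a `merges` attribute.
#' @export
train_bpe_vocab <- function(corpus, target_size = 4096L, seed = 1L) {
  assert_that(length(corpus) > 0L, "corpus must be non-empty")
  assert_that(is_count(target_size) && target_size >= 4L,
              "`target_size` must be an integer >= 4")
  target_size <- as.integer(target_size)
  assert_that(all(grepl("^[ACGTN]+$", corpus)),
              "corpus alphabet must be A/C/G/T/N")

  sep <- 0L  # boundary marker between sequences and around N runs
  base_ids <- seq_along(DNA_BASES)  # A=1, C=2, G=3, T=4
  names(base_ids) <- DNA_BASES
  chunks <- unlist(strsplit(corpus, "N+"), use.names = FALSE)
  chunks <- chunks[nchar(chunks) > 0L]
  assert_that(length(chunks) > 0L, "corpus contains no A/C/G/T content")
  stream <- unlist(lapply(chunks, function(s) {
    c(base_ids[strsplit(s, "", fixed = TRUE)[[1L]]], sep)
  }), use.names = FALSE)

  piece_strings <- DNA_BASES
  merges <- character(0)
  n_pieces <- 4L
  while (n_pieces < target_size) {
    n <- length(stream)
    key_base <- n_pieces + 2L
    left <- stream[-n]
    right <- stream[-1L]
    ok <- left != sep & right != sep
    if (!any(ok)) break
    keys <- as.integer(left[ok]) * key_base + as.integer(right[ok])
    sorted <- sort.int(keys, method = "radix")
    runs <- rle(sorted)
    top <- which.max(runs$lengths)   # ties: smallest key, deterministic
    if (runs$lengths[top] < 2L) break  # nothing left worth merging
    best <- runs$values[top]
    a <- best %/% key_base
    b <- best %% key_base
    pos <- which(left == a & right == b)
    # drop overlapping occurrences (relevant when a == b, e.g. "AA" in "AAA")
    if (length(pos) > 1L) {
      keep <- logical(length(pos))
      last <- -2L
      for (i in seq_along(pos)) {
        if (pos[i] > last + 1L) { keep[i] <- TRUE; last <- pos[i] }
      }
      pos <- pos[keep]
    }
    n_pieces <- n_pieces + 1L
    piece_strings <- c(piece_strings, paste0(piece_strings[a], piece_strings[b]))
    merges <- c(merges, paste(piece_strings[a], piece_strings[b]))
    stream[pos] <- n_pieces
    stream <- stream[-(pos + 1L)]
  }
  if (n_pieces < target_size) {
    abort_invalid(sprintf(
      "corpus too small to reach %d BPE tokens: achieved %d",
      target_size, n_pieces), class = "affinitylm_bpe_exhausted")
  }
  v <- new_token_vocab(kind = "bpe", k = NA_integer_,
                       tokens = c(SPECIAL_TOKENS, piece_strings))
  attr(v, "merges") <- merges
  attr(v, "seed") <- as.integer(seed)
  v
}

# Greedy longest-match segmentation of one sequence against a BPE vocabulary.
# Pieces containing N are emitted as single "N" characters (mapped to [UNK]
# by the caller since N is not in the vocabulary).
bpe_segment <- function(sequence, vocab) {
  L <- nchar(sequence)
  max_len <- vocab$max_token_nchar
  starts <- integer(0); ends <- integer(0); tokens <- character(0)
  i <- 1L
  while (i <= L) {
    len <- min(max_len, L - i + 1L)
    while (len > 1L) {
      piece <- substr(sequence, i, i + len - 1L)
      if (exists(piece, envir = vocab$index, inherits = FALSE)) break
      len <- len - 1L
    }
    piece <- substr(sequence, i, i + len - 1L)
    starts <- c(starts, i); ends <- c(ends, i + len - 1L)
    tokens <- c(tokens, piece)
    i <- i + len
  }
  list(tokens = tokens, starts = starts, ends = ends)
}
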