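#' Token vocabularies for DNA sequences
#'
#' A `token_vocab` holds an ordered token set under one of three tokenization
#' schemes: single-base, overlapping k-mer (stride 1), or byte-pair encoding
#' (BPE).  Every vocabulary carries the five special tokens `[PAD]`, `[UNK]`,
#' `[CLS]`, `[SEP]`, `[MASK]` at fixed indices 0--4, followed by the scheme's
#' own tokens, so vocabulary sizes are 4+5 (single base), 4^k+5 (k-mer) and
#' 4096+5 (default BPE).  Token ids are 0-based throughout.
#'
#' @param k k-mer width, an integer in 1..8.
#' @return A `token_vocab` object with fields `kind`, `k`, `tokens`, `size`,
#'   and an internal token-to-id hash.
#' @examples
#' v <- build_kmer_vocab(4)
#' v$size  # 4^4 + 5
#' @export
build_kmer_vocab <- function(k) {
  assert_that(is_count(k) && k >= 1 && k <= 8,
              "`k` must be an integer in 1..8")
  k <- as.integer(k)
  kmers <- do.call(paste0, expand.grid(rep(list(DNA_BASES), k),
                                       stringsAsFactors = FALSE)[, k:1, drop = FALSE])
  kmers <- sort(kmers)  # lexicographic over A,C,G,T
  new_token_vocab(kind = if (k == 1L) "single_base" else "kmer",
                  k = k, tokens = c(SPECIAL_TOKENS, kmers))
}

#' @rdname build_kmer_vocab
#' @export
build_single_base_vocab <- function() build_kmer_vocab(1L)

new_token_vocab <- function(kind, k, tokens) {
  index <- new.env(parent = emptyenv())
  for (i in seq_along(tokens)) assign(tokens[i], i - 1L, envir = index)
  v <- structure(
    list(kind = kind, k = k, tokens = tokens, size = length(tokens),
         special_tokens = SPECIAL_TOKENS, index = index,
         max_token_nchar = max(nchar(tokens[-seq_len(5L)]))),
    class = "token_vocab"
  )
  validate_token_vocab(v)
}

validate_token_vocab <- function(v) {
  assert_that(identical(v$tokens[1:5], SPECIAL_TOKENS),
              "special tokens must occupy indices 0-4 in the fixed order")
  assert_that(!anyDuplicated(v$tokens), "tokens must be unique")
  assert_that(v$size == length(v$tokens), "size must equal token count")
  expected <- switch(v$kind,
    single_base = 4L + 5L,
    kmer = 4L^v$k + 5L,
    bpe = NA_integer_
  )
  if (!is.na(expected)) {
    assert_that(v$size == expected,
                sprintf("%s vocabulary must have %d tokens, got %d",
                        v$kind, expected, v$size))
  }
  if (v$kind == "bpe") {
    assert_that(all(DNA_BASES %in% v$tokens),
                "BPE vocabulary must contain the four single bases")
  }
  v
}

#' @export
print.token_vocab <- function(x, ...) {
  cat(sprintf("<token_vocab: %s%s, |v| = %d>\n", x$kind,
              if (x$kind == "kmer") paste0(" k=", x$k) else "", x$size))
  invisible(x)
}

token_id <- function(vocab, token) {
  id <- mget(token, envir = vocab$index, ifnotfound = list(UNK_ID))
  as.integer(unlist(id, use.names = FALSE))
}

#' Tokenize a DNA sequence
#'
#' Converts an uppercase A/C/G/T/N string into an ordered list of 0-based
#' token ids plus per-token character spans (0-based half-open offsets into
#' the source).  k-mer tokenization uses stride 1 (overlapping windows), so a
#' masked k-mer cannot be reconstructed from its neighbours' identity alone
#' only when several consecutive tokens are masked together.  Characters (or
#' k-mers / BPE pieces) containing `N` map to `[UNK]`.  No `[CLS]`/`[SEP]`
#' framing is added here; the model-side collator does that.
#'
#' @param sequence DNA string.
#' @param vocab A `token_vocab`.
#' @return A `tokenized_seq`: list with `token_ids` (integer, 0-based) and
#'   `char_spans` (two-column matrix `start`,`end`).
#' @examples
#' tokenize("AGAACG", build_kmer_vocab(4))$token_ids
#' @export
tokenize <- function(sequence, vocab) {
  check_dna(sequence)
  stopifnot(inherits(vocab, "token_vocab"))
  L <- nchar(sequence)
  if (vocab$kind %in% c("single_base", "kmer")) {
    k <- vocab$k
    assert_that(L >= k, sprintf("sequence shorter than k = %d", k))
    starts <- seq_len(L - k + 1L)
    toks <- substring(sequence, starts, starts + k - 1L)
    ids <- token_id(vocab, toks)
    spans <- cbind(start = starts - 1L, end = starts + k - 1L)
  } else {
    pieces <- bpe_segment(sequence, vocab)
    ids <- token_id(vocab, pieces$tokens)
    spans <- cbind(start = pieces$starts - 1L, end = pieces$ends)
  }
  structure(list(token_ids = ids, char_spans = spans, source = sequence),
            class = "tokenized_seq")
}

#' Reconstruct a sequence from its tokenization
#'
#' Inverse of [tokenize()]: exact for single-base and BPE tokenizations of
#' A/C/G/T input; for stride-1 k-mers the sequence is rebuilt from the first
#' token plus the last character of each subsequent token.
#'
#' @param tokenized A `tokenized_seq`.
#' @param vocab The vocabulary used to produce it.
#' @return The DNA string.
#' @export
detokenize <- function(tokenized, vocab) {
  stopifnot(inherits(tokenized, "tokenized_seq"))
  toks <- vocab$tokens[tokenized$token_ids + 1L]
  toks <- toks[!toks %in% SPECIAL_TOKENS]
  if (vocab$kind %in% c("kmer") && vocab$k > 1L) {
    paste0(toks[1L], paste(substring(toks[-1L], vocab$k, vocab$k), collapse = ""))
  } else {
    paste(toks, collapse = "")
  }
}

#' Write / read a vocabulary as plain text
#'
#' One token per line; the line number (0-based) is the token id.  The loader
#' re-validates all vocabulary invariants.
#'
#' @param vocab A `token_vocab`.
#' @param path File path.
#' @export
write_vocab <- function(vocab, path) {
  writeLines(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocab
#' @param kind Scheme of the stored vocabulary (`"bpe"` unless the file is a
#'   k-mer table); external BPE vocabularies (e.g. published by other DNA
#'   language models) are accepted this way.
#' @export
read_vocab <- function(path, kind = c("bpe", "single_base", "kmer")) {
  kind <- match.arg(kind)
  tokens <- readLines(path)
  k <- if (kind == "single_base") 1L
       else if (kind == "kmer") nchar(tokens[6L])
       else NA_integer_
  new_token_vocab(kind = kind, k = k, tokens = tokens)
}
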