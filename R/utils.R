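#' @keywords internal
#' @useDynLib affinitylm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

SPECIAL_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")

# Fixed special-token ids (0-based), stable across every vocabulary so that
# adapters and heads can be moved between checkpoints that share a config.
PAD_ID <- 0L
UNK_ID <- 1L
CLS_ID <- 2L
SEP_ID <- 3L
MASK_ID <- 4L

abort_invalid <- function(msg, class = "affinitylm_invalid_argument") {
  stop(errorCondition(msg, class = c(class, "affinitylm_error")))
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort_invalid(msg)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x)
}

#' Derive a per-stage random seed from one master seed
#'
#' All pipeline randomness funnels through a single `--seed`; each stage uses a
#' seed derived deterministically from the master seed and the stage name, so
#' adding a stage never perturbs the draws of another.
#'
#' @param seed Master integer seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  assert_that(is_count(seed), "`seed` must be a single integer")
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(stage)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Validate a DNA sequence string (uppercase A/C/G/T/N)
check_dna <- function(sequence, allow_n = TRUE) {
  assert_that(is.character(sequence) && length(sequence) == 1L,
              "`sequence` must be a single character string")
  assert_that(nchar(sequence) > 0L, "empty sequence")
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  assert_that(grepl(pat, sequence),
              "sequence must be uppercase A/C/G/T (and N where allowed)")
  invisible(sequence)
}
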