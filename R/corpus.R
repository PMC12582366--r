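# Pretraining corpus construction from open-chromatin peak intervals.
#
# Peaks come from BED3+/narrowPeak files (0-based half-open intervals, as
# ATAC-seq pipelines emit them); sequences come from an indexed FASTA.  The
# corpus feeds the masked-language-model pretraining stage.

#' Read peak intervals from a BED/narrowPeak file
#'
#' @param path Tab-separated BED3+ or narrowPeak file (no header).
#' @return A `GRanges` with 0-based half-open input coordinates converted to
#'   the 1-based closed convention `GenomicRanges` uses; a `source_id`
#'   metadata column records `file:line`.
#' @export
read_peaks <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  assert_that(ncol(tab) >= 3L, "BED file needs at least 3 columns")
  gr <- GenomicRanges::GRanges(
    seqnames = tab[[1L]],
    ranges = IRanges::IRanges(start = tab[[2L]] + 1L, end = tab[[3L]])
  )
  S4Vectors::mcols(gr)$source_id <- paste0(basename(path), ":", seq_len(nrow(tab)))
  gr
}

#' Extract peak sequences into a pretraining corpus
#'
#' Intervals longer than `max_length` are centre-cropped to `max_length`
#' (keeping one sequence per peak); sequences shorter than `min_length`, with
#' an N fraction above `max_n_fraction`, or containing any residual N are
#' dropped.  Coordinates are interpreted as BED 0-based half-open when
#' `peaks` is a data frame / file; a `GRanges` is used as-is.
#'
#' @param peaks A `GRanges` (e.g. from [read_peaks()]) or a data frame with
#'   columns chrom/start/end in BED convention.
#' @param reference A named `DNAStringSet` (or path to a FASTA file).
#' @param max_length,min_length Length window in bp (defaults 512 / 20).
#' @param max_n_fraction Peaks whose sequence exceeds this N fraction are
#'   dropped before the strict no-N filter.
#' @return A `pretrain_corpus`: list with `sequences` (character),
#'   `source_id` (per surviving sequence), `max_length`, and `report`
#'   (counts of inputs, outputs and per-reason drops).
#' @export
extract_peak_sequences <- function(peaks, reference, max_length = 512L,
                                   min_length = 20L, max_n_fraction = 0.1) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  if (is.data.frame(peaks)) {
    peaks <- GenomicRanges::GRanges(
      seqnames = peaks[[1L]],
      ranges = IRanges::IRanges(start = peaks[[2L]] + 1L, end = peaks[[3L]])
    )
  }
  n_in <- length(peaks)
  assert_that(n_in > 0L, "no peaks supplied")
  src <- S4Vectors::mcols(peaks)$source_id
  if (is.null(src)) src <- paste0("peak:", seq_len(n_in))

  chroms <- as.character(GenomicRanges::seqnames(peaks))
  known <- chroms %in% names(reference)
  n_missing <- sum(!known)
  if (n_missing > 0L) {
    warning(sprintf("%d peak(s) on chromosomes absent from the reference; skipped",
                    n_missing))
  }
  sequences <- character(0)
  keep_src <- character(0)
  drops <- c(missing_chrom = n_missing, too_short = 0L,
             n_fraction = 0L, residual_n = 0L)
  for (i in which(known)) {
    st <- GenomicRanges::start(peaks)[i]
    en <- GenomicRanges::end(peaks)[i]
    chrom_len <- Biostrings::width(reference[chroms[i]])
    en <- min(en, chrom_len)
    len <- en - st + 1L
    if (len > max_length) {  # centre-crop, keeping one sequence per peak
      off <- (len - max_length) %/% 2L
      st <- st + off
      en <- st + max_length - 1L
    }
    if (en - st + 1L < min_length) { drops["too_short"] <- drops["too_short"] + 1L; next }
    s <- as.character(Biostrings::subseq(reference[[chroms[i]]], st, en))
    n_frac <- lengths(regmatches(s, gregexpr("N", s))) / nchar(s)
    if (n_frac > max_n_fraction) { drops["n_fraction"] <- drops["n_fraction"] + 1L; next }
    if (grepl("N", s)) { drops["residual_n"] <- drops["residual_n"] + 1L; next }
    sequences <- c(sequences, s)
    keep_src <- c(keep_src, src[i])
  }
  structure(
    list(sequences = sequences, source_id = keep_src,
         max_length = as.integer(max_length),
         report = list(n_peaks = n_in, n_out = length(sequences),
                       drops = as.list(drops))),
    class = "pretrain_corpus"
  )
}

#' @export
print.pretrain_corpus <- function(x, ...) {
  cat(sprintf("<pretrain_corpus: %d sequences (from %d peaks), max length %d bp>\n",
              length(x$sequences), x$report$n_peaks, x$max_length))
  invisible(x)
}

#' Random-slice augmentation for a pretraining batch
#'
#' Draws one length ratio r ~ U(0.1, 1.0) per batch and cuts every sequence
#' to a contiguous substring of length `max(min_length, floor(r * L))` at a
#' uniformly random start, teaching the model to handle variable lengths.
#' Sequences already at or below the cut length pass through unchanged.
#'
#' @param batch Character vector of sequences.
#' @param min_length Lower bound on the sliced length (default 10 bp).
#' @param ratio Override the random ratio (used in tests); `NULL` draws it.
#' @param per_sequence If `TRUE`, draw an independent ratio per sequence.
#' @return Character vector of slices, same length as `batch`.
#' @export
random_slice <- function(batch, min_length = 10L, ratio = NULL,
                         per_sequence = FALSE) {
  assert_that(length(batch) > 0L, "batch must be non-empty")
  n <- length(batch)
  r <- if (!is.null(ratio)) rep_len(ratio, if (per_sequence) n else 1L)
       else stats::runif(if (per_sequence) n else 1L, 0.1, 1.0)
  if (!per_sequence) r <- rep_len(r, n)
  L <- nchar(batch)
  cut <- pmax(pmin(min_length, L), pmin(L, floor(r * L)))
  start <- floor(stats::runif(n) * (L - cut)) + 1L
  substring(batch, start, start + cut - 1L)
}

#' Write / read a corpus as one-sequence-per-line gzipped text with a JSON report
#'
#' @param corpus A `pretrain_corpus`.
#' @param path Output path (".gz" appended text file); the report is written
#'   alongside as `<path>.report.json`.
#' @export
write_corpus <- function(corpus, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(corpus$sequences, con)
  jsonlite::write_json(corpus$report, paste0(path, ".report.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  seqs <- readLines(con)
  structure(list(sequences = seqs, source_id = NULL,
                 max_length = max(nchar(seqs)),
                 report = list(n_peaks = NA, n_out = length(seqs),
                               drops = list())),
            class = "pretrain_corpus")
}
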