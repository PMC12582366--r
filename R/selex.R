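# HT-SELEX protocol layer: per-cycle read counting, fold-enrichment relative
# affinity estimation, and the affinity-binned construction of disjoint
# fine-tune / validation / hold-out splits.

#' Count reads of one SELEX cycle
#'
#' Exact multiset counts over a FASTA/FASTQ file (or an in-memory character
#' vector).  Reads containing N are dropped and reported.
#'
#' @param reads Path to a FASTA or FASTQ file, or a character vector of reads.
#' @param cycle_index Selection-cycle index (0 = initial library).
#' @param format `"auto"` sniffs FASTQ (`@`) vs FASTA (`>`).
#' @return A `cycle_pool`: list with `cycle_index`, `counts` (named integer
#'   vector), `total`, and `n_dropped`.
#' @export
count_pool <- function(reads, cycle_index = 0L, format = "auto") {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    if (format == "auto") {
      first <- readLines(reads, n = 1L)
      format <- if (startsWith(first, "@")) "fastq" else "fasta"
    }
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = format))
  }
  assert_that(length(reads) > 0L, "empty read set")
  has_n <- grepl("N", reads, fixed = TRUE)
  n_dropped <- sum(has_n)
  reads <- reads[!has_n]
  assert_that(length(reads) > 0L, "all reads degenerate (contain N)")
  tab <- table(reads)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(list(cycle_index = as.integer(cycle_index), counts = counts,
                 total = sum(counts), n_dropped = n_dropped),
            class = "cycle_pool")
}

#' @export
print.cycle_pool <- function(x, ...) {
  cat(sprintf("<cycle_pool: cycle %d, %d reads, %d unique (%d N-dropped)>\n",
              x$cycle_index, x$total, length(x$counts), x$n_dropped))
  invisible(x)
}

#' Estimate relative binding affinity by fold enrichment
#'
#' For every sequence s observed in the later cycle, the pseudocounted
#' frequency ratio
#' `[(n_later(s) + pc) / total_later] / [(n_earlier(s) + pc) / total_earlier]`
#' is computed and normalised by its maximum, giving relative affinities in
#' (0, 1].
#'
#' @param earlier,later `cycle_pool`s with increasing cycle indices.
#' @param pseudocount Added to both counts (default 0.5).
#' @return An `affinity_dataset` (provenance `"selex"`) over the later
#'   cycle's unique sequences.
#' @export
estimate_relative_affinity <- function(earlier, later, pseudocount = 0.5) {
  stopifnot(inherits(earlier, "cycle_pool"), inherits(later, "cycle_pool"))
  assert_that(later$cycle_index > earlier$cycle_index,
              "`later` must come from a later selection cycle")
  assert_that(earlier$total > 0L && later$total > 0L, "zero-total pool")
  seqs <- names(later$counts)
  n_later <- as.numeric(later$counts)
  n_earlier <- as.numeric(earlier$counts[seqs])
  n_earlier[is.na(n_earlier)] <- 0
  enrich <- ((n_later + pseudocount) / later$total) /
            ((n_earlier + pseudocount) / earlier$total)
  affinity_dataset(seqs, enrich / max(enrich), provenance = "selex")
}

#' Affinity bin edges
#'
#' `Nsub` half-open bins tiling `[vmin, vmax]`, the last bin closed:
#' `[vmin, vmin+vbin), ..., [vmin+(Nsub-1)*vbin, vmax]`.
#'
#' @param vmin,vmax Affinity bounds (`vmax > vmin`).
#' @param n_bins Nsub.
#' @return A `binning_spec` with `edges` (length `n_bins + 1`) and `vbin`.
#' @export
binning_spec <- function(vmin, vmax, n_bins) {
  assert_that(vmax > vmin,
              "degenerate affinity range: vmax must exceed vmin")
  assert_that(is_count(n_bins) && n_bins >= 1L, "invalid bin count")
  vbin <- (vmax - vmin) / n_bins
  structure(list(n_bins = as.integer(n_bins), vmin = vmin, vmax = vmax,
                 vbin = vbin, edges = vmin + vbin * (0:n_bins)),
            class = "binning_spec")
}

# Bin index for each value: half-open bins, last bin closed at vmax.
bin_index <- function(values, spec) {
  i <- findInterval(values, spec$edges, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), spec$n_bins)
}

# One binned sampling pass: one random record per bin; empty bins backfilled
# from the nearest non-empty bin (ties toward the lower bin) so the pass
# always returns exactly n_bins records.
sample_one_pass <- function(values, avail_idx, n_bins) {
  spec <- binning_spec(min(values[avail_idx]), max(values[avail_idx]), n_bins)
  bins <- bin_index(values[avail_idx], spec)
  by_bin <- split(avail_idx, factor(bins, levels = seq_len(n_bins)))
  picked <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    pool <- by_bin[[b]]
    if (length(pool) == 0L) {
      for (off in seq_len(n_bins)) {      # nearest non-empty; lower bin first
        for (cand in c(b - off, b + off)) {
          if (cand >= 1L && cand <= n_bins && length(by_bin[[cand]]) > 0L) {
            pool <- by_bin[[cand]]; b_src <- cand; break
          }
        }
        if (length(pool) > 0L) break
      }
    } else b_src <- b
    stopifnot(length(pool) > 0L)
    take <- pool[sample.int(length(pool), 1L)]
    by_bin[[b_src]] <- setdiff(by_bin[[b_src]], take)
    picked[b] <- take
  }
  picked
}

#' Binned fine-tune / validation / hold-out sampling
#'
#' Three sampling passes without replacement: pass 1 draws one record from
#' each of `N` affinity bins over the full data (the fine-tuning set); passes
#' 2 and 3 draw from `N/10` bins recomputed over the remaining records (the
#' validation and hold-out test sets).  Records picked in one pass are
#' removed before the next, so the splits are pairwise disjoint with exact
#' sizes `N`, `N/10`, `N/10`.
#'
#' @param data An `affinity_dataset`.
#' @param N Fine-tuning set size; divisible by 10.
#' @param seed Integer seed.
#' @return A `split_result`: list of `finetune_idx`, `valid_idx`, `test_idx`
#'   (1-based indices into `data`).
#' @export
bin_and_sample <- function(data, N, seed = 1L) {
  stopifnot(inherits(data, "affinity_dataset"))
  assert_that(is_count(N) && N %% 10L == 0L, "`N` must be divisible by 10")
  need <- N + 2L * (N %/% 10L)
  if (data$N < need) {
    abort_invalid(sprintf(
      "insufficient records: need %d (N + 2*N/10), have %d (short by %d)",
      need, data$N, need - data$N), class = "affinitylm_insufficient")
  }
  v <- data$affinities
  assert_that(max(v) > min(v),
              "degenerate affinity range: all affinities identical (vbin = 0)")
  with_seed(derive_seed(seed, "bin_and_sample"), {
    remaining <- seq_len(data$N)
    ft <- sample_one_pass(v, remaining, N)
    remaining <- setdiff(remaining, ft)
    va <- sample_one_pass(v, remaining, N %/% 10L)
    remaining <- setdiff(remaining, va)
    te <- sample_one_pass(v, remaining, N %/% 10L)
    structure(list(finetune_idx = ft, valid_idx = va, test_idx = te),
              class = "split_result")
  })
}

#' Manifest pairing fine-tuned checkpoints with external test sets
#'
#' Declares, per evaluation, which metric applies: PCC for continuous
#' affinity tables (hold-out, cross-experiment, cross-platform), AUROC for
#' binary in-vivo tables.
#'
#' @param finetuned_on Identifier of the fine-tuning dataset/checkpoint.
#' @param test_sets Character vector of test-table identifiers.
#' @param kind `"cross_experiment"`, `"cross_platform"`, or `"in_vivo"`.
#' @param label_type `"affinity"` (continuous, PCC) or `"binary"` (AUROC);
#'   recycled across `test_sets`.
#' @return Data frame with one row per evaluation.
#' @export
build_cross_test_manifest <- function(finetuned_on, test_sets,
                                      kind = c("cross_experiment",
                                               "cross_platform", "in_vivo"),
                                      label_type = NULL) {
  kind <- match.arg(kind)
  if (is.null(label_type)) {
    label_type <- if (kind == "in_vivo") "binary" else "affinity"
  }
  label_type <- rep_len(label_type, length(test_sets))
  metric <- ifelse(label_type == "affinity", "pcc", "auroc")
  if (kind == "in_vivo" && any(label_type != "binary")) {
    abort_invalid("in_vivo test sets are binary-labelled; PCC does not apply")
  }
  if (kind != "in_vivo" && any(label_type == "binary")) {
    abort_invalid(sprintf("%s test sets carry continuous affinities; AUROC does not apply",
                          kind))
  }
  data.frame(finetuned_on = finetuned_on, test_set = test_sets, kind = kind,
             label_type = label_type, metric = metric,
             stringsAsFactors = FALSE)
}
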