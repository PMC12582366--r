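# LoRA + affinity-head supervised fine-tuning.
#
# The pretrained backbone is frozen; rank-12 adapters on the query/key/value
# projections and a fresh affinity head are trained to minimise mean squared
# error against min-max-scaled affinities, with early stopping on a held-out
# validation split.

#' Construct an affinity dataset
#'
#' @param sequences Character vector of DNA sequences.
#' @param affinities Numeric vector, same length, all finite.
#' @param provenance One of `"pbm"`, `"selex"`, `"synthetic"`.
#' @return An `affinity_dataset` with fields `sequences`, `affinities`, `N`.
#' @export
affinity_dataset <- function(sequences, affinities,
                             provenance = c("synthetic", "pbm", "selex")) {
  provenance <- match.arg(provenance)
  assert_that(length(sequences) == length(affinities),
              "sequences and affinities must have equal length")
  assert_that(all(is.finite(affinities)), "affinities must be finite")
  structure(list(sequences = as.character(sequences),
                 affinities = as.numeric(affinities),
                 N = length(sequences), provenance = provenance),
            class = "affinity_dataset")
}

#' @export
print.affinity_dataset <- function(x, ...) {
  cat(sprintf("<affinity_dataset: %d sequences (%s), affinity range [%.3g, %.3g]>\n",
              x$N, x$provenance, min(x$affinities), max(x$affinities)))
  invisible(x)
}

#' Read / write two-column (sequence, affinity) TSV tables
#'
#' The on-disk format of PBM intensity tables and SELEX-derived relative
#' affinities: tab-separated, optional header, sequence then numeric value.
#' Binary-label tables (second column 0/1) use the same layout.
#'
#' @param path TSV path.
#' @param provenance Stored provenance tag.
#' @return An `affinity_dataset`.
#' @export
read_affinity_tsv <- function(path, provenance = "synthetic") {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  header <- is.na(suppressWarnings(as.numeric(first[2L])))
  tab <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE)
  affinity_dataset(tab[[1L]], tab[[2L]], provenance = provenance)
}

#' @rdname read_affinity_tsv
#' @param data An `affinity_dataset`.
#' @export
write_affinity_tsv <- function(data, path) {
  utils::write.table(
    data.frame(sequence = data$sequences, affinity = data$affinities),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reserve a random validation split
#'
#' @param data An `affinity_dataset`.
#' @param fraction Validation fraction (default 0.10); `round(fraction * N)`
#'   records are reserved.
#' @param seed Integer seed.
#' @return List with `train` and `valid` `affinity_dataset`s and the
#'   validation indices.
#' @export
split_validation <- function(data, fraction = 0.10, seed = 1L) {
  assert_that(fraction > 0 && fraction < 1, "`fraction` must be in (0, 1)")
  assert_that(data$N >= 10L, "need at least 10 records to split")
  n_valid <- round(fraction * data$N)
  assert_that(n_valid >= 1L, "validation split would be empty")
  idx <- with_seed(derive_seed(seed, "split_validation"),
                   sample.int(data$N, n_valid))
  subset_ds <- function(i) affinity_dataset(data$sequences[i],
                                            data$affinities[i],
                                            data$provenance)
  list(train = subset_ds(setdiff(seq_len(data$N), idx)),
       valid = subset_ds(idx), valid_idx = sort(idx))
}

#' Mean squared error
#' @param predictions,targets Equal-length numeric vectors.
#' @return `(1/N) * sum((predictions - targets)^2)`.
#' @export
mse_loss <- function(predictions, targets) {
  assert_that(length(predictions) == length(targets) && length(targets) >= 1L,
              "prediction/target length mismatch")
  mean((predictions - targets)^2)
}

#' Early stopping policy
#'
#' @param max_epochs Hard epoch cap (default 300).
#' @param tolerance Epochs to continue past the best validation loss
#'   (default 10).
#' @return An `early_stop_policy`.
#' @export
early_stop_policy <- function(max_epochs = 300L, tolerance = 10L) {
  assert_that(tolerance < max_epochs, "tolerance must be below max_epochs")
  structure(list(max_epochs = as.integer(max_epochs),
                 tolerance = as.integer(tolerance),
                 monitored = "validation loss"),
            class = "early_stop_policy")
}

#' Early-stopping decision on a validation-loss trace
#'
#' Pure helper implementing the halt rule the fine-tuning loop uses: training
#' stops after the epoch that lies `tolerance` epochs past the best
#' validation loss (ties keep the earliest best).
#'
#' @param valid_losses Numeric vector, one entry per completed epoch.
#' @param tolerance Patience in epochs.
#' @return List with `best_epoch`, `stop_epoch` (`NA` if the trace ends
#'   before the rule fires), and `should_stop` for the trace as given.
#' @export
early_stop_epoch <- function(valid_losses, tolerance = 10L) {
  n <- length(valid_losses)
  best <- 1L
  stop_epoch <- NA_integer_
  for (e in seq_len(n)) {
    if (valid_losses[e] < valid_losses[best]) best <- e
    if (e - best >= tolerance) { stop_epoch <- e; break }
  }
  list(best_epoch = best, stop_epoch = stop_epoch,
       should_stop = !is.na(stop_epoch))
}

# Evaluate scaled-space validation loss without touching optimizer state.
eval_valid_loss <- function(params, ids_list, y_scaled, batch_size = 64L) {
  n <- length(ids_list)
  preds <- numeric(n)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    coll <- collate_ids(ids_list[chunk], params$config$max_tokens, truncate = TRUE)
    fwd <- model_forward(params, coll$ids, coll$mask)
    preds[chunk] <- affinity_head_forward(params, fwd$H, nrow(coll$ids),
                                          ncol(coll$ids), coll$lengths)$yhat
  }
  mse_loss(preds, y_scaled)
}

# Standardisation statistics for the pooled head input, computed once over
# the fine-tuning set with the frozen backbone.  Centring removes the large
# sequence-independent component of the pooled representation so the head
# trains on an O(1) signal.
compute_head_norm <- function(params, ids_list, batch_size = 64L) {
  params$head_norm <- NULL
  n <- length(ids_list)
  hc <- matrix(0, n, params$config$hidden_width)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    coll <- collate_ids(ids_list[chunk], params$config$max_tokens, truncate = TRUE)
    fwd <- model_forward(params, coll$ids, coll$mask)
    hc[chunk, ] <- affinity_head_forward(params, fwd$H, nrow(coll$ids),
                                         ncol(coll$ids), coll$lengths)$hc
  }
  s <- apply(hc, 2L, stats::sd)
  # floor relative to the typical dimension so near-constant dimensions are
  # not amplified into the adapters' gradients
  list(center = colMeans(hc),
       scale = pmax(s, 0.1 * stats::median(s) + 1e-12))
}

#' Fine-tune a pretrained model for affinity regression
#'
#' Freezes the backbone, attaches LoRA adapters (unless `full_finetune`),
#' min-max scales the affinities to `[0, 1]` (scaler stored on the model for
#' prediction-time inversion), reserves a 10% validation split, and trains
#' adapters + affinity head with AdamW at a constant learning rate until the
#' early-stopping rule fires.  The best-validation-epoch weights are
#' returned.
#'
#' @param pretrained An `affinity_lm` (the pretrained backbone, token head
#'   optional).
#' @param data An `affinity_dataset`.
#' @param vocab The `token_vocab` matching the model.
#' @param lora A `lora_config`; ignored under `full_finetune`.
#' @param stop An `early_stop_policy`.
#' @param lr Constant learning rate (default 1e-4).
#' @param batch_size Sequences per step (default 128).
#' @param seed Master seed (split, adapter init, batch order).
#' @param valid_fraction Validation fraction (default 0.10).
#' @param full_finetune Ablation switch: update all parameters instead of
#'   adapters only (used by with/without-pretraining comparisons).
#' @param clip_norm Global L2 gradient-norm clip per step (default 1.0;
#'   `Inf` disables).
#' @param pooling Head input: the final `[CLS]` hidden vector (`"cls"`,
#'   default) or the mean over real token positions (`"mean"`).  Either way
#'   the pooled vector is standardised with train-set statistics frozen at
#'   fine-tuning start and stored on the checkpoint.
#' @return List with `params` (best-epoch model, scaler attached), `trace`
#'   (epoch/train_loss/valid_loss), `best_epoch`, and `stopped_epoch`.
#' @export
finetune <- function(pretrained, data, vocab, lora = lora_config(),
                     stop = early_stop_policy(), lr = 1e-4, batch_size = 128L,
                     seed = 1L, valid_fraction = 0.10, full_finetune = FALSE,
                     pooling = c("cls", "mean"), clip_norm = 1.0) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(pretrained, "affinity_lm"),
            inherits(data, "affinity_dataset"))
  rng <- range(data$affinities)
  assert_that(rng[2] > rng[1], "affinities are constant; nothing to regress")
  scaler <- list(min = rng[1], max = rng[2])
  y_all <- (data$affinities - scaler$min) / (scaler$max - scaler$min)
  scaled <- affinity_dataset(data$sequences, y_all, data$provenance)
  sp <- split_validation(scaled, fraction = valid_fraction, seed = seed)

  params <- pretrained
  if (!full_finetune) {
    params <- attach_lora(params, lora, seed = seed)
  }
  params$scaler <- scaler
  params$pooling <- pooling
  train_ids <- lapply(sp$train$sequences, function(s) tokenize(s, vocab)$token_ids)
  valid_ids <- lapply(sp$valid$sequences, function(s) tokenize(s, vocab)$token_ids)
  y_train <- sp$train$affinities
  y_valid <- sp$valid$affinities
  params$head_norm <- compute_head_norm(params, train_ids,
                                        batch_size = batch_size)

  state <- adamw_init(params, trainable_weights(params))
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      valid_loss = numeric(0))
  best <- list(epoch = 0L, loss = Inf, weights = params$weights)
  n <- length(train_ids)
  train_lens <- lengths(train_ids)

  with_seed(derive_seed(seed, "finetune"), {
    for (epoch in seq_len(stop$max_epochs)) {
      # fresh shuffle every epoch, then group similar lengths so padding
      # stays small on ragged inputs (random tie-break within a length)
      ord <- sample.int(n)
      ord <- ord[order(train_lens[ord])]
      chunks <- split(ord, ceiling(seq_len(n) / batch_size))
      chunk_order <- sample.int(length(chunks))
      epoch_loss <- 0
      for (ci in chunk_order) {
        idx <- chunks[[ci]]
        coll <- collate_ids(train_ids[idx], params$config$max_tokens,
                            truncate = TRUE)
        B <- nrow(coll$ids); T <- ncol(coll$ids)
        fwd <- model_forward(params, coll$ids, coll$mask, need_cache = TRUE)
        head <- affinity_head_forward(params, fwd$H, B, T, coll$lengths)
        loss <- mse_loss(head$yhat, y_train[idx])
        epoch_loss <- epoch_loss + loss * length(idx)
        ab <- affinity_head_backward(params, head,
                                     2 * (head$yhat - y_train[idx]) / B, B, T)
        grads <- model_backward(params, fwd$cache, ab$dH)
        for (g in names(ab$grads)) grads[[g]] <- ab$grads[[g]]
        grads <- clip_grad_norm(grads, clip_norm)
        res <- adamw_step(params, grads, state, lr)
        params <- res$params; state <- res$state
      }
      vloss <- eval_valid_loss(params, valid_ids, y_valid)
      if (!is.finite(vloss)) {
        abort_invalid(sprintf("validation loss non-finite at epoch %d", epoch),
                      class = "affinitylm_diverged")
      }
      trace <- rbind(trace, data.frame(epoch = epoch,
                                       train_loss = epoch_loss / n,
                                       valid_loss = vloss))
      if (vloss < best$loss) {
        best <- list(epoch = epoch, loss = vloss, weights = params$weights)
      }
      if (epoch - best$epoch >= stop$tolerance) break
    }
  })
  params$weights <- best$weights
  list(params = params, trace = trace, best_epoch = best$epoch,
       best_valid_loss = best$loss, stopped_epoch = nrow(trace))
}
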