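# Span-masked language-model pretraining.
#
# k-mer tokenizations use consecutive-span masking (default span length 10)
# because a single masked stride-1 k-mer is trivially recoverable from its
# overlapping neighbours; single-base and BPE tokenizations may use
# independent single-token masking.  Masked inputs are always replaced by
# [MASK] (no 80/10/10 corruption split).

#' Masking policy
#'
#' @param mode `"span"` (consecutive tokens) or `"single"` (independent).
#' @param span_length Tokens per masked span (default 10).
#' @param mask_proportion Fraction of tokens masked per sequence (default 0.15).
#' @return A `masking_policy`.
#' @export
masking_policy <- function(mode = c("span", "single"), span_length = 10L,
                           mask_proportion = 0.15) {
  mode <- match.arg(mode)
  assert_that(mask_proportion > 0 && mask_proportion < 1,
              "mask_proportion must be in (0, 1)")
  assert_that(is_count(span_length) && span_length >= 1L,
              "span_length must be a positive integer")
  structure(list(mode = mode, span_length = as.integer(span_length),
                 mask_proportion = mask_proportion),
            class = "masking_policy")
}

#' Apply masking to one tokenized sequence
#'
#' Span mode masks `round(mask_proportion * L / span_length)` non-overlapping
#' spans of `span_length` tokens placed uniformly at random (rejection
#' sampling); when that count rounds to zero, a single truncated span of
#' `ceiling(mask_proportion * L)` tokens keeps M >= 1.  Single mode masks
#' each token independently with probability `mask_proportion`, redrawing if
#' nothing was selected.
#'
#' @param tokens A `tokenized_seq` or an integer vector of 0-based token ids.
#' @param policy A `masking_policy`.
#' @return A `masked_seq`: list with `input_ids` (masked), `mask_positions`
#'   (1-based), `target_ids`, and `M`.
#' @export
apply_masking <- function(tokens, policy) {
  ids <- if (inherits(tokens, "tokenized_seq")) tokens$token_ids else as.integer(tokens)
  L <- length(ids)
  assert_that(L >= 2L, "need at least 2 tokens to mask")
  p <- policy$mask_proportion
  if (policy$mode == "single") {
    repeat {
      sel <- which(stats::runif(L) < p)
      if (length(sel) > 0L) break
    }
  } else {
    lmask <- policy$span_length
    if (lmask > L) {
      warning(sprintf("span_length %d exceeds sequence length %d; one full-length span",
                      lmask, L))
      sel <- seq_len(L)
    } else {
      n_spans <- round(p * L / lmask)
      if (n_spans < 1L) {
        len <- min(L, as.integer(ceiling(p * L)))
        start <- sample.int(L - len + 1L, 1L)
        sel <- start:(start + len - 1L)
      } else {
        max_start <- L - lmask + 1L
        starts <- integer(0)
        tries <- 0L
        while (length(starts) < n_spans) {
          cand <- sample.int(max_start, 1L)
          if (!any(abs(cand - starts) < lmask)) starts <- c(starts, cand)
          tries <- tries + 1L
          if (tries > 1000L * n_spans) {  # dense masking; fall back to grid
            starts <- seq(1L, by = lmask, length.out = n_spans)
            break
          }
        }
        sel <- sort(unique(unlist(lapply(starts, function(s) s:(s + lmask - 1L)))))
      }
    }
  }
  input_ids <- ids
  input_ids[sel] <- MASK_ID
  structure(list(input_ids = input_ids, mask_positions = sel,
                 target_ids = ids[sel], M = length(sel)),
            class = "masked_seq")
}

#' Masked-token cross-entropy loss
#'
#' Mean over masked positions of the negative log softmax probability of the
#' true token: `-(1/M) * sum_i log softmax(That_i)[v(t_i)]`.
#'
#' @param logits M x |v| matrix of token-prediction scores.
#' @param target_ids Integer vector of 0-based true token ids, length M.
#' @return Scalar loss.
#' @examples
#' masked_lm_loss(matrix(0, 2, 9), c(5L, 6L))  # == log(9)
#' @export
masked_lm_loss <- function(logits, target_ids) {
  logits <- as.matrix(logits)
  M <- nrow(logits)
  if (M == 0L || length(target_ids) == 0L) {
    abort_invalid("no masked positions: loss undefined",
                  class = "affinitylm_empty_mask")
  }
  assert_that(length(target_ids) == M, "one target per logit row required")
  mx <- logits[cbind(seq_len(M), max.col(logits, ties.method = "first"))]
  lse <- mx + log(rowSums(exp(logits - mx)))
  ll <- logits[cbind(seq_len(M), as.integer(target_ids) + 1L)]
  mean(lse - ll)
}

#' Pretrain the encoder with masked language modelling
#'
#' Minimises the masked-token cross-entropy over the corpus.  Each step
#' samples a batch, applies the per-batch random-slice augmentation, masks,
#' and takes one AdamW step under the warm-up + cosine schedule.  Gradient
#' flows to the backbone and token head only.
#'
#' @param corpus A `pretrain_corpus` or character vector of sequences.
#' @param vocab A `token_vocab`.
#' @param config An `encoder_config` (its `vocab_size` must match `vocab`).
#' @param policy A `masking_policy`.
#' @param schedule A `train_schedule`; `total_steps` here is the actual
#'   number of optimizer steps run.
#' @param seed Master seed for initialisation, batch order and masking.
#' @param log_every Record the loss trace every this many steps.
#' @param params Optionally resume from an existing model instead of a fresh
#'   initialisation.
#' @return List with `params` (the pretrained model, token head retained),
#'   `trace` (data.frame step/lr/loss), and `diverged` flag.
#' @export
pretrain <- function(corpus, vocab, config, policy = masking_policy(),
                     schedule = train_schedule(), seed = 1L, log_every = 50L,
                     params = NULL) {
  sequences <- if (inherits(corpus, "pretrain_corpus")) corpus$sequences else corpus
  assert_that(length(sequences) > 0L, "corpus must be non-empty")
  assert_that(config$vocab_size == vocab$size,
              "config vocab_size must match the vocabulary")
  if (is.null(params)) params <- init_encoder(config, seed = seed)
  trainable <- grep("^(embed|L[0-9]+\\.|final_ln|tok\\.)", names(params$weights),
                    value = TRUE)
  state <- adamw_init(params, trainable)
  trace <- data.frame(step = integer(0), lr = numeric(0), loss = numeric(0))
  last_good <- params
  diverged <- FALSE

  with_seed(derive_seed(seed, "pretrain"), {
    for (step in seq_len(schedule$total_steps)) {
      batch_idx <- sample.int(length(sequences), schedule$batch_size,
                              replace = length(sequences) < schedule$batch_size)
      batch <- random_slice(sequences[batch_idx],
                            min_length = max(10L, vocab$k %||% 1L))
      toks <- lapply(batch, tokenize, vocab = vocab)
      masked <- lapply(toks, apply_masking, policy = policy)
      coll <- collate_ids(lapply(masked, `[[`, "input_ids"),
                          config$max_tokens, truncate = TRUE)
      T <- ncol(coll$ids)
      rows <- unlist(lapply(seq_along(masked), function(b) {
        mp <- masked[[b]]$mask_positions
        mp <- mp[mp + 1L <= coll$lengths[b] - 1L]  # survive truncation
        (b - 1L) * T + 1L + mp                      # +1 for [CLS]
      }))
      targets <- unlist(lapply(seq_along(masked), function(b) {
        mp <- masked[[b]]$mask_positions
        keep <- mp + 1L <= coll$lengths[b] - 1L
        masked[[b]]$target_ids[keep]
      }))
      fwd <- model_forward(params, coll$ids, coll$mask, need_cache = TRUE)
      logits <- token_head_forward(params, fwd$H, rows)
      loss <- masked_lm_loss(logits, targets)
      if (!is.finite(loss)) {
        warning(sprintf("loss diverged at step %d; returning last checkpoint", step))
        params <- last_good
        diverged <- TRUE
        break
      }
      M <- length(rows)
      mx <- logits[cbind(seq_len(M), max.col(logits, ties.method = "first"))]
      P <- exp(logits - (mx + log(rowSums(exp(logits - mx)))))
      hit <- cbind(seq_len(M), targets + 1L)
      dlogits <- P
      dlogits[hit] <- dlogits[hit] - 1
      dlogits <- dlogits / M
      dH <- matrix(0, nrow(fwd$H), config$hidden_width)
      dH[rows, ] <- dlogits %*% params$weights$embed
      grads <- model_backward(params, fwd$cache, dH)
      grads$embed <- grads$embed + crossprod(dlogits, fwd$H[rows, , drop = FALSE])
      grads$tok.b <- matrix(colSums(dlogits))
      lr <- schedule_lr(step, schedule)
      res <- adamw_step(params, grads, state, lr)
      params <- res$params; state <- res$state
      if (step %% log_every == 0L || step == schedule$total_steps) {
        trace <- rbind(trace, data.frame(step = step, lr = lr, loss = loss))
        last_good <- params
      }
    }
  })
  list(params = params, trace = trace, diverged = diverged)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
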