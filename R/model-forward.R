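# Forward pass of the Transformer encoder.
#
# Pre-layer-norm residual blocks with GELU feed-forwards; rotary position
# embeddings (base 10000) applied to query and key vectors only, so attention
# logits depend on relative token offsets.  Batches are padded to the longest
# member; `[PAD]` columns are masked out of every attention row.  All shapes
# are row-per-token: a batch of B sequences padded to T tokens travels as a
# (B*T) x d matrix in sequence-major order.

LN_EPS <- 1e-5

# tanh-approximation GELU (the usual Transformer variant; cheaper than the
# exact Gaussian CDF and indistinguishable at these scales)
gelu <- function(x) {
  0.5 * x * (1 + tanh(0.7978845608028654 * (x + 0.044715 * x^3)))
}
gelu_grad <- function(x) {
  u <- 0.7978845608028654 * (x + 0.044715 * x^3)
  t <- tanh(u)
  0.5 * (1 + t) + 0.5 * x * (1 - t * t) *
    0.7978845608028654 * (1 + 3 * 0.044715 * x^2)
}

ln_forward <- function(X, g, b) {
  ln_fwd_cpp(X, as.numeric(g), as.numeric(b), LN_EPS)
}

ln_backward <- function(dy, ln, g) {
  ln_bwd_cpp(dy, ln$xhat, ln$inv_sd, as.numeric(g))
}

# Rotary tables for T positions (0-based) at per-head width dh.
rope_tables <- function(T, dh, base = 10000) {
  half <- dh %/% 2L
  inv_freq <- base^(-(2 * (seq_len(half) - 1)) / dh)
  ang <- outer(0:(T - 1), inv_freq)
  idx <- rep(seq_len(half), each = 2L)
  list(cos = cos(ang)[, idx, drop = FALSE], sin = sin(ang)[, idx, drop = FALSE])
}

# x: n x dh with rows at positions pos (1-based into the tables)
rope_rotate <- function(x, tab, pos, inverse = FALSE) {
  odd <- seq(1L, ncol(x), by = 2L)
  x90 <- x
  x90[, odd] <- -x[, odd + 1L]
  x90[, odd + 1L] <- x[, odd]
  s <- tab$sin[pos, , drop = FALSE]
  if (inverse) s <- -s
  x * tab$cos[pos, , drop = FALSE] + x90 * s
}

# Collate 0-based token-id vectors: prepend [CLS], append [SEP], pad.
collate_ids <- function(ids_list, max_tokens, truncate = FALSE) {
  framed <- lapply(ids_list, function(ids) {
    ids <- c(CLS_ID, ids, SEP_ID)
    if (length(ids) > max_tokens) {
      if (!truncate) {
        abort_invalid(sprintf(
          "sequence of %d tokens exceeds max_tokens = %d (set truncate = TRUE to crop)",
          length(ids), max_tokens), class = "affinitylm_overlong")
      }
      ids <- c(ids[seq_len(max_tokens - 1L)], SEP_ID)
    }
    ids
  })
  lens <- lengths(framed)
  T <- max(lens)
  B <- length(framed)
  ids_mat <- matrix(PAD_ID, B, T)
  mask <- matrix(FALSE, B, T)
  for (b in seq_len(B)) {
    ids_mat[b, seq_len(lens[b])] <- framed[[b]]
    mask[b, seq_len(lens[b])] <- TRUE
  }
  list(ids = ids_mat, mask = mask, lengths = lens)
}

# Effective projection with optional LoRA path: Y = XW + b [+ (alpha/r) X A B]
proj_forward <- function(X, W, b, loraA = NULL, loraB = NULL, scale = 0) {
  Y <- X %*% W + rep(b, each = nrow(X))
  XA <- NULL
  if (!is.null(loraA)) {
    XA <- X %*% loraA
    Y <- Y + scale * (XA %*% loraB)
  }
  list(Y = Y, XA = XA)
}

# Full forward pass.  ids/mask as from collate_ids().  Returns the final
# hidden states plus (optionally) a cache for backprop and per-sequence
# attention arrays [layer, head, T, T].
model_forward <- function(params, ids, mask, need_cache = FALSE,
                          need_attn = FALSE) {
  cfg <- params$config
  w <- params$weights
  B <- nrow(ids); T <- ncol(ids)
  d <- cfg$hidden_width; nh <- cfg$num_heads; dh <- d %/% nh
  lora_scale <- if (!is.null(params$lora)) params$lora$alpha / params$lora$rank else 0
  lora_on <- function(l, tgt) {
    !is.null(params$lora) && tgt %in% params$lora$targets &&
      !is.null(w[[sprintf("L%d.W%s.loraA", l, substr(tgt, 1, 1))]])
  }

  flat_ids <- as.vector(t(ids))            # sequence-major
  X <- w$embed[flat_ids + 1L, , drop = FALSE]
  tab <- rope_tables(T, dh)
  valid_int <- matrix(as.integer(mask), B, T)

  cache <- if (need_cache) vector("list", cfg$num_layers)
  attn_out <- if (need_attn) {
    lapply(seq_len(B), function(b) array(0, c(cfg$num_layers, nh, T, T)))
  }

  for (l in seq_len(cfg$num_layers)) {
    p <- function(nm) w[[sprintf("L%d.%s", l, nm)]]
    ln1 <- ln_forward(X, p("ln1.g"), p("ln1.b"))
    qp <- proj_forward(ln1$y, p("Wq"), p("bq"),
                       if (lora_on(l, "query")) p("Wq.loraA"),
                       if (lora_on(l, "query")) p("Wq.loraB"), lora_scale)
    kp <- proj_forward(ln1$y, p("Wk"), p("bk"),
                       if (lora_on(l, "key")) p("Wk.loraA"),
                       if (lora_on(l, "key")) p("Wk.loraB"), lora_scale)
    vp <- proj_forward(ln1$y, p("Wv"), p("bv"),
                       if (lora_on(l, "value")) p("Wv.loraA"),
                       if (lora_on(l, "value")) p("Wv.loraB"), lora_scale)
    Q <- qp$Y; K <- kp$Y; V <- vp$Y
    Qr <- rope_all_cpp(Q, tab$cos, tab$sin, nh, T, FALSE)
    Kr <- rope_all_cpp(K, tab$cos, tab$sin, nh, T, FALSE)
    att <- attn_forward_cpp(Qr, Kr, V, valid_int, B, T, nh)
    ctx <- att$ctx
    if (need_attn) {
      for (b in seq_len(B)) {
        for (h in seq_len(nh)) {
          attn_out[[b]][l, h, , ] <- matrix(att$A[, (b - 1L) * nh + h], T, T)
        }
      }
    }
    attn_proj <- ctx %*% p("Wo") + rep(p("bo"), each = B * T)
    X2 <- X + attn_proj
    ln2 <- ln_forward(X2, p("ln2.g"), p("ln2.b"))
    Z1 <- ln2$y %*% p("W1") + rep(p("b1"), each = B * T)
    gl <- gelu_fwd_cpp(Z1)
    X3 <- X2 + gl$y %*% p("W2") + rep(p("b2"), each = B * T)
    if (need_cache) {
      cache[[l]] <- list(X_in = X, ln1 = ln1, qXA = qp$XA, kXA = kp$XA,
                         vXA = vp$XA, Q = Q, K = K, V = V, Qr = Qr, Kr = Kr,
                         A = att$A, ctx = ctx, X2 = X2, ln2 = ln2,
                         A1 = gl$y, A1g = gl$g)
    }
    X <- X3
  }
  fln <- ln_forward(X, w$final_ln.g, w$final_ln.b)
  list(H = fln$y,
       cache = if (need_cache) list(layers = cache, final_ln = fln,
                                    pre_final = X, flat_ids = flat_ids,
                                    ids = ids, mask = mask,
                                    tab = tab, B = B, T = T),
       attention = attn_out)
}

# Affinity head forward.  Pools the final hidden states ([CLS] vector by
# default, or the mean over real sequence tokens), optionally standardises
# the pooled vector with statistics frozen at fine-tuning start
# (params$head_norm), and applies a two-layer perceptron.
affinity_head_forward <- function(params, H, B, T, lengths = NULL) {
  w <- params$weights
  pooling <- params$pooling
  if (is.null(pooling)) pooling <- "cls"
  if (pooling == "cls") {
    hc <- H[(seq_len(B) - 1L) * T + 1L, , drop = FALSE]
  } else {
    assert_that(!is.null(lengths), "mean pooling needs per-sequence lengths")
    hc <- matrix(0, B, ncol(H))
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * T + 2L):((b - 1L) * T + lengths[b] - 1L)
      hc[b, ] <- colMeans(H[rows, , drop = FALSE])
    }
  }
  if (!is.null(params$head_norm)) {
    hc <- (hc - rep(params$head_norm$center, each = B)) /
      rep(params$head_norm$scale, each = B)
  }
  Z <- hc %*% w$aff.W1 + rep(w$aff.b1, each = B)
  A <- gelu(Z)
  yhat <- drop(A %*% w$aff.w2) + w$aff.b2[1L, 1L]
  list(yhat = yhat, hc = hc, Z = Z, A = A, pooling = pooling,
       lengths = lengths)
}

#' Encode sequences with the model
#'
#' Runs the full encoder and returns per-token hidden vectors and, on
#' request, every layer/head attention matrix.  `[CLS]` and `[SEP]` are added
#' here; batches are padded with `[PAD]` and masked so pad positions receive
#' zero attention mass.
#'
#' @param params An `affinity_lm`.
#' @param sequences Character vector of DNA sequences, or a list of 0-based
#'   token-id vectors.
#' @param vocab The `token_vocab` to tokenize with (ignored when `sequences`
#'   is already tokenized).
#' @param need_attn Return attention matrices (one `[layer, head, T, T]`
#'   array per sequence)?
#' @param truncate Crop overlong inputs instead of erroring.
#' @return A list with `hidden` (per-sequence matrices, one row per token
#'   including `[CLS]`/`[SEP]`, pads removed), `attention` (if requested,
#'   trimmed to the real token span), and `token_ids`.
#' @export
encode <- function(params, sequences, vocab = NULL, need_attn = FALSE,
                   truncate = FALSE) {
  ids_list <- sequences_to_ids(sequences, vocab)
  coll <- collate_ids(ids_list, params$config$max_tokens, truncate = truncate)
  fwd <- model_forward(params, coll$ids, coll$mask, need_attn = need_attn)
  B <- nrow(coll$ids); T <- ncol(coll$ids)
  hidden <- lapply(seq_len(B), function(b) {
    fwd$H[((b - 1L) * T + 1L):((b - 1L) * T + coll$lengths[b]), , drop = FALSE]
  })
  attention <- if (need_attn) {
    lapply(seq_len(B), function(b) {
      Lb <- coll$lengths[b]
      fwd$attention[[b]][, , seq_len(Lb), seq_len(Lb), drop = FALSE]
    })
  }
  list(hidden = hidden, attention = attention,
       token_ids = lapply(seq_len(B), function(b)
         coll$ids[b, seq_len(coll$lengths[b])]))
}

sequences_to_ids <- function(sequences, vocab) {
  if (is.character(sequences)) {
    assert_that(!is.null(vocab), "`vocab` is required for raw sequences")
    lapply(sequences, function(s) tokenize(s, vocab)$token_ids)
  } else if (is.list(sequences)) {
    lapply(sequences, function(x) {
      if (inherits(x, "tokenized_seq")) x$token_ids else as.integer(x)
    })
  } else {
    abort_invalid("`sequences` must be character or a list of tokenizations")
  }
}

#' Predict binding affinity for a batch of sequences
#'
#' Runs the encoder and the affinity prediction head (a two-layer perceptron
#' over the final `[CLS]` hidden vector).  If the model carries a min-max
#' affinity scaler from fine-tuning, predictions are mapped back to the
#' original affinity scale unless `rescale = FALSE`.
#'
#' @inheritParams encode
#' @param rescale Invert the stored min-max scaler (default `TRUE`).
#' @param batch_size Sequences per forward pass.
#' @return Numeric vector of predicted affinities, one per sequence.
#' @export
predict_affinity <- function(params, sequences, vocab = NULL, rescale = TRUE,
                             batch_size = 64L, truncate = FALSE) {
  assert_that(!is.null(params$weights$aff.w2), "model has no affinity head")
  ids_list <- sequences_to_ids(sequences, vocab)
  n <- length(ids_list)
  out <- numeric(n)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    coll <- collate_ids(ids_list[chunk], params$config$max_tokens,
                        truncate = truncate)
    fwd <- model_forward(params, coll$ids, coll$mask)
    out[chunk] <- affinity_head_forward(params, fwd$H, nrow(coll$ids),
                                        ncol(coll$ids), coll$lengths)$yhat
  }
  if (rescale && !is.null(params$scaler)) {
    out <- out * (params$scaler$max - params$scaler$min) + params$scaler$min
  }
  assert_that(all(is.finite(out)), "non-finite affinity prediction")
  out
}
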