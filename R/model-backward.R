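# Manual backpropagation through the encoder.
#
# Mirrors model_forward() layer by layer in reverse.  When the backbone is
# frozen (LoRA fine-tuning) the backbone weight gradients are skipped but
# activations are still backpropagated so gradients reach adapters in lower
# layers.  Correctness is pinned by a finite-difference test on a tiny
# configuration.

# dH: gradient w.r.t. the final (post layer-norm) hidden states, (B*T) x d.
# Returns a named list of gradients covering the requested weights plus
# "embed" accumulated over input-embedding rows (the tied output projection's
# contribution is added by the caller).
model_backward <- function(params, cache, dH) {
  cfg <- params$config
  w <- params$weights
  want_backbone <- !params$backbone_frozen
  B <- cache$B; T <- cache$T
  d <- cfg$hidden_width; nh <- cfg$num_heads; dh <- d %/% nh
  n <- B * T
  tab <- cache$tab
  lora_scale <- if (!is.null(params$lora)) params$lora$alpha / params$lora$rank else 0
  grads <- list()

  fb <- ln_backward(dH, cache$final_ln, w$final_ln.g)
  if (want_backbone) {
    grads$final_ln.g <- matrix(fb$dg); grads$final_ln.b <- matrix(fb$db)
  }
  dX <- fb$dx

  for (l in rev(seq_len(cfg$num_layers))) {
    cl <- cache$layers[[l]]
    nm <- function(s) sprintf("L%d.%s", l, s)
    p <- function(s) w[[nm(s)]]

    # FFN block: X3 = X2 + gelu(LN2(X2) W1 + b1) W2 + b2
    dA1 <- dX %*% t(p("W2"))
    if (want_backbone) {
      grads[[nm("W2")]] <- crossprod(cl$A1, dX)
      grads[[nm("b2")]] <- matrix(colSums(dX))
    }
    dZ1 <- dA1 * cl$A1g
    if (want_backbone) {
      grads[[nm("W1")]] <- crossprod(cl$ln2$y, dZ1)
      grads[[nm("b1")]] <- matrix(colSums(dZ1))
    }
    dy2 <- dZ1 %*% t(p("W1"))
    l2 <- ln_backward(dy2, cl$ln2, p("ln2.g"))
    if (want_backbone) {
      grads[[nm("ln2.g")]] <- matrix(l2$dg); grads[[nm("ln2.b")]] <- matrix(l2$db)
    }
    dX2 <- dX + l2$dx

    # Attention block: X2 = X_in + (heads(LN1(X_in))) Wo + bo
    dctx <- dX2 %*% t(p("Wo"))
    if (want_backbone) {
      grads[[nm("Wo")]] <- crossprod(cl$ctx, dX2)
      grads[[nm("bo")]] <- matrix(colSums(dX2))
    }
    ab <- attn_backward_cpp(dctx, cl$A, cl$Qr, cl$Kr, cl$V, B, T, nh)
    dQr <- ab$dQr; dKr <- ab$dKr; dV <- ab$dV
    dQ <- rope_all_cpp(dQr, tab$cos, tab$sin, nh, T, TRUE)
    dK <- rope_all_cpp(dKr, tab$cos, tab$sin, nh, T, TRUE)
    dy1 <- matrix(0, n, d)
    for (tgt in c("query", "key", "value")) {
      c1 <- substr(tgt, 1, 1)
      dP <- switch(tgt, query = dQ, key = dK, value = dV)
      Wn <- nm(sprintf("W%s", c1))
      if (want_backbone) {
        grads[[Wn]] <- crossprod(cl$ln1$y, dP)
        grads[[nm(sprintf("b%s", c1))]] <- matrix(colSums(dP))
      }
      dy1 <- dy1 + dP %*% t(w[[Wn]])
      An <- nm(sprintf("W%s.loraA", c1)); Bn <- nm(sprintf("W%s.loraB", c1))
      if (!is.null(w[[An]])) {
        XA <- cl[[sprintf("%sXA", c1)]]
        dPB <- dP %*% t(w[[Bn]])
        grads[[Bn]] <- lora_scale * crossprod(XA, dP)
        grads[[An]] <- lora_scale * crossprod(cl$ln1$y, dPB)
        dy1 <- dy1 + lora_scale * (dPB %*% t(w[[An]]))
      }
    }
    l1 <- ln_backward(dy1, cl$ln1, p("ln1.g"))
    if (want_backbone) {
      grads[[nm("ln1.g")]] <- matrix(l1$dg); grads[[nm("ln1.b")]] <- matrix(l1$db)
    }
    dX <- dX2 + l1$dx
  }

  if (want_backbone) {
    dE <- matrix(0, cfg$vocab_size, d)
    agg <- rowsum(dX, cache$flat_ids)
    dE[as.integer(rownames(agg)) + 1L, ] <- agg
    grads$embed <- dE
  }
  grads
}

# Gradient of the affinity head; returns head grads and dH (B*T x d, nonzero
# only at [CLS] rows).
affinity_head_backward <- function(params, head, dyhat, B, T) {
  w <- params$weights
  dyhat <- matrix(dyhat, ncol = 1L)
  dA <- dyhat %*% t(w$aff.w2)
  dZ <- dA * gelu_grad(head$Z)
  dhc <- dZ %*% t(w$aff.W1)
  if (!is.null(params$head_norm)) {
    dhc <- dhc / rep(params$head_norm$scale, each = B)
  }
  dH <- matrix(0, B * T, params$config$hidden_width)
  if (head$pooling == "cls") {
    dH[(seq_len(B) - 1L) * T + 1L, ] <- dhc
  } else {
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * T + 2L):((b - 1L) * T + head$lengths[b] - 1L)
      dH[rows, ] <- matrix(dhc[b, ] / length(rows), length(rows),
                           ncol(dhc), byrow = TRUE)
    }
  }
  list(dH = dH,
       grads = list(aff.W1 = crossprod(head$hc, dZ),
                    aff.b1 = matrix(colSums(dZ)),
                    aff.w2 = crossprod(head$A, dyhat),
                    aff.b2 = matrix(sum(dyhat))))
}

# Tied-embedding token prediction head over selected rows of H.
# Returns logits (M x V); backward adds the softmax-cross-entropy gradient.
token_head_forward <- function(params, H, rows) {
  H[rows, , drop = FALSE] %*% t(params$weights$embed) +
    rep(params$weights$tok.b, each = length(rows))
}
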