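# Low-rank adaptation of the attention projections.
#
# A frozen projection W gains a trainable update (alpha/rank) * A B with
# A (d x r) Gaussian-initialised and B (r x d) zero-initialised, so the
# adapted model reproduces the frozen model exactly until the first update.

#' LoRA configuration
#'
#' @param rank Adapter rank (default 12).
#' @param alpha Scaling numerator; the update is scaled by `alpha / rank`
#'   (default 24, i.e. scale 2).
#' @param targets Which attention projections receive adapters; any non-empty
#'   subset of `c("query", "key", "value")`.
#' @param init_sd Gaussian sd of the A-side initialisation (default 0.05).
#'   The B side is always zero, so this only sets the scale of the first
#'   adapter gradients, not the initial function.
#' @return A `lora_config`.
#' @export
lora_config <- function(rank = 12L, alpha = 24,
                        targets = c("query", "key", "value"),
                        init_sd = 0.05) {
  assert_that(is_count(rank) && rank >= 1L, "`rank` must be a positive integer")
  targets <- match.arg(targets, several.ok = TRUE)
  assert_that(length(targets) >= 1L, "`targets` must be non-empty")
  structure(list(rank = as.integer(rank), alpha = alpha, targets = targets,
                 init_sd = init_sd),
            class = "lora_config")
}

#' Attach LoRA adapters and freeze the backbone
#'
#' Inserts rank-`r` adapters into the configured projection layers of every
#' encoder block, zero-initialising the B side so outputs are unchanged
#' before training, and flags the backbone (and token head) as frozen.
#'
#' @param params An `affinity_lm` without adapters.
#' @param cfg A `lora_config`.
#' @param seed Seed for the Gaussian A-side initialisation.
#' @return The adapted model; trainable weights are now exactly the adapters
#'   plus the affinity head.
#' @export
attach_lora <- function(params, cfg = lora_config(), seed = 1L) {
  stopifnot(inherits(params, "affinity_lm"), inherits(cfg, "lora_config"))
  if (!is.null(params$lora)) {
    abort_invalid("model already carries LoRA adapters",
                  class = "affinitylm_lora_exists")
  }
  d <- params$config$hidden_width
  r <- cfg$rank
  params$weights <- with_seed(derive_seed(seed, "lora"), {
    w <- params$weights
    for (l in seq_len(params$config$num_layers)) {
      for (tgt in cfg$targets) {
        c1 <- substr(tgt, 1, 1)
        w[[sprintf("L%d.W%s.loraA", l, c1)]] <-
          matrix(stats::rnorm(d * r, sd = cfg$init_sd %||% 0.05), d, r)
        w[[sprintf("L%d.W%s.loraB", l, c1)]] <- matrix(0, r, d)
      }
    }
    w
  })
  params$lora <- cfg
  params$backbone_frozen <- TRUE
  params
}

#' Merge adapters into the backbone (for export) — inverse of [attach_lora()]
#' in effect, not in trainability: the result has no adapters and an
#' unfrozen backbone whose projections equal W + (alpha/rank) A B.
#' @param params An adapted `affinity_lm`.
#' @return An `affinity_lm` with merged projections.
#' @export
merge_lora <- function(params) {
  assert_that(!is.null(params$lora), "model has no LoRA adapters")
  s <- params$lora$alpha / params$lora$rank
  w <- params$weights
  for (l in seq_len(params$config$num_layers)) {
    for (tgt in params$lora$targets) {
      c1 <- substr(tgt, 1, 1)
      An <- sprintf("L%d.W%s.loraA", l, c1)
      Bn <- sprintf("L%d.W%s.loraB", l, c1)
      Wn <- sprintf("L%d.W%s", l, c1)
      w[[Wn]] <- w[[Wn]] + s * (w[[An]] %*% w[[Bn]])
      w[[An]] <- NULL; w[[Bn]] <- NULL
    }
  }
  params$weights <- w
  params$lora <- NULL
  params$backbone_frozen <- FALSE
  params
}
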