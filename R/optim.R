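# AdamW optimizer and the warm-up + cosine learning-rate schedule.

#' Training schedule for pretraining
#'
#' Linear warm-up from 0 to `peak_lr` over `warmup_steps`, then cosine decay
#' to 0 at `total_steps`.  Optimizer moments follow the AdamW settings
#' beta1 = 0.9, beta2 = 0.98, eps = 1e-7.
#'
#' @param total_steps,warmup_steps Step counts (defaults 500000 / 50000).
#' @param peak_lr Peak learning rate (default 1e-4).
#' @param batch_size Sequences per optimizer step (default 128).
#' @return A `train_schedule`.
#' @export
train_schedule <- function(total_steps = 500000L, warmup_steps = 50000L,
                           peak_lr = 1e-4, batch_size = 128L) {
  assert_that(warmup_steps < total_steps,
              "warmup_steps must be smaller than total_steps")
  structure(list(total_steps = as.integer(total_steps),
                 warmup_steps = as.integer(warmup_steps),
                 peak_lr = peak_lr, batch_size = as.integer(batch_size),
                 beta1 = 0.9, beta2 = 0.98, eps = 1e-7),
            class = "train_schedule")
}

#' Learning rate at a given step
#' @param step Step index (0-based; step 0 has lr 0).
#' @param schedule A `train_schedule`.
#' @return The learning rate.
#' @export
schedule_lr <- function(step, schedule) {
  w <- schedule$warmup_steps; tot <- schedule$total_steps
  ifelse(step <= w,
         schedule$peak_lr * step / w,
         schedule$peak_lr * 0.5 * (1 + cos(pi * pmin(1, (step - w) / (tot - w)))))
}

# Scale gradients so their global L2 norm does not exceed `max_norm`.
clip_grad_norm <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

adamw_init <- function(params, trainable) {
  list(m = lapply(params$weights[trainable], function(x) x * 0),
       v = lapply(params$weights[trainable], function(x) x * 0),
       t = 0L)
}

# One decoupled-weight-decay Adam step over the trainable weights present in
# `grads`.  Bias and layer-norm parameters are excluded from weight decay.
adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.98,
                       eps = 1e-7, weight_decay = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    decay <- if (grepl("\\.b[qkvo12]?$|\\.g$", nm)) 0 else weight_decay
    params$weights[[nm]] <- params$weights[[nm]] -
      lr * (upd + decay * params$weights[[nm]])
  }
  list(params = params, state = state)
}
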