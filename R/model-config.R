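# Transformer-encoder configuration and parameter initialisation.
#
# The default configuration (8 layers x 8 heads, hidden 512, feed-forward
# 2048) realises a model of about 26 million parameters with a 5-mer
# vocabulary.  Positions enter only through rotary embeddings applied to
# query/key vectors; there is no learned absolute-position table.  Input and
# output token embeddings are tied.

#' Encoder configuration
#'
#' @param vocab_size Vocabulary size |v| (including the five special tokens).
#' @param num_layers,num_heads Encoder depth and heads per layer (defaults 8, 8).
#' @param hidden_width Residual-stream width; must divide evenly into heads,
#'   with an even per-head width (rotary embeddings rotate dimension pairs).
#' @param ffn_width Feed-forward inner width (default 4x hidden).
#' @param max_tokens Maximum token count per sequence including `[CLS]`/`[SEP]`.
#' @param dropout Dropout fraction (kept in the config for provenance; the
#'   reference implementation trains tiny models without dropout).
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(vocab_size, num_layers = 8L, num_heads = 8L,
                           hidden_width = 512L, ffn_width = 2048L,
                           max_tokens = 514L, dropout = 0) {
  assert_that(is_count(vocab_size) && vocab_size > 5L, "invalid vocab_size")
  assert_that(is_count(num_layers) && num_layers >= 1L, "invalid num_layers")
  assert_that(is_count(num_heads) && num_heads >= 1L, "invalid num_heads")
  assert_that(hidden_width %% num_heads == 0L,
              "hidden_width must be divisible by num_heads")
  assert_that((hidden_width / num_heads) %% 2L == 0L,
              "per-head width must be even (RoPE pairs dimensions)")
  structure(list(vocab_size = as.integer(vocab_size),
                 num_layers = as.integer(num_layers),
                 num_heads = as.integer(num_heads),
                 hidden_width = as.integer(hidden_width),
                 ffn_width = as.integer(ffn_width),
                 max_tokens = as.integer(max_tokens),
                 dropout = dropout),
            class = "encoder_config")
}

# Named shapes of every weight tensor, the single source of truth used by
# initialisation, the parameter census, and the optimizer.
weight_shapes <- function(config, lora = NULL) {
  d <- config$hidden_width; f <- config$ffn_width; V <- config$vocab_size
  shapes <- list(embed = c(V, d))
  for (l in seq_len(config$num_layers)) {
    p <- function(nm) sprintf("L%d.%s", l, nm)
    layer <- list(c(d, 1), c(d, 1),                 # ln1 gain, bias
                  c(d, d), c(d, 1), c(d, d), c(d, 1),
                  c(d, d), c(d, 1), c(d, d), c(d, 1),
                  c(d, 1), c(d, 1),                 # ln2 gain, bias
                  c(d, f), c(f, 1), c(f, d), c(d, 1))
    names(layer) <- sapply(c("ln1.g", "ln1.b", "Wq", "bq", "Wk", "bk",
                             "Wv", "bv", "Wo", "bo", "ln2.g", "ln2.b",
                             "W1", "b1", "W2", "b2"), p)
    shapes <- c(shapes, layer)
    if (!is.null(lora)) {
      r <- lora$rank
      for (tgt in lora$targets) {
        shapes[[p(sprintf("W%s.loraA", substr(tgt, 1, 1)))]] <- c(d, r)
        shapes[[p(sprintf("W%s.loraB", substr(tgt, 1, 1)))]] <- c(r, d)
      }
    }
  }
  shapes$final_ln.g <- c(d, 1); shapes$final_ln.b <- c(d, 1)
  shapes$tok.b <- c(V, 1)                            # tied-embedding head bias
  shapes$aff.W1 <- c(d, d); shapes$aff.b1 <- c(d, 1)
  shapes$aff.w2 <- c(d, 1); shapes$aff.b2 <- c(1, 1)
  shapes
}

weight_group <- function(name) {
  if (grepl("^embed$|^L[0-9]+\\.(ln|W[qkvo]|b[qkvo]|W[12]|b[12])", name) &&
      !grepl("lora", name) || grepl("^final_ln", name)) return("backbone")
  if (grepl("lora", name)) return("lora")
  if (grepl("^tok\\.", name)) return("token_head")
  if (grepl("^aff\\.", name)) return("affinity_head")
  stop("unknown weight name: ", name)
}

#' Count model parameters
#'
#' Closed-form census over the named weight shapes; `include` selects the
#' parameter groups.  The tied output embedding is counted once (under the
#' backbone); the token prediction head contributes only its bias.
#'
#' @param params A model (from [init_encoder()]) or an `encoder_config`.
#' @param include Character subset of
#'   `c("backbone", "token_head", "affinity_head", "lora")`.
#' @param lora Optional `lora_config` when `params` is a bare config.
#' @return Integer parameter count.
#' @examples
#' cfg <- encoder_config(vocab_size = 4^5 + 5)
#' param_count(cfg)  # about 26 million
#' @export
param_count <- function(params,
                        include = c("backbone", "token_head", "affinity_head"),
                        lora = NULL) {
  config <- if (inherits(params, "encoder_config")) params else params$config
  if (is.null(lora) && !inherits(params, "encoder_config")) lora <- params$lora
  shapes <- weight_shapes(config, lora = lora)
  groups <- vapply(names(shapes), weight_group, character(1))
  sum(vapply(shapes[groups %in% include], prod, numeric(1)))
}

#' Initialise encoder parameters
#'
#' Deterministic given the seed: weight matrices are drawn N(0, 0.02^2),
#' biases start at zero, layer-norm gains at one.  The returned model has a
#' token prediction head (tied embedding + bias) and an affinity head (a
#' two-layer perceptron over the final `[CLS]` hidden vector); no LoRA
#' adapters until [attach_lora()] is called.
#'
#' @param config An `encoder_config`.
#' @param seed Integer seed.
#' @return An `affinity_lm` model object.
#' @export
init_encoder <- function(config, seed = 1L) {
  stopifnot(inherits(config, "encoder_config"))
  shapes <- weight_shapes(config)
  weights <- with_seed(derive_seed(seed, "init"), {
    lapply(names(shapes), function(nm) {
      sh <- shapes[[nm]]
      if (grepl("\\.g$", nm)) {
        matrix(1, sh[1], sh[2])
      } else if (grepl("\\.b[qkvo12]?$", nm)) {
        matrix(0, sh[1], sh[2])
      } else {
        matrix(stats::rnorm(prod(sh), sd = 0.02), sh[1], sh[2])
      }
    })
  })
  names(weights) <- names(shapes)
  structure(list(config = config, weights = weights, lora = NULL,
                 backbone_frozen = FALSE, seed = as.integer(seed),
                 scaler = NULL),
            class = "affinity_lm")
}

#' @export
print.affinity_lm <- function(x, ...) {
  cat(sprintf(
    "<affinity_lm: %d layers x %d heads, hidden %d, |v| = %d, %.2fM params%s%s>\n",
    x$config$num_layers, x$config$num_heads, x$config$hidden_width,
    x$config$vocab_size,
    param_count(x, include = c("backbone", "token_head", "affinity_head",
                               "lora")) / 1e6,
    if (!is.null(x$lora)) sprintf(", LoRA r=%d", x$lora$rank) else "",
    if (x$backbone_frozen) ", backbone frozen" else ""))
  invisible(x)
}

#' Names of trainable weights under the current training phase
#'
#' During pretraining everything but adapters (which do not exist yet) is
#' trainable; once the backbone is frozen and adapters attached, only the
#' adapters and the affinity head are.
#' @param params An `affinity_lm`.
#' @return Character vector of weight names.
#' @export
trainable_weights <- function(params) {
  groups <- vapply(names(params$weights), weight_group, character(1))
  if (params$backbone_frozen) {
    names(params$weights)[groups %in% c("lora", "affinity_head")]
  } else {
    names(params$weights)[groups %in% c("backbone", "token_head",
                                        "affinity_head", "lora")]
  }
}

#' Save / load a model checkpoint
#'
#' Weights go to an RDS file next to a JSON manifest recording the config,
#' seed, LoRA settings, affinity scaler and a hash of the weight names, so
#' adapters can be matched to compatible backbones.
#'
#' @param params An `affinity_lm`.
#' @param path Directory to write into (created if needed).
#' @export
save_checkpoint <- function(params, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(params$config), seed = params$seed,
                   lora = if (!is.null(params$lora)) unclass(params$lora),
                   scaler = params$scaler,
                   backbone_frozen = params$backbone_frozen,
                   pooling = params$pooling, head_norm = params$head_norm,
                   weight_names = names(params$weights))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  saveRDS(params$weights, file.path(path, "weights.rds"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(encoder_config, manifest$config[
    c("vocab_size", "num_layers", "num_heads", "hidden_width", "ffn_width",
      "max_tokens", "dropout")])
  weights <- readRDS(file.path(path, "weights.rds"))
  lora <- manifest$lora
  if (!is.null(lora)) {
    lora <- do.call(lora_config, lora[intersect(
      c("rank", "alpha", "targets", "init_sd"), names(lora))])
  }
  hn <- manifest$head_norm
  if (!is.null(hn)) hn <- list(center = unlist(hn$center),
                               scale = unlist(hn$scale))
  structure(list(config = cfg, weights = weights, lora = lora,
                 backbone_frozen = isTRUE(manifest$backbone_frozen),
                 seed = manifest$seed, scaler = manifest$scaler,
                 pooling = manifest$pooling, head_norm = hn),
            class = "affinity_lm")
}
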