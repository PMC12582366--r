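# Independent closed-form parameter census, written against the declared
# architecture (tied embeddings, per-layer QKVO + FFN + two layer-norms,
# final layer-norm, token-head bias, two-layer affinity head).
census_oracle <- function(d, f, V, L, include_heads = TRUE) {
  per_layer <- 4 * (d * d + d) + (d * f + f) + (f * d + d) + 4 * d
  n <- V * d + L * per_layer + 2 * d
  if (include_heads) n <- n + V + (d * d + d) + (d + 1)
  n
}

test_that("parameter count matches the closed form and rounds to 26 million", {
  cfg <- encoder_config(vocab_size = 4^5 + 5)   # default 8x8, 512/2048
  expect_equal(param_count(cfg), census_oracle(512, 2048, 1029, 8))
  expect_equal(round(param_count(cfg) / 1e6), 26)
  # trainable census during pretraining (no affinity head updates) also
  # rounds to the printed figure
  expect_equal(round(param_count(cfg, include = c("backbone", "token_head")) / 1e6),
               26)
})

test_that("census equals brute-force enumeration for varied configurations", {
  set.seed(31)
  for (i in 1:5) {
    nh <- sample(c(1L, 2L, 4L), 1)
    d <- nh * 2L * sample(2:6, 1)
    cfg <- encoder_config(vocab_size = sample(c(9L, 69L, 261L), 1),
                          num_layers = sample(1:3, 1), num_heads = nh,
                          hidden_width = d, ffn_width = sample(c(16L, 32L), 1),
                          max_tokens = 32L)
    m <- init_encoder(cfg, seed = i)
    enumerated <- sum(vapply(m$weights, length, numeric(1)))
    expect_equal(param_count(cfg), enumerated)
    expect_equal(param_count(cfg),
                 census_oracle(d, cfg$ffn_width, cfg$vocab_size, cfg$num_layers))
  }
})

test_that("initialisation is deterministic and config invariants enforced", {
  cfg <- micro_encoder_config()
  a <- init_encoder(cfg, seed = 7L)
  b <- init_encoder(cfg, seed = 7L)
  expect_identical(a$weights, b$weights)
  c <- init_encoder(cfg, seed = 8L)
  expect_false(identical(a$weights$embed, c$weights$embed))
  expect_error(encoder_config(9L, hidden_width = 10L, num_heads = 4L),
               class = "affinitylm_invalid_argument")
  expect_error(encoder_config(9L, hidden_width = 9L, num_heads = 3L),
               class = "affinitylm_invalid_argument")  # odd head width
})

test_that("single-token input yields the trivial attention matrix", {
  m <- init_encoder(micro_encoder_config(), seed = 1L)
  enc <- encode(m, list(5L), need_attn = TRUE)
  A <- enc$attention[[1L]]
  expect_equal(dim(A), c(2, 2, 3, 3))   # [CLS] x [SEP] framing adds 2
  expect_true(all(abs(apply(A, c(1, 2, 3), sum) - 1) < 1e-5))
})

test_that("attention rows sum to 1 over non-pad positions in every layer/head", {
  m <- init_encoder(micro_encoder_config(), seed = 2L)
  ids <- list(c(5L, 6L, 7L, 8L), c(6L, 8L))   # ragged: forces padding
  coll <- affinitylm:::collate_ids(ids, 32L)
  fwd <- affinitylm:::model_forward(m, coll$ids, coll$mask, need_attn = TRUE)
  for (b in 1:2) {
    Tb <- ncol(coll$ids)
    sums <- apply(fwd$attention[[b]], c(1, 2, 3), sum)
    expect_true(all(abs(sums - 1) < 1e-5))
    # padding columns receive zero attention mass
    pad_cols <- which(!coll$mask[b, ])
    if (length(pad_cols) > 0) {
      expect_true(all(fwd$attention[[b]][, , , pad_cols] == 0))
    }
  }
})

test_that("RoPE attention logits depend only on relative position", {
  tab <- affinitylm:::rope_tables(64L, 8L)
  set.seed(11)
  q <- matrix(rnorm(8), 1); k <- matrix(rnorm(8), 1)
  dot_at <- function(p1, p2) {
    sum(affinitylm:::rope_rotate(q, tab, p1) *
        affinitylm:::rope_rotate(k, tab, p2))
  }
  for (s in c(1L, 3L, 7L)) {
    base <- dot_at(1L, 1L + s)
    for (shift in c(5L, 20L, 50L)) {
      expect_equal(dot_at(1L + shift, 1L + s + shift), base, tolerance = 1e-10)
    }
  }
  # absolute position does change the raw vectors (it is only the product
  # that is shift-invariant)
  expect_false(isTRUE(all.equal(affinitylm:::rope_rotate(q, tab, 1L),
                                affinitylm:::rope_rotate(q, tab, 5L))))
})

test_that("overlong inputs error unless truncation is requested", {
  m <- init_encoder(micro_encoder_config(), seed = 3L)
  long <- list(rep(5L, 40L))
  expect_error(encode(m, long), class = "affinitylm_overlong")
  enc <- encode(m, long, truncate = TRUE)
  expect_equal(nrow(enc$hidden[[1L]]), 32L)
})

test_that("LoRA attachment preserves outputs, freezes the backbone", {
  m <- init_encoder(micro_encoder_config(), seed = 4L)
  ids <- list(c(5L, 6L, 7L), c(8L, 8L, 5L))
  coll <- affinitylm:::collate_ids(ids, 32L)
  before <- affinitylm:::model_forward(m, coll$ids, coll$mask)$H
  ad <- attach_lora(m, lora_config(rank = 4L, alpha = 8), seed = 9L)
  after <- affinitylm:::model_forward(ad, coll$ids, coll$mask)$H
  expect_lt(max(abs(before - after)), 1e-6)     # zero-init B side
  expect_true(ad$backbone_frozen)
  # trainable set is exactly adapters + affinity head
  tw <- trainable_weights(ad)
  expect_true(all(grepl("lora|^aff\\.", tw)))
  d <- ad$config$hidden_width
  expect_equal(param_count(ad, include = "lora"),
               ad$config$num_layers * 3 * 4 * (d + d))  # r(d_in + d_out) each
  expect_error(attach_lora(ad, lora_config()), class = "affinitylm_lora_exists")
  # doubling rank and alpha together leaves the initial forward unchanged
  ad2 <- attach_lora(m, lora_config(rank = 8L, alpha = 16), seed = 9L)
  expect_lt(max(abs(affinitylm:::model_forward(ad2, coll$ids, coll$mask)$H -
                    before)), 1e-6)
})

test_that("merging adapters reproduces the adapted forward pass", {
  m <- init_encoder(micro_encoder_config(), seed = 5L)
  ad <- attach_lora(m, lora_config(rank = 2L, alpha = 4), seed = 2L)
  for (nm in grep("loraB", names(ad$weights), value = TRUE)) {
    ad$weights[[nm]] <- matrix(rnorm(length(ad$weights[[nm]]), sd = 0.1),
                               nrow(ad$weights[[nm]]))
  }
  coll <- affinitylm:::collate_ids(list(c(5L, 7L, 6L, 8L)), 32L)
  H_ad <- affinitylm:::model_forward(ad, coll$ids, coll$mask)$H
  H_merged <- affinitylm:::model_forward(merge_lora(ad), coll$ids, coll$mask)$H
  expect_equal(H_ad, H_merged, tolerance = 1e-12)
})

test_that("affinity predictions are deterministic and shape-correct", {
  m <- init_encoder(micro_encoder_config(), seed = 6L)
  v <- build_single_base_vocab()
  seqs <- c("ACGTACG", "ACGTACG", "TTTT", "ACGTACGTACGTACGT")
  p <- predict_affinity(m, seqs, v)
  expect_length(p, 4L)
  expect_equal(p[1], p[2])              # identical inputs, identical outputs
  expect_true(all(is.finite(p)))
  expect_identical(predict_affinity(m, seqs, v), p)
})

test_that("checkpoints round-trip through disk", {
  m <- init_encoder(micro_encoder_config(), seed = 10L)
  m <- attach_lora(m, lora_config(rank = 2L), seed = 1L)
  m$scaler <- list(min = 0.2, max = 1.4)
  dir <- withr::local_tempdir()
  save_checkpoint(m, dir)
  m2 <- load_checkpoint(dir)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$config, m$config)
  expect_equal(m2$scaler$min, 0.2)
  expect_true(m2$backbone_frozen)
})
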