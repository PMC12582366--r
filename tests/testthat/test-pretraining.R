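test_that("span masking arithmetic: 15% of a 1000-token sequence in 10-token spans", {
  withr::with_seed(1, {
    mb <- apply_masking(seq_len(1000) * 0L + 5L, masking_policy())
  })
  expect_equal(mb$M, 150L)
  # 15 spans of 10 consecutive tokens
  spans <- split(mb$mask_positions,
                 cumsum(c(1L, diff(mb$mask_positions) != 1L)))
  expect_length(spans, 15L)
  expect_true(all(lengths(spans) == 10L))
  expect_true(all(mb$input_ids[mb$mask_positions] == 4L))  # [MASK] id
  expect_identical(mb$target_ids, rep(5L, 150L))
})

test_that("short sequences fall back to one truncated span keeping M >= 1", {
  withr::with_seed(2, {
    mb <- apply_masking(rep(6L, 20L), masking_policy())
  })
  expect_equal(mb$M, 3L)                           # ceiling(0.15 * 20)
  expect_true(all(diff(mb$mask_positions) == 1L))  # one consecutive span
  expect_warning(
    withr::with_seed(3, apply_masking(rep(6L, 5L), masking_policy())),
    "span_length")
})

test_that("masking is reproducible and respects the proportion on average", {
  a <- withr::with_seed(7, apply_masking(rep(5L, 200L), masking_policy()))
  b <- withr::with_seed(7, apply_masking(rep(5L, 200L), masking_policy()))
  expect_identical(a$mask_positions, b$mask_positions)
  # span mode at L = 200: round(0.15*200/10) = 3 spans -> exactly 30 tokens
  expect_equal(a$M, 30L)
  # single mode: empirical fraction over many applications near 15%
  withr::with_seed(8, {
    fr <- vapply(1:2000, function(i) {
      apply_masking(rep(5L, 200L), masking_policy("single"))$M / 200
    }, numeric(1))
  })
  expect_lt(abs(mean(fr) - 0.15), 0.01)
  # spans never overlap
  withr::with_seed(9, {
    for (i in 1:50) {
      mb <- apply_masking(rep(5L, 120L), masking_policy())
      expect_false(anyDuplicated(mb$mask_positions) > 0)
    }
  })
})

test_that("masked LM loss matches closed forms", {
  expect_equal(masked_lm_loss(matrix(0, 4, 1029), c(5L, 6L, 7L, 8L)),
               log(1029), tolerance = 1e-12)
  logits <- matrix(0, 1, 9)
  logits[1, 6] <- 10                               # correct class id 5
  expect_equal(masked_lm_loss(logits, 5L), -log(exp(10) / (exp(10) + 8)),
               tolerance = 1e-9)
  # monotone approach to zero as the correct logit grows; the closed form at
  # logit 20 is log(1 + 8 exp(-20)) = 1.65e-8
  losses <- vapply(c(2, 5, 10, 20), function(z) {
    lg <- matrix(0, 1, 9); lg[1, 6] <- z
    masked_lm_loss(lg, 5L)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_lt(losses[4], 1e-7)
  expect_equal(losses[4], log1p(8 * exp(-20)), tolerance = 1e-6)
  expect_error(masked_lm_loss(matrix(0, 0, 9), integer(0)),
               class = "affinitylm_empty_mask")
})

test_that("learning-rate schedule hits its endpoints", {
  sch <- train_schedule(total_steps = 1000L, warmup_steps = 100L, peak_lr = 1e-4)
  expect_equal(schedule_lr(0, sch), 0)
  expect_equal(schedule_lr(100, sch), 1e-4)
  expect_lt(schedule_lr(1000, sch), 1e-12)
  expect_lt(schedule_lr(550, sch), 1e-4)           # decaying after warm-up
  expect_gt(schedule_lr(550, sch), 0)
  expect_error(train_schedule(total_steps = 10L, warmup_steps = 10L),
               class = "affinitylm_invalid_argument")
})

test_that("a tiny pretraining run beats the uniform-prediction baseline", {
  pr <- flagship_pretrain()
  expect_false(pr$diverged)
  final <- tail(pr$trace$loss, 1)
  expect_lt(final, log(tiny_vocab$size) - 0.5)
  # loss actually fell over training
  expect_lt(final, pr$trace$loss[1])
})

test_that("pretraining is deterministic given the seed", {
  corp <- random_dna(30, 40, seed = 21)
  cfg <- micro_encoder_config()
  sch <- train_schedule(total_steps = 5L, warmup_steps = 2L, peak_lr = 1e-3,
                        batch_size = 4L)
  v <- build_single_base_vocab()
  a <- pretrain(corp, v, cfg, masking_policy("single"), sch, seed = 5L,
                log_every = 1L)
  b <- pretrain(corp, v, cfg, masking_policy("single"), sch, seed = 5L,
                log_every = 1L)
  expect_identical(a$trace, b$trace)
  expect_identical(a$params$weights, b$params$weights)
  # gradient flows to backbone + token head only: no adapters exist, and the
  # affinity head (never touched by the masked-LM loss) stays at init
  init <- init_encoder(cfg, seed = 5L)
  expect_identical(a$params$weights$aff.W1, init$weights$aff.W1)
  expect_false(identical(a$params$weights$embed, init$weights$embed))
})
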