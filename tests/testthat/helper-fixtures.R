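# Shared fixtures.  The end-to-end "flagship" pipeline (tiny pretrain ->
# LoRA fine-tune -> hold-out prediction -> attention motif) is expensive, so
# it is computed lazily once per test run and reused by every test that
# needs any of its pieces.

# Single-threaded BLAS: multi-threaded reductions reorder floating-point
# sums, and the training loops are chaotic enough that run-to-run jitter can
# move end-of-training metrics.  Must be set before the first BLAS call.
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1",
           MKL_NUM_THREADS = "1")

tiny_vocab <- build_single_base_vocab()

tiny_encoder_config <- function(vocab_size = tiny_vocab$size) {
  encoder_config(vocab_size = vocab_size, num_layers = 6L, num_heads = 8L,
                 hidden_width = 64L, ffn_width = 128L, max_tokens = 130L)
}

micro_encoder_config <- function(vocab_size = 9L) {
  encoder_config(vocab_size = vocab_size, num_layers = 2L, num_heads = 2L,
                 hidden_width = 8L, ffn_width = 16L, max_tokens = 32L)
}

random_dna <- function(n, length, seed = 1L) {
  withr::with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1)))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Tiny pretrained backbone on a planted-motif background corpus.
flagship_pretrain <- function() {
  cached("pretrain", {
    spec <- planted_motif_spec(noise_sd = 0)
    corp <- generate_corpus(2000, 100, spec, seed = 11)
    sched <- train_schedule(total_steps = 400L, warmup_steps = 40L,
                            peak_lr = 1e-3, batch_size = 16L)
    pr <- pretrain(corp$corpus, tiny_vocab, tiny_encoder_config(),
                   masking_policy("single"), sched, seed = 11)
    pr
  })
}

# Noiseless planted-motif affinity data put through the binned-split
# protocol, fine-tuned with LoRA, plus hold-out predictions.
flagship_finetune <- function() {
  cached("finetune", {
    spec <- planted_motif_spec(noise_sd = 0)
    gen <- generate_affinity_dataset(3000, 30, spec, seed = 12)
    split <- bin_and_sample(gen$data, 2000L, seed = 13)
    ft_data <- affinity_dataset(gen$data$sequences[split$finetune_idx],
                                gen$data$affinities[split$finetune_idx])
    ft <- finetune(flagship_pretrain()$params, ft_data, tiny_vocab,
                   lr = 3e-3, batch_size = 64L,
                   stop = early_stop_policy(max_epochs = 60L, tolerance = 15L),
                   seed = 14)
    hold_seq <- gen$data$sequences[split$test_idx]
    hold_y <- gen$data$affinities[split$test_idx]
    pred <- predict_affinity(ft$params, hold_seq, tiny_vocab)
    list(spec = spec, gen = gen, split = split, ft = ft,
         hold_seq = hold_seq, hold_y = hold_y, pred = pred)
  })
}

flagship_motif <- function() {
  cached("motif", {
    fx <- flagship_finetune()
    mot <- extract_motifs(fx$ft$params, fx$hold_seq, tiny_vocab,
                          motif_config(top_n_sequences = 100L))
    mot
  })
}
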