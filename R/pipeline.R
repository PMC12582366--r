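# Config-driven orchestration: simulate -> pretrain -> finetune -> predict ->
# evaluate -> extract-motifs, with one master seed, per-stage derived seeds,
# and JSON reports.  The CLI at inst/cli/affinitylm.R is a thin wrapper over
# these functions.

#' Run a multi-stage pipeline from a configuration
#'
#' `config` is a named list (or a path to a YAML/JSON file holding one) with
#' a `stages` character vector — any subset, in order, of `"simulate"`,
#' `"pretrain"`, `"finetune"`, `"predict"`, `"evaluate"`,
#' `"extract_motifs"` — plus optional per-stage parameter lists of the same
#' names.  Artifacts and a `report.json` land in `out_dir`; every stage logs
#' its derived seed.  Re-running an identical config reproduces identical
#' reports (timestamps aside).
#'
#' @param config Named list or path to a YAML/JSON config file.
#' @param out_dir Output directory.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return Invisibly, a list with per-stage results and the report.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stages <- config$stages
  assert_that(length(stages) >= 1L, "config must list at least one stage")
  known <- c("simulate", "pretrain", "finetune", "predict", "evaluate",
             "extract_motifs")
  assert_that(all(stages %in% known),
              paste("unknown stage; expected subset of:",
                    paste(known, collapse = ", ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list()
  report <- list(seed = seed, stages = list())
  cfg_of <- function(stage) config[[stage]] %||NULL% list()

  spec <- do.call(planted_motif_spec,
                  c(cfg_of("spec"), list(seed = derive_seed(seed, "spec"))))

  for (stage in stages) {
    sseed <- derive_seed(seed, stage)
    sc <- cfg_of(stage)
    res <- switch(stage,
      simulate = {
        n <- sc$n %||NULL% 2000L
        len <- sc$length %||NULL% 30L
        gen <- generate_affinity_dataset(n, len, spec, seed = sseed)
        write_affinity_tsv(gen$data, file.path(out_dir, "affinity.tsv"))
        corp <- generate_corpus(sc$corpus_n %||NULL% 2000L,
                                sc$corpus_length %||NULL% 100L, spec,
                                seed = sseed)
        write_corpus(corp$corpus, file.path(out_dir, "corpus.txt.gz"))
        state$data <- gen$data
        state$truth <- gen$truth
        state$corpus <- corp$corpus
        list(n_affinity = n, n_corpus = length(corp$corpus$sequences))
      },
      pretrain = {
        vocab <- build_single_base_vocab()
        ecfg <- do.call(encoder_config, c(
          list(vocab_size = vocab$size),
          sc$encoder %||NULL% list(num_layers = 6L, num_heads = 8L,
                                   hidden_width = 64L, ffn_width = 128L,
                                   max_tokens = 130L)))
        sched <- do.call(train_schedule, sc$schedule %||NULL%
                           list(total_steps = 300L, warmup_steps = 30L,
                                peak_lr = 1e-3, batch_size = 16L))
        pr <- pretrain(state$corpus, vocab, ecfg,
                       masking_policy("single"), sched, seed = sseed)
        state$vocab <- vocab
        state$pretrained <- pr$params
        utils::write.csv(pr$trace, file.path(out_dir, "pretrain_trace.csv"),
                         row.names = FALSE)
        list(final_loss = pr$trace$loss[nrow(pr$trace)],
             baseline = log(vocab$size))
      },
      finetune = {
        ft <- finetune(state$pretrained, state$data, state$vocab,
                       stop = do.call(early_stop_policy, sc$stop %||NULL%
                                        list(max_epochs = 60L, tolerance = 15L)),
                       lr = sc$lr %||NULL% 3e-3,
                       batch_size = sc$batch_size %||NULL% 64L, seed = sseed)
        state$model <- ft$params
        save_checkpoint(ft$params, file.path(out_dir, "checkpoint"))
        utils::write.csv(ft$trace, file.path(out_dir, "finetune_trace.csv"),
                         row.names = FALSE)
        list(best_epoch = ft$best_epoch, best_valid_loss = ft$best_valid_loss)
      },
      predict = {
        preds <- predict_affinity(state$model, state$data$sequences,
                                  state$vocab)
        utils::write.table(
          data.frame(sequence = state$data$sequences, prediction = preds),
          file.path(out_dir, "predictions.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
        state$predictions <- preds
        list(n = length(preds))
      },
      evaluate = {
        pcc <- pearson_correlation(state$predictions, state$data$affinities)
        rep <- evaluation_report("pcc", pcc, length(state$predictions),
                                 dataset_id = "affinity.tsv", seed = sseed)
        utils::write.table(rep, file.path(out_dir, "evaluation.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        list(pcc = pcc)
      },
      extract_motifs = {
        mcfg <- do.call(motif_config, sc$motif %||NULL% list())
        mot <- extract_motifs(state$model, state$data$sequences, state$vocab,
                              mcfg)
        if (!is.null(mot$pfm)) {
          write_pfm_jaspar(mot$pfm, file.path(out_dir, "motif.jaspar"))
          write_pfm_meme(mot$pfm, file.path(out_dir, "motif.meme"))
        }
        state$motif <- mot
        list(n_subsequences = length(mot$subsequences),
             width = if (!is.null(mot$pfm)) mot$pfm$width else NA)
      })
    report$stages[[stage]] <- c(list(seed = sseed), res)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(state = state, report = report))
}

`%||NULL%` <- function(a, b) if (is.null(a)) b else a
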