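# Shared fixtures, built in code.  The toy model is trained once per test
# session and reused by the attribution and feature-selection tests.

random_seq <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

toy_genome <- function(seed = 404, lens = c(chrA = 3000L, chrB = 2000L)) {
  set.seed(seed)
  Biostrings::DNAStringSet(vapply(lens, random_seq, ""))
}

write_bed <- function(df) {
  path <- tempfile(fileext = ".bed")
  writeLines(apply(df, 1, paste, collapse = "\t"), path)
  path
}

# small trained model on a separable motif-insertion set; cached
.fixture_env <- new.env(parent = emptyenv())

toy_sim_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  cfg <- simulation_config(n_sequences = 200, L = 200, seed = 91)
  report <- run_simulation_experiment(
    cfg,
    model_cfg = model_config(channels = 12L, fc_hidden = 16L),
    train_cfg = train_config(learning_rate = 3e-3, batch_size = 16L,
                             max_epochs = 60L, lr_decay_every = 20L,
                             early_stop_patience = 10L),
    seed = 91)
  .fixture_env$fit <- report
  report
}
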