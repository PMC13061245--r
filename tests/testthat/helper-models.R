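# Shared trained models for the heavier suites. Built lazily, once per
# test run, at the budgets the package documents for desk-scale rehearsal.

.model_cache <- new.env(parent = emptyenv())

# GAN trained on 200 synthetic pairs (fixed seed, reduced epoch budget).
acceptance_gan <- function() {
  if (is.null(.model_cache$gan)) {
    pairs <- make_pairs(200, seed = 1001)
    .model_cache$gan_pairs <- pairs
    .model_cache$gan <- train_gan(pairs, gan_config(epochs = 150,
                                                    batch_size = 32,
                                                    seed = 1))
  }
  list(model = .model_cache$gan, pairs = .model_cache$gan_pairs)
}

# Full pipeline on 60 simulated "measured" trials.
acceptance_run <- function() {
  if (is.null(.model_cache$run)) {
    trials <- simulate_dataset(sim_config(n_trials = 60, seed = 11))
    cfg <- pipeline_config(
      gan = gan_config(epochs = 2000, batch_size = 16, seed = 1),
      rnn = rnn_config(epochs = 50, batch_size = 64, patience = 15, seed = 1),
      n_gan = 400, n_mix = 200, seed = 1)
    .model_cache$run <- suppressWarnings(run_end_to_end(trials, cfg))
  }
  .model_cache$run
}
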