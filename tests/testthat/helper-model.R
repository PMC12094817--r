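# one trained toy denoiser shared by the acceptance tests; trained lazily at
# the study conditions (n = 5000 proteins, N = 16, 20 epochs, fixed seeds)
# and cached for the rest of the run

.model_cache <- new.env(parent = emptyenv())

toy_study_world <- function() toy_world_params()

get_trained_toy_fit <- function() {
  if (is.null(.model_cache$fit)) {
    ds <- sample_toy_proteins(toy_study_world(), 5000, 16, seed = 101)
    .model_cache$fit <- train_denoiser(ds, denoiser_config(),
                                       train_config(epochs = 20, seed = 202))
  }
  .model_cache$fit
}

get_toy_holdout <- function(n = 1000) {
  # seed disjoint from the training draw
  sample_toy_proteins(toy_study_world(), n, 16, seed = 303)
}
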