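# Shared trained CNN: training the torque model takes a few minutes, so it
# is done at most once per test session and reused by every test that needs
# a realistic model. The first caller pays the cost and the elapsed training
# time is retained for the timing assertions.

.cnn_cache <- new.env(parent = emptyenv())

get_trained_cnn <- function() {
  if (is.null(.cnn_cache$trained)) {
    dataset <- gen_isometric_dataset(n_samples = 2000, seed = 7)
    t0 <- proc.time()[["elapsed"]]
    trained <- train(build_model(cnn_config(seed = 1)), dataset)
    .cnn_cache$train_elapsed <- proc.time()[["elapsed"]] - t0
    .cnn_cache$dataset <- dataset
    .cnn_cache$trained <- trained
  }
  list(model = .cnn_cache$trained$model,
       metrics = .cnn_cache$trained$metrics,
       dataset = .cnn_cache$dataset,
       train_elapsed = .cnn_cache$train_elapsed)
}
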