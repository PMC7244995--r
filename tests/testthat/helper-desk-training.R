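# One desk-scale training run (200 synthetic 64x64 frames, 20 epochs,
# fixed seed) shared by the learning and latent-structure tests.

.desk_cache <- new.env(parent = emptyenv())

desk_training <- function() {
  if (!is.null(.desk_cache$result)) return(.desk_cache$result)
  cfg <- modelConfig(inputResolution = 64, inputChannels = 3)
  ds <- simulateDataset(10, grades = 0:4, resolution = 64, channels = 3,
                        nFrames = 20, seed = 101)
  tc <- trainConfig(epochs = 20, batchSize = 16, seed = 101,
                    validationFraction = 0.1)
  fit <- train(ds, cfg, train_config = tc)
  .desk_cache$result <- list(fit = fit, cfg = cfg, dataset = ds, seed = 101)
  .desk_cache$result
}

# held-out synthetic videos from subjects never seen in training
desk_heldout <- function(n = 4, grade = 0, nFrames = 20) {
  lapply(seq_len(n), function(i) {
    simulateVideo(syntheticVideoSpec(sprintf("H%02d", i), grade = grade,
                                     resolution = 64, channels = 3,
                                     nFrames = nFrames, seed = 555000 + i))
  })
}
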