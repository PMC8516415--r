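# Shared fixtures, built once per test session. The short synthetic night
# and small trained model are reused across files to keep the suite fast.

.fixture_env <- new.env(parent = emptyenv())

fixture_night <- function() {
  if (is.null(.fixture_env$night)) {
    .fixture_env$night <- simulate_night(seed = 101, n_epochs = 120)
  }
  .fixture_env$night
}

fixture_features <- function() {
  if (is.null(.fixture_env$features)) {
    .fixture_env$features <- prepare_night(fixture_night()$recording)
  }
  .fixture_env$features
}

fixture_model <- function() {
  if (is.null(.fixture_env$model)) {
    .fixture_env$model <- fit_stager(fixture_features(),
                                     fixture_night()$hypnogram,
                                     hyperparameters(n_estimators = 60))
  }
  .fixture_env$model
}

sine_epoch <- function(freq = 10, rate = 100, dur = 30, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq(1 / rate, dur, by = 1 / rate) + phase)
}

single_channel_rec <- function(x, rate = 100, role = "EEG", label = "C4-M1") {
  recording(list(list(label = label, role = role, samples = x, rate = rate)))
}
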