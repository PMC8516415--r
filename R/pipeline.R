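#' Prepare the staging feature matrix for one night
#'
#' Runs the full preprocessing and feature pipeline on a recording:
#' resample every channel to the analysis rate, bandpass filter, cut into
#' 30-s epochs, extract the raw per-epoch features and assemble the final
#' matrix (raw + smoothed-normalized variants + time-elapsed + optional
#' age/sex covariates).
#'
#' @param rec A [recording()].
#' @param meta Optional list with `age` and `sex` (see
#'   [assemble_features()]).
#' @param target_rate Analysis rate in Hz (default 100).
#' @param band Bandpass edges in Hz (default `c(0.4, 30)`).
#' @param epoch_len_s Epoch length in seconds (default 30).
#' @param cfg A [smoothing_config()].
#' @return Assembled feature data frame, one row per epoch.
#' @export
prepare_night <- function(rec, meta = NULL, target_rate = 100,
                          band = c(0.4, 30), epoch_len_s = 30,
                          cfg = smoothing_config()) {
  rec <- resample_recording(rec, target_rate)
  rec <- bandpass_recording(rec, band[1], band[2])
  channels <- epoch_recording(rec, epoch_len_s)
  ft <- extract_features(channels)
  assemble_features(ft, cfg = cfg, meta = meta)
}

#' Train a stage classifier on several nights
#'
#' Prepares features for each night independently (smoothing and
#' normalization never cross nights), stacks them, and fits the
#' class-weighted boosted ensemble.
#'
#' @param nights List of nights; each a list with elements `recording` and
#'   `hypnogram` (e.g. from [simulate_night()]).
#' @param hp [hyperparameters()].
#' @param meta Optional list of per-night `meta` lists.
#' @param ... Passed to [prepare_night()].
#' @return A `trained_stager`.
#' @export
train_stager <- function(nights, hp = hyperparameters(), meta = NULL, ...) {
  stopifnot(length(nights) >= 1)
  fts <- vector("list", length(nights))
  labs <- vector("list", length(nights))
  for (i in seq_along(nights)) {
    fts[[i]] <- prepare_night(nights[[i]]$recording,
                              meta = if (!is.null(meta)) meta[[i]], ...)
    labs[[i]] <- nights[[i]]$hypnogram
    if (nrow(fts[[i]]) != n_epochs(labs[[i]])) {
      stop("night ", i, ": feature rows (", nrow(fts[[i]]),
           ") do not match hypnogram epochs (", n_epochs(labs[[i]]), ")")
    }
  }
  features <- do.call(rbind, fts)
  all_lab <- hypnogram(unlist(lapply(labs, `[[`, "stages")),
                       unlist(lapply(labs, `[[`, "scored")),
                       labs[[1]]$epoch_len_s)
  fit_stager(features, all_lab, hp)
}

#' Stage one night
#'
#' Applies a trained classifier to a recording: full preprocessing +
#' feature pipeline, then per-epoch probabilities, confidence and the
#' predicted hypnogram.
#'
#' @param rec A [recording()].
#' @param model A `trained_stager`.
#' @param meta Optional `age`/`sex` list (must match how the model was
#'   trained).
#' @param ... Passed to [prepare_night()].
#' @return List: `hypnogram`, `probs` (a [stage_probs()]).
#' @export
stage_night <- function(rec, model, meta = NULL, ...) {
  ft <- prepare_night(rec, meta = meta, ...)
  probs <- predict_proba(model, ft)
  list(hypnogram = probs_to_hypnogram(probs), probs = probs)
}

#' End-to-end synthetic staging benchmark
#'
#' Generates independent synthetic training and testing nights, trains the
#' default classifier on the training set, stages every held-out night, and
#' evaluates each against its generative hypnogram with
#' [stratified_report()]. One master seed determines every night and the
#' model fit.
#'
#' @param n_train,n_test Numbers of training / held-out nights.
#' @param n_epochs Night length in epochs (default 960 = 8 h).
#' @param seed Master seed.
#' @param hp [hyperparameters()].
#' @return List: `reports` (per-test-night `eval_report`s), `summary`
#'   (median accuracy/kappa/MCC/macro-F1 and pooled stratified accuracies
#'   across the held-out nights), `model`.
#' @export
run_synthetic_benchmark <- function(n_train = 20, n_test = 5,
                                    n_epochs = 960, seed = 1,
                                    hp = hyperparameters()) {
  train_nights <- lapply(seq_len(n_train), function(i) {
    simulate_night(seed = derive_seed(seed, 10, i), n_epochs = n_epochs)
  })
  model <- train_stager(train_nights, hp = hp)
  reports <- vector("list", n_test)
  for (i in seq_len(n_test)) {
    night <- simulate_night(seed = derive_seed(seed, 20, i),
                            n_epochs = n_epochs)
    res <- stage_night(night$recording, model)
    reports[[i]] <- stratified_report(night$hypnogram, res$hypnogram,
                                      res$probs)
  }
  g <- function(field) vapply(reports, `[[`, numeric(1), field)
  summary <- list(
    median_accuracy = stats::median(g("accuracy")),
    median_kappa = stats::median(g("kappa")),
    median_mcc = stats::median(g("mcc")),
    median_f1_macro = stats::median(g("f1_macro")),
    mean_transition_accuracy = mean(g("transition_accuracy")),
    mean_stable_accuracy = mean(g("stable_accuracy")),
    mean_highconf_accuracy = mean(g("highconf_accuracy")),
    mean_lowconf_accuracy = mean(g("lowconf_accuracy")),
    mean_second_choice_accuracy = mean(g("second_choice_accuracy"),
                                       na.rm = TRUE),
    mean_highconf_fraction = mean(g("highconf_fraction"))
  )
  list(reports = reports, summary = summary, model = model)
}
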