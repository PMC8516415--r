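#' Stager hyperparameters
#'
#' Defaults are the selected configuration of the staging model: 500
#' boosting rounds, maximum tree depth 5, at most 90 leaves per tree, 60% of
#' features sampled per tree, and per-stage class weights
#' N1 = 2.2, N2 = 1, N3 = 1.2, R = 1.4, W = 1 that counteract the natural
#' imbalance of sleep stages (N2 is ~half of a typical night, N1 ~5%).
#'
#' @param n_estimators Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param num_leaves Maximum leaves per tree.
#' @param feature_fraction Fraction of features sampled per tree.
#' @param class_weights Named vector of per-stage sample weights.
#' @param learning_rate Shrinkage (backend default 0.1).
#' @param seed Integer seed for the boosting backend.
#' @return List of class `"stager_hp"`.
#' @export
hyperparameters <- function(n_estimators = 500, max_depth = 5,
                            num_leaves = 90, feature_fraction = 0.60,
                            class_weights = c(W = 1, N1 = 2.2, N2 = 1,
                                              N3 = 1.2, R = 1.4),
                            learning_rate = 0.1, seed = 42) {
  stopifnot(n_estimators >= 1, max_depth >= 1, num_leaves >= 2,
            feature_fraction > 0, feature_fraction <= 1)
  if (!all(stages() %in% names(class_weights))) {
    stop("class_weights must name every stage: ", paste(stages(), collapse = ", "))
  }
  if (any(class_weights <= 0)) stop("class weights must be positive")
  structure(list(n_estimators = n_estimators, max_depth = max_depth,
                 num_leaves = num_leaves, feature_fraction = feature_fraction,
                 class_weights = class_weights[stages()],
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "stager_hp")
}

#' Hyperparameter selection loss
#'
#' The model-selection criterion combines cross-validated accuracy and the
#' train/test gap: `|acc_train - acc_test| + 4 * (1 - acc_test)`. It is 0
#' exactly when both accuracies are 1. The gap term penalizes overfitting,
#' but is down-weighted by a factor of 4 relative to the test error, so the
#' selected model must above all be accurate on held-out data.
#'
#' @param acc_train,acc_test Accuracies in \[0, 1\].
#' @return Nonnegative scalar loss.
#' @export
selection_loss <- function(acc_train, acc_test) {
  if (any(c(acc_train, acc_test) < 0 | c(acc_train, acc_test) > 1)) {
    stop("accuracies must lie in [0, 1]")
  }
  abs(acc_train - acc_test) + 4 * (1 - acc_test)
}

#' Cartesian class-weight grid
#'
#' Expands a per-stage candidate list into the full Cartesian product of
#' class-weight combinations, in deterministic order (first stage varies
#' fastest). The default search space — N1 in \{1.6, 1.8, 2, 2.2\}, N2 in
#' \{0.8, 0.9, 1\}, and each of N3, R, W in \{1, 1.2, 1.4\} — yields 324
#' combinations.
#'
#' @param space Named list of numeric candidate vectors, one per stage.
#' @return List of named weight vectors.
#' @export
class_weight_grid <- function(space = default_class_weight_space()) {
  stopifnot(is.list(space), length(space) >= 1, !is.null(names(space)))
  if (any(vapply(space, length, integer(1)) == 0)) {
    stop("empty candidate list in class-weight space")
  }
  g <- expand.grid(space, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) unlist(g[i, , drop = FALSE]))
}

#' @rdname class_weight_grid
#' @export
default_class_weight_space <- function() {
  list(N1 = c(1.6, 1.8, 2, 2.2), N2 = c(0.8, 0.9, 1),
       N3 = c(1, 1.2, 1.4), R = c(1, 1.2, 1.4), W = c(1, 1.2, 1.4))
}

# ---- fitting ----------------------------------------------------------------

#' Fit the sleep-stage classifier
#'
#' Trains a class-weighted gradient-boosted tree ensemble (xgboost,
#' histogram tree method with leaf-wise growth) on an assembled feature
#' table and per-epoch stage labels. Stage weights are applied as
#' per-sample weights. Unscored epochs are excluded. Training is
#' deterministic for a fixed `hp$seed` on a single thread.
#'
#' @param features Assembled feature data frame ([assemble_features()]).
#' @param labels A [hypnogram()] with one label per feature row.
#' @param hp A [hyperparameters()] object.
#' @param nthread Number of training threads (default 1, deterministic).
#' @return Object of class `"trained_stager"` holding the fitted ensemble,
#'   the feature-name contract and the hyperparameters.
#' @export
fit_stager <- function(features, labels, hp = hyperparameters(), nthread = 1) {
  stopifnot(inherits(labels, "hypnogram"), inherits(hp, "stager_hp"))
  if (nrow(features) != length(labels$stages)) {
    stop("feature rows (", nrow(features), ") do not match label epochs (",
         length(labels$stages), ")")
  }
  keep <- labels$scored
  y <- stage_codes(labels)[keep] - 1L
  if (length(unique(y)) < 2) stop("need >= 2 distinct scored stages to fit")
  X <- as.matrix(features[keep, , drop = FALSE])
  storage.mode(X) <- "double"
  w <- hp$class_weights[y + 1L]
  dtrain <- xgboost::xgb.DMatrix(X, label = y, weight = w)
  params <- list(objective = "multi:softprob", num_class = 5L,
                 max_depth = hp$max_depth, max_leaves = hp$num_leaves,
                 grow_policy = "lossguide", tree_method = "hist",
                 colsample_bytree = hp$feature_fraction,
                 eta = hp$learning_rate, nthread = nthread, seed = hp$seed)
  booster <- xgboost::xgb.train(params, dtrain, nrounds = hp$n_estimators,
                                verbose = 0)
  structure(list(booster = booster, feature_names = colnames(features),
                 hp = hp, format = "somnostage-model", version = 1L),
            class = "trained_stager")
}

# align a feature table to the training feature-name contract
align_features <- function(m, features) {
  missing_ <- setdiff(m$feature_names, colnames(features))
  extra <- setdiff(colnames(features), m$feature_names)
  if (length(missing_) || length(extra)) {
    stop("feature names do not match the trained model",
         if (length(missing_)) paste0("; missing: ",
                                      paste(missing_, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")))
  }
  X <- as.matrix(features[, m$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Per-epoch stage probabilities
#'
#' @param m A `trained_stager`.
#' @param features Assembled feature data frame with exactly the training
#'   feature set (order-insensitive, matched by name).
#' @return Object of class `"stage_probs"`: `probs` (matrix, epochs x 5,
#'   canonical stage order, rows summing to 1) and `confidence` (row max).
#' @export
predict_proba <- function(m, features) {
  stopifnot(inherits(m, "trained_stager"))
  X <- align_features(m, features)
  p <- predict(m$booster, xgboost::xgb.DMatrix(X))
  p <- matrix(p, nrow = nrow(X), ncol = 5)
  p <- p / rowSums(p)
  colnames(p) <- stages()
  stage_probs(p)
}

#' Construct a stage-probability object
#'
#' @param p Matrix with 5 columns in canonical stage order; rows must be
#'   nonnegative and are renormalized to sum to 1.
#' @return Object of class `"stage_probs"`.
#' @export
stage_probs <- function(p) {
  p <- as.matrix(p)
  stopifnot(ncol(p) == 5, all(p >= 0))
  p <- p / rowSums(p)
  colnames(p) <- stages()
  structure(list(probs = p, confidence = apply(p, 1, max)),
            class = "stage_probs")
}

#' Predict a hypnogram
#'
#' Argmax over the per-epoch stage probabilities; ties are broken in favor
#' of the earlier canonical stage (W before N1 before ... R).
#'
#' @param object A `trained_stager`.
#' @param features Assembled feature data frame.
#' @param ... Unused.
#' @return A [hypnogram()].
#' @export
predict.trained_stager <- function(object, features, ...) {
  probs <- predict_proba(object, features)
  probs_to_hypnogram(probs)
}

#' @rdname predict.trained_stager
#' @param probs A `stage_probs` object.
#' @export
probs_to_hypnogram <- function(probs) {
  stopifnot(inherits(probs, "stage_probs"))
  idx <- max.col(probs$probs, ties.method = "first")
  hypnogram(stages()[idx])
}

# ---- importance -------------------------------------------------------------

#' Feature importance by stage-averaged absolute attribution
#'
#' Per-epoch Shapley-value attributions (xgboost `predcontrib`) are summed
#' in absolute value across all epochs separately for each stage's output,
#' then averaged across the five stages, giving one nonnegative score per
#' feature. If the attribution backend fails, split-gain importance is used
#' instead with a warning.
#'
#' @param m A `trained_stager`.
#' @param features Feature data frame to attribute over.
#' @return Named numeric vector, one score per feature, decreasing order.
#' @export
feature_importance <- function(m, features) {
  stopifnot(inherits(m, "trained_stager"))
  X <- align_features(m, features)
  contrib <- tryCatch(
    predict(m$booster, xgboost::xgb.DMatrix(X), predcontrib = TRUE),
    error = function(e) NULL
  )
  if (!is.null(contrib)) {
    # array: epochs x stages x (features + bias)
    per_stage <- apply(abs(contrib), c(2, 3), sum)
    score <- colMeans(per_stage)
    score <- score[seq_len(ncol(X))]
    names(score) <- m$feature_names
  } else {
    warning("attribution backend unavailable; falling back to split-gain importance")
    imp <- xgboost::xgb.importance(model = m$booster)
    score <- stats::setNames(rep(0, length(m$feature_names)), m$feature_names)
    score[imp$Feature] <- imp$Gain
  }
  sort(score, decreasing = TRUE)
}

# ---- persistence ------------------------------------------------------------

#' Save / load a trained stager
#'
#' The model is persisted as a versioned compressed archive embedding the
#' serialized ensemble, the feature-name contract and the hyperparameters;
#' loading refuses archives with an unknown format tag, and prediction
#' refuses feature sets that do not match the embedded names.
#'
#' @param m A `trained_stager`.
#' @param path Archive path (`.rds`).
#' @return `path` invisibly (save); the restored model (load).
#' @export
save_stager <- function(m, path) {
  stopifnot(inherits(m, "trained_stager"))
  obj <- list(format = m$format, version = m$version,
              feature_names = m$feature_names, hp = unclass(m$hp),
              booster_raw = xgboost::xgb.save.raw(m$booster))
  saveRDS(obj, path, compress = "gzip")
  invisible(path)
}

#' @rdname save_stager
#' @export
load_stager <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "somnostage-model")) {
    stop("not a somnostage model archive: ", path)
  }
  structure(list(booster = xgboost::xgb.load.raw(obj$booster_raw),
                 feature_names = obj$feature_names,
                 hp = structure(obj$hp, class = "stager_hp"),
                 format = obj$format, version = obj$version),
            class = "trained_stager")
}

# ---- cross-validated selection ----------------------------------------------

#' Cross-validated grid search over hyperparameters
#'
#' Generic threefold (by default) cross-validated search over a list of
#' hyperparameter candidates, minimizing [selection_loss()] (the gap-aware
#' criterion). Candidates are lists of arguments to [hyperparameters()].
#'
#' @param features Assembled feature data frame.
#' @param labels A [hypnogram()].
#' @param grid List of candidate hyperparameter argument lists.
#' @param nfolds Number of folds (default 3).
#' @param seed Seed controlling fold assignment.
#' @return List: `best` (the winning [hyperparameters()]), `scores` (data
#'   frame of per-candidate mean train/test accuracy and loss).
#' @export
cv_select_hyperparameters <- function(features, labels, grid, nfolds = 3,
                                      seed = 42) {
  scores <- lapply(grid, function(args) {
    hp <- do.call(hyperparameters, args)
    cv <- cv_accuracy(features, labels, hp, nfolds, seed)
    data.frame(acc_train = cv["train"], acc_test = cv["test"],
               loss = selection_loss(cv["train"], cv["test"]))
  })
  tab <- do.call(rbind, scores)
  rownames(tab) <- NULL
  best <- do.call(hyperparameters, grid[[which.min(tab$loss)]])
  list(best = best, scores = tab)
}

#' Cross-validated class-weight search
#'
#' Searches a class-weight grid by k-fold cross-validation, maximizing the
#' mean of accuracy and macro-F1 on held-out folds.
#'
#' @param features,labels,nfolds,seed As in [cv_select_hyperparameters()].
#' @param space Per-stage candidate lists ([default_class_weight_space()]).
#' @param base_hp Hyperparameters whose class weights are overridden.
#' @return List: `best` (winning weight vector), `scores` (per-candidate
#'   mean of accuracy and macro-F1).
#' @export
cv_select_class_weights <- function(features, labels,
                                    space = default_class_weight_space(),
                                    base_hp = hyperparameters(),
                                    nfolds = 3, seed = 42) {
  grid <- class_weight_grid(space)
  metric <- vapply(grid, function(wts) {
    hp <- do.call(hyperparameters, utils::modifyList(unclass(base_hp),
                                                     list(class_weights = wts)))
    cv_mean_acc_f1(features, labels, hp, nfolds, seed)
  }, numeric(1))
  list(best = grid[[which.max(metric)]],
       scores = data.frame(candidate = seq_along(grid), metric = metric))
}

cv_folds <- function(n, nfolds, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(nfolds), n))
}

cv_accuracy <- function(features, labels, hp, nfolds, seed) {
  keep <- which(labels$scored)
  fold <- cv_folds(length(keep), nfolds, seed)
  accs <- vapply(seq_len(nfolds), function(f) {
    tr <- keep[fold != f]; te <- keep[fold == f]
    m <- fit_stager(features[tr, , drop = FALSE], subset_hyp(labels, tr), hp)
    acc <- function(idx) {
      pred <- predict(m, features[idx, , drop = FALSE])
      mean(pred$stages == labels$stages[idx])
    }
    c(train = acc(tr), test = acc(te))
  }, numeric(2))
  rowMeans(accs)
}

cv_mean_acc_f1 <- function(features, labels, hp, nfolds, seed) {
  keep <- which(labels$scored)
  fold <- cv_folds(length(keep), nfolds, seed)
  vals <- vapply(seq_len(nfolds), function(f) {
    tr <- keep[fold != f]; te <- keep[fold == f]
    m <- fit_stager(features[tr, , drop = FALSE], subset_hyp(labels, tr), hp)
    pred <- predict(m, features[te, , drop = FALSE])
    cm <- confusion(subset_hyp(labels, te), pred)
    mean(c(agreement_scores(cm)[["accuracy"]], stage_f1(cm)$macro))
  }, numeric(1))
  mean(vals)
}

subset_hyp <- function(h, idx) {
  hypnogram(h$stages[idx], h$scored[idx], h$epoch_len_s)
}
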