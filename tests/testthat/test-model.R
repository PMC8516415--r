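test_that("selection loss follows the gap-plus-error formula", {
  expect_equal(selection_loss(1.0, 1.0), 0.0)
  expect_equal(selection_loss(0.9, 0.8), 0.9, tolerance = 1e-12)
  expect_equal(selection_loss(0.8, 0.8), 0.8, tolerance = 1e-12)
  expect_error(selection_loss(1.2, 0.5), "\\[0, 1\\]")
  expect_error(selection_loss(0.5, -0.1), "\\[0, 1\\]")
})

test_that("class-weight grid expands the full Cartesian product", {
  expect_length(class_weight_grid(), 324L)
  expect_length(class_weight_grid(list(N1 = 2.2, N2 = 1, N3 = 1, R = 1, W = 1)), 1L)
  g <- class_weight_grid(list(a = c(1, 2), b = c(1, 2, 3)))
  expect_length(g, 6L)
  # enumeration oracle: every pair occurs exactly once
  pairs <- unique(vapply(g, paste, character(1), collapse = "/"))
  expect_length(pairs, 6L)
  expect_error(class_weight_grid(list(a = numeric(0))), "empty")
})

test_that("default hyperparameters echo the selected configuration", {
  hp <- hyperparameters()
  expect_equal(hp$n_estimators, 500)
  expect_equal(hp$max_depth, 5)
  expect_equal(hp$num_leaves, 90)
  expect_equal(hp$feature_fraction, 0.60)
  expect_equal(hp$class_weights,
               c(W = 1, N1 = 2.2, N2 = 1, N3 = 1.2, R = 1.4))
  expect_error(hyperparameters(class_weights = c(W = 1)), "every stage")
})

test_that("a separable two-feature problem is learned essentially perfectly", {
  set.seed(55)
  n <- 100
  y <- rep(stages(), each = n / 5)
  ft <- data.frame(f1 = match(y, stages()) + rnorm(n, sd = 0.05),
                   f2 = rnorm(n))
  m <- fit_stager(ft, hypnogram(y), hyperparameters(n_estimators = 80))
  pred <- predict(m, ft)
  expect_gte(mean(pred$stages == y), 0.99)
  expect_error(fit_stager(ft, hypnogram(rep("N2", n))), "2 distinct")
  expect_error(fit_stager(ft[1:10, ], hypnogram(y)), "do not match")
})

test_that("probabilities are normalized, confidence is the row max, argmax matches predict", {
  ft <- fixture_features()
  m <- fixture_model()
  probs <- predict_proba(m, ft)
  expect_equal(rowSums(probs$probs), rep(1, nrow(ft)), tolerance = 1e-9)
  expect_true(all(probs$probs >= 0 & probs$probs <= 1))
  expect_equal(probs$confidence, apply(probs$probs, 1, max))
  expect_true(all(probs$confidence >= 0.2))
  pred <- predict(m, ft)
  expect_equal(pred$stages, stages()[max.col(probs$probs, "first")])
})

test_that("prediction refuses mismatched feature sets and names the difference", {
  ft <- fixture_features()
  m <- fixture_model()
  err <- expect_error(predict_proba(m, ft[, -3]), "missing")
  expect_match(conditionMessage(err), names(ft)[3])
  extra <- cbind(ft, bogus_feature = 1)
  expect_error(predict_proba(m, extra), "bogus_feature")
})

test_that("argmax ties break toward the earlier canonical stage", {
  p <- rbind(c(0.3, 0.3, 0.2, 0.1, 0.1),
             c(0.1, 0.2, 0.4, 0.2, 0.1),
             c(0.2, 0.2, 0.2, 0.2, 0.2))
  h <- probs_to_hypnogram(stage_probs(p))
  expect_equal(h$stages, c("W", "N2", "W"))
})

test_that("training is deterministic and unaffected by duplicating every row", {
  set.seed(66)
  n <- 80
  y <- sample(stages(), n, replace = TRUE, prob = c(2, 1, 3, 1, 1))
  ft <- data.frame(f1 = match(y, stages()) + rnorm(n, sd = 0.3),
                   f2 = rnorm(n), f3 = rnorm(n))
  hp <- hyperparameters(n_estimators = 40)
  m1 <- fit_stager(ft, hypnogram(y), hp)
  m2 <- fit_stager(ft, hypnogram(y), hp)
  probe <- data.frame(f1 = seq(0.5, 5.5, length.out = 20),
                      f2 = 0, f3 = 0)
  expect_identical(predict_proba(m1, probe)$probs,
                   predict_proba(m2, probe)$probs)
  # duplicating every row rescales all gradients uniformly: the predicted
  # stages are unchanged (histogram binning perturbs probabilities slightly)
  mdup <- fit_stager(rbind(ft, ft), hypnogram(c(y, y)), hp)
  expect_identical(predict(mdup, probe)$stages, predict(m1, probe)$stages)
  expect_equal(predict_proba(mdup, probe)$probs,
               predict_proba(m1, probe)$probs, tolerance = 0.1)
})

test_that("unscored epochs are excluded from training", {
  set.seed(77)
  n <- 60
  y <- rep(c("W", "N2", "N3"), each = n / 3)
  ft <- data.frame(f1 = match(y, stages()) + rnorm(n, sd = 0.05), f2 = rnorm(n))
  # poison the unscored epochs with wrong-looking features
  y2 <- y; y2[1:10] <- "UNS"
  m <- fit_stager(ft, hypnogram(y2), hyperparameters(n_estimators = 40))
  pred <- predict(m, ft)
  expect_gte(mean(pred$stages[11:n] == y[11:n]), 0.95)
})

test_that("model archives round-trip across sessions and refuse foreign files", {
  ft <- fixture_features()
  m <- fixture_model()
  f <- tempfile(fileext = ".rds")
  save_stager(m, f)
  m2 <- load_stager(f)
  expect_identical(predict_proba(m2, ft)$probs, predict_proba(m, ft)$probs)
  expect_identical(m2$feature_names, m$feature_names)
  junk <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), junk)
  expect_error(load_stager(junk), "not a somnostage model")
})

test_that("attribution importance ranks signal above noise and splits duplicates", {
  set.seed(88)
  n <- 150
  y <- sample(stages(), n, replace = TRUE)
  signal_ft <- match(y, stages()) + rnorm(n, sd = 0.2)
  ft <- data.frame(informative = signal_ft, noise = rnorm(n))
  hp <- hyperparameters(n_estimators = 60)
  m <- fit_stager(ft, hypnogram(y), hp)
  imp <- feature_importance(m, ft)
  expect_true(all(imp >= 0))
  expect_gt(imp[["informative"]], imp[["noise"]])
  # duplicated informative column: combined mass stays within 2x the original
  ft2 <- data.frame(informative = signal_ft, informative2 = signal_ft,
                    noise = rnorm(n))
  m2 <- fit_stager(ft2, hypnogram(y), hp)
  imp2 <- feature_importance(m2, ft2)
  expect_lte(imp2[["informative"]] + imp2[["informative2"]],
             2 * imp[["informative"]])
  expect_gt(imp2[["informative"]] + imp2[["informative2"]],
            imp2[["noise"]])
})

test_that("raising a stage's class weight does not lower its recall", {
  night <- fixture_night()
  ft <- fixture_features()
  st <- night$hypnogram$stages
  recall_n1 <- function(w_n1) {
    hp <- hyperparameters(n_estimators = 40,
                          class_weights = c(W = 1, N1 = w_n1, N2 = 1,
                                            N3 = 1, R = 1))
    m <- fit_stager(ft, night$hypnogram, hp)
    pred <- predict(m, ft)
    mean(pred$stages[st == "N1"] == "N1")
  }
  expect_gte(recall_n1(5), recall_n1(1))
})

test_that("cross-validated selection minimizes the gap-aware loss over a grid", {
  night <- fixture_night()
  ft <- fixture_features()
  grid <- list(list(n_estimators = 15, max_depth = 2),
               list(n_estimators = 30, max_depth = 3))
  sel <- cv_select_hyperparameters(ft, night$hypnogram, grid, nfolds = 3,
                                   seed = 5)
  expect_s3_class(sel$best, "stager_hp")
  expect_equal(nrow(sel$scores), 2L)
  expect_equal(which.min(sel$scores$loss),
               match(sel$best$n_estimators, c(15, 30)))
  expect_equal(sel$scores$loss,
               abs(sel$scores$acc_train - sel$scores$acc_test) +
                 4 * (1 - sel$scores$acc_test))
})
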