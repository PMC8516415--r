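test_that("confusion matrices tally jointly scored epochs", {
  h <- random_hypnogram(50)
  cm <- confusion(h, h)
  expect_equal(sum(diag(cm)), 50)
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  ref <- hypnogram(rep("N2", 20)); pred <- hypnogram(rep("N3", 20))
  cm2 <- confusion(ref, pred)
  expect_equal(cm2["N2", "N3"], 20L)
  expect_equal(sum(cm2), 20)
  expect_error(confusion(h, hypnogram(rep("W", 10))), "lengths differ")
  expect_error(confusion(hypnogram(rep("UNS", 5)), hypnogram(rep("W", 5))),
               "no jointly scored")
})

test_that("unscored epochs in either hypnogram are excluded from the tally", {
  ref <- hypnogram(c("W", "N2", "UNS", "N3"))
  pred <- hypnogram(c("W", "UNS", "N2", "N3"))
  cm <- confusion(ref, pred)
  expect_equal(sum(cm), 2)
  expect_equal(cm["W", "W"], 1L)
  expect_equal(cm["N3", "N3"], 1L)
})

test_that("perfect agreement scores (1, 1, 1); constant prediction scores kappa 0", {
  cm <- diag(c(10L, 8L, 30L, 9L, 12L))
  s <- agreement_scores(cm)
  expect_equal(unname(s), c(1, 1, 1))
  # balanced reference, constant prediction: chance-level kappa
  cm0 <- matrix(0L, 5, 5); cm0[, 3] <- 10L
  s0 <- agreement_scores(cm0)
  expect_equal(s0[["kappa"]], 0)
  expect_equal(s0[["accuracy"]], 0.2)
})

test_that("an embedded two-class problem matches the closed-form scores", {
  cm <- matrix(0L, 5, 5, dimnames = list(stages(), stages()))
  cm[2, 2] <- 40L; cm[2, 3] <- 10L; cm[3, 2] <- 5L; cm[3, 3] <- 45L
  s <- agreement_scores(cm)
  # hand-computed: po = 85/100; pe = (50*45 + 50*55)/100^2 = 0.5
  expect_equal(s[["accuracy"]], 0.85)
  expect_equal(s[["kappa"]], (0.85 - 0.5) / 0.5)
  # binary MCC closed form on the 2x2 block
  mcc <- (40 * 45 - 10 * 5) / sqrt(50 * 50 * 45 * 55)
  expect_equal(s[["mcc"]], mcc, tolerance = 1e-12)
})

test_that("F1 is the harmonic mean of precision and sensitivity", {
  cm <- matrix(0L, 5, 5)
  cm[1, 1] <- 5L; cm[1, 2] <- 5L; cm[2, 1] <- 5L; cm[2, 2] <- 5L
  f <- stage_f1(cm)
  expect_equal(f$per_stage[["W"]], 0.5)   # precision = sensitivity = 0.5
  perfect <- stage_f1(diag(c(2L, 2L, 2L, 2L, 2L)))
  expect_equal(unname(perfect$per_stage), rep(1, 5))
  expect_equal(perfect$macro, 1)
})

test_that("stages absent from both scorings are excluded from the macro mean", {
  cm <- matrix(0L, 5, 5)
  cm[1, 1] <- 10L; cm[3, 3] <- 5L; cm[3, 1] <- 5L
  f <- stage_f1(cm)
  expect_true(is.na(f$per_stage[["R"]]))
  present <- f$per_stage[!is.na(f$per_stage)]
  expect_equal(f$macro, mean(present))
})

test_that("agreement and F1 match brute-force oracles on 1000 random matrices", {
  set.seed(71)
  for (i in 1:1000) {
    cm <- random_confusion()
    expect_equal(agreement_scores(cm), oracle_scores(cm), tolerance = 1e-9)
    expect_equal(stage_f1(cm)$per_stage, oracle_f1(cm), tolerance = 1e-12)
  }
})

test_that("confusion matches the brute-force tally on random hypnogram pairs", {
  set.seed(73)
  for (i in 1:200) {
    ref <- random_hypnogram(40, p_uns = 0.1)
    pred <- random_hypnogram(40, p_uns = 0.1)
    expect_equal(unclass(confusion(ref, pred)), oracle_confusion(ref, pred),
                 ignore_attr = TRUE)
  }
})

test_that("transition masking flags the 3-minute neighborhood of stage changes", {
  expect_false(any(transition_mask(hypnogram(rep("N2", 30)))))
  # single transition between epochs 10 and 11: epochs 8..13 flagged
  h <- hypnogram(c(rep("N2", 10), rep("N3", 20)))
  m <- transition_mask(h)
  expect_equal(which(m), 8:13)
  alternating <- hypnogram(rep(c("N2", "N3"), 15))
  expect_true(all(transition_mask(alternating)))
  expect_error(transition_mask(h, window_min = 0.4), "multiple")
})

test_that("transition masks match a brute-force boundary scan on random nights", {
  set.seed(79)
  for (i in 1:100) {
    h <- random_hypnogram(25)
    expect_equal(transition_mask(h), oracle_transition_mask(h))
  }
})

test_that("the stage-transition fraction is invariant under relabeling", {
  set.seed(83)
  h <- random_hypnogram(100)
  relabel <- c(W = "N3", N1 = "R", N2 = "W", N3 = "N1", R = "N2")
  h2 <- hypnogram(unname(relabel[h$stages]))
  expect_equal(transition_fraction(h), transition_fraction(h2))
})

test_that("stratified accuracies recombine into the overall correct count", {
  set.seed(89)
  n <- 200
  # blocky hypnogram so both stable and transition epochs exist
  ref <- hypnogram(rep(sample(stages(), 20, replace = TRUE), each = 10))
  pred_lab <- ref$stages
  flip <- runif(n) < 0.2
  pred_lab[flip] <- sample(stages(), sum(flip), replace = TRUE)
  pred <- hypnogram(pred_lab)
  # mix of sharp (high-confidence) and flat probability rows
  p <- matrix(runif(n * 5), n, 5)
  sharp <- seq_len(n) %% 2 == 0
  p[sharp, ] <- 0.02
  p[cbind(which(sharp), sample(5, sum(sharp), replace = TRUE))] <- 0.92
  probs <- stage_probs(p)
  rep_ <- stratified_report(ref, pred, probs)
  tmask <- transition_mask(ref)
  correct <- sum(ref$stages == pred$stages)
  trans_correct <- rep_$transition_accuracy * sum(tmask)
  stable_correct <- rep_$stable_accuracy * sum(!tmask)
  expect_equal(trans_correct + stable_correct, correct, tolerance = 1e-9)
  high <- probs$confidence >= 0.8
  hi_c <- rep_$highconf_accuracy * sum(high)
  lo_c <- rep_$lowconf_accuracy * sum(!high)
  expect_equal(hi_c + lo_c, correct, tolerance = 1e-9)
  expect_error(stratified_report(ref, pred, probs, conf_threshold = 1.2),
               "strictly between")
})

test_that("second-choice accuracy ranks the runner-up stage of misclassified epochs", {
  ref <- hypnogram(c("N2", "N2", "N3", "W"))
  pred <- hypnogram(c("N2", "N3", "N2", "W"))
  # errors at epochs 2 and 3; runner-up equals the reference at both
  p <- rbind(c(0.05, 0.05, 0.80, 0.05, 0.05),
             c(0.05, 0.05, 0.30, 0.55, 0.05),
             c(0.05, 0.05, 0.50, 0.35, 0.05),
             c(0.80, 0.05, 0.05, 0.05, 0.05))
  r <- stratified_report(ref, pred, stage_probs(p))
  expect_equal(r$second_choice_accuracy, 1)
  r_perfect <- stratified_report(ref, ref, stage_probs(p))
  expect_true(is.na(r_perfect$second_choice_accuracy))
})

test_that("Holm adjustment matches the hand-computed step-down", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  set.seed(97)
  for (i in 1:200) {
    p <- runif(sample(1:8, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, oracle_holm(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))   # order preserved
  }
  expect_error(holm_adjust(c(0.5, 1.3)), "\\[0, 1\\]")
})
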