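#' Epoch-by-epoch confusion matrix
#'
#' Tallies reference vs predicted stages over the epochs scored in both
#' hypnograms (rows = reference, columns = prediction, canonical stage
#' order). Epochs unscored in either hypnogram are excluded.
#'
#' @param ref,pred [hypnogram()]s of equal length.
#' @return 5x5 integer matrix of class `"stage_confusion"`.
#' @export
confusion <- function(ref, pred) {
  stopifnot(inherits(ref, "hypnogram"), inherits(pred, "hypnogram"))
  if (n_epochs(ref) != n_epochs(pred)) {
    stop("hypnogram lengths differ: ", n_epochs(ref), " vs ", n_epochs(pred))
  }
  both <- ref$scored & pred$scored
  if (!any(both)) stop("no jointly scored epochs")
  cm <- table(factor(ref$stages[both], levels = stages()),
              factor(pred$stages[both], levels = stages()))
  cm <- unclass(as.matrix(cm))
  storage.mode(cm) <- "integer"
  structure(cm, class = c("stage_confusion", class(cm)))
}

#' Agreement scores from a confusion matrix
#'
#' Textbook multiclass accuracy, Cohen's kappa and Matthews correlation
#' coefficient. Degenerate cases are guarded: when chance agreement is 1
#' (both scorings constant), kappa is 1 if observed agreement is 1 and 0
#' otherwise; an MCC denominator of 0 gives MCC 0.
#'
#' @param cm A 5x5 confusion matrix ([confusion()]).
#' @return Named vector `accuracy`, `kappa`, `mcc`.
#' @export
agreement_scores <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / n
  rs <- rowSums(cm); cs <- colSums(cm)
  pe <- sum(rs * cs) / n^2
  kappa <- if (abs(1 - pe) < 1e-15) {
    if (abs(po - 1) < 1e-15) 1 else 0
  } else {
    (po - pe) / (1 - pe)
  }
  # multiclass MCC
  num <- sum(diag(cm)) * n - sum(rs * cs)
  den <- sqrt(n^2 - sum(cs^2)) * sqrt(n^2 - sum(rs^2))
  mcc <- if (den == 0) 0 else num / den
  c(accuracy = po, kappa = kappa, mcc = mcc)
}

#' Per-stage and macro F1 scores
#'
#' One-vs-rest precision and sensitivity per stage; F1 is their harmonic
#' mean. Stages absent from both reference and prediction are excluded
#' from the macro average; a stage that is present but never correctly
#' predicted scores 0.
#'
#' @param cm A 5x5 confusion matrix.
#' @return List with `per_stage` (named vector, `NA` for absent stages) and
#'   `macro`.
#' @export
stage_f1 <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) == 0) stop("empty confusion matrix")
  tp <- diag(cm); rs <- rowSums(cm); cs <- colSums(cm)
  f1 <- ifelse(rs + cs > 0, 2 * tp / (rs + cs), NA_real_)
  names(f1) <- stages()
  list(per_stage = f1, macro = mean(f1, na.rm = TRUE))
}

#' Transition-epoch mask
#'
#' Flags every epoch that lies within `window_min / 2` minutes of a stage
#' transition in the hypnogram (default 3-minute window: 1.5 min before,
#' 1.5 min after). With boundaries indexed between epochs `i` and `i + 1`,
#' epoch `e` is flagged when a boundary `b` with differing stages exists in
#' `[e - half, e + half - 1]`, `half` being the window half-width in epochs
#' (3 for the default 3-min window of 30-s epochs).
#'
#' @param hyp A [hypnogram()].
#' @param window_min Full window in minutes; `window_min * 60` must be a
#'   multiple of twice the epoch length.
#' @return Logical vector, one flag per epoch.
#' @export
transition_mask <- function(hyp, window_min = 3) {
  stopifnot(inherits(hyp, "hypnogram"))
  half_s <- window_min * 60 / 2
  half <- half_s / hyp$epoch_len_s
  if (abs(half - round(half)) > 1e-9 || half < 1) {
    stop("window (", window_min, " min) must be a positive multiple of ",
         "twice the epoch length")
  }
  half <- as.integer(round(half))
  n <- n_epochs(hyp)
  s <- hyp$stages
  bounds <- which(s[-1] != s[-n])      # boundary b sits between b and b+1
  mask <- logical(n)
  for (b in bounds) {
    lo <- max(1, b - half + 1)
    hi <- min(n, b + half)
    mask[lo:hi] <- TRUE
  }
  mask
}

#' Percentage of stage transitions in a hypnogram
#'
#' Fraction of consecutive scored epoch pairs whose stages differ —
#' a simple sleep-fragmentation index, invariant under stage relabeling.
#'
#' @param hyp A [hypnogram()].
#' @return Proportion in \[0, 1\].
#' @export
transition_fraction <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  s <- hyp$stages[hyp$scored]
  if (length(s) < 2) return(0)
  mean(s[-1] != s[-length(s)])
}

#' Full stratified evaluation report
#'
#' Epoch-by-epoch evaluation of a predicted hypnogram against a reference:
#' overall accuracy/kappa/MCC, per-stage and macro F1, reference and
#' predicted stage proportions, accuracy stratified by transition vs stable
#' epochs (reference-defined, [transition_mask()]) and by algorithm
#' confidence (at or above vs below `conf_threshold`), and the
#' second-choice accuracy — among misclassified epochs, the fraction whose
#' runner-up probability stage is the reference stage (`NA` when there are
#' no misclassified epochs).
#'
#' @param ref,pred [hypnogram()]s of equal length.
#' @param probs Optional [stage_probs()] aligned with `pred`.
#' @param conf_threshold High-confidence threshold in (0, 1), default 0.80.
#' @return List of class `"eval_report"`.
#' @export
stratified_report <- function(ref, pred, probs = NULL, conf_threshold = 0.80) {
  if (conf_threshold <= 0 || conf_threshold >= 1) {
    stop("conf_threshold must lie strictly between 0 and 1")
  }
  cm <- confusion(ref, pred)
  scores <- agreement_scores(cm)
  f1 <- stage_f1(cm)
  both <- ref$scored & pred$scored
  correct <- ref$stages == pred$stages & both
  acc_on <- function(mask) {
    m <- mask & both
    if (!any(m)) return(NA_real_)
    mean(ref$stages[m] == pred$stages[m])
  }
  tmask <- transition_mask(ref)
  rep <- list(
    confusion = cm,
    accuracy = scores[["accuracy"]], kappa = scores[["kappa"]],
    mcc = scores[["mcc"]],
    f1_per_stage = f1$per_stage, f1_macro = f1$macro,
    stage_proportions = rbind(
      ref = prop.table(table(factor(ref$stages[both], levels = stages()))),
      pred = prop.table(table(factor(pred$stages[both], levels = stages())))),
    transition_accuracy = acc_on(tmask),
    stable_accuracy = acc_on(!tmask),
    transition_fraction_ref = transition_fraction(ref),
    transition_fraction_pred = transition_fraction(pred)
  )
  if (!is.null(probs)) {
    stopifnot(inherits(probs, "stage_probs"))
    if (nrow(probs$probs) != n_epochs(pred)) {
      stop("probability rows do not match hypnogram length")
    }
    high <- probs$confidence >= conf_threshold
    rep$highconf_accuracy <- acc_on(high)
    rep$lowconf_accuracy <- acc_on(!high)
    rep$highconf_fraction <- mean(high[both])
    err <- both & !correct
    if (any(err)) {
      ord2 <- apply(probs$probs[err, , drop = FALSE], 1,
                    function(p) stages()[order(p, decreasing = TRUE)[2]])
      rep$second_choice_accuracy <- mean(ord2 == ref$stages[err])
    } else {
      rep$second_choice_accuracy <- NA_real_
    }
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f | kappa %.3f | MCC %.3f | macro-F1 %.3f\n",
              x$accuracy, x$kappa, x$mcc, x$f1_macro))
  cat("F1 per stage: ",
      paste(sprintf("%s %.3f", names(x$f1_per_stage), x$f1_per_stage),
            collapse = "  "), "\n")
  cat(sprintf("accuracy: stable %.3f / transition %.3f",
              x$stable_accuracy, x$transition_accuracy))
  if (!is.null(x$highconf_accuracy)) {
    cat(sprintf(" | high-conf %.3f / low-conf %.3f",
                x$highconf_accuracy, x$lowconf_accuracy))
  }
  cat("\n")
  invisible(x)
}

#' Holm step-down multiple-comparison adjustment
#'
#' Adjusts a vector of p-values with the Holm method (via
#' [stats::p.adjust()]), after validating the input range.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "holm")
}
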