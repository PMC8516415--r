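#' Construct a scorer panel
#'
#' A panel of hypnograms of one night scored independently by several human
#' scorers, for consensus construction and interrater analysis.
#'
#' @param hypnograms List of >= 2 [hypnogram()]s of equal length and epoch
#'   length.
#' @param scorer_ids Optional character labels (default `scorer1`, ...).
#' @return Object of class `"scorer_panel"`.
#' @export
scorer_panel <- function(hypnograms, scorer_ids = NULL) {
  stopifnot(is.list(hypnograms), length(hypnograms) >= 2)
  lens <- vapply(hypnograms, n_epochs, integer(1))
  if (length(unique(lens)) != 1) stop("hypnograms differ in epoch count")
  els <- vapply(hypnograms, function(h) h$epoch_len_s, numeric(1))
  if (length(unique(els)) != 1) stop("hypnograms differ in epoch length")
  if (is.null(scorer_ids)) scorer_ids <- paste0("scorer", seq_along(hypnograms))
  stopifnot(length(scorer_ids) == length(hypnograms))
  structure(list(hypnograms = hypnograms, scorer_ids = scorer_ids),
            class = "scorer_panel")
}

n_scorers <- function(panel) length(panel$hypnograms)

#' Pairwise interscorer agreement matrix
#'
#' Entry (i, j) is the fraction of epochs scored by both scorers i and j on
#' which they assigned the same stage. The matrix is symmetric with unit
#' diagonal.
#'
#' @param panel A [scorer_panel()].
#' @return Numeric matrix `n_scorers x n_scorers`.
#' @export
pairwise_agreement <- function(panel) {
  stopifnot(inherits(panel, "scorer_panel"))
  k <- n_scorers(panel)
  A <- diag(1, k)
  for (i in seq_len(k - 1)) {
    hi <- panel$hypnograms[[i]]
    for (j in (i + 1):k) {
      hj <- panel$hypnograms[[j]]
      both <- hi$scored & hj$scored
      if (!any(both)) {
        stop("scorers ", i, " and ", j, " share no scored epochs")
      }
      A[i, j] <- A[j, i] <- mean(hi$stages[both] == hj$stages[both])
    }
  }
  dimnames(A) <- list(panel$scorer_ids, panel$scorer_ids)
  A
}

#' Most reliable scorer of a panel
#'
#' The scorer with the highest average agreement with all the other
#' scorers. Ties are broken toward the lowest scorer index (deterministic).
#'
#' @param panel A [scorer_panel()] with >= 3 scorers.
#' @return Integer scorer index.
#' @export
most_reliable <- function(panel) {
  stopifnot(inherits(panel, "scorer_panel"))
  if (n_scorers(panel) < 3) stop("reliability needs >= 3 scorers")
  A <- pairwise_agreement(panel)
  mean_others <- (rowSums(A) - 1) / (n_scorers(panel) - 1)
  # round away float noise so exact reliability ties resolve by index
  unname(which.max(round(mean_others, 12)))
}

#' Consensus hypnogram by per-epoch plurality vote
#'
#' Each epoch takes the most voted stage among the scorers who scored it.
#' When the top vote is tied, the label of the night's most reliable scorer
#' is used, provided it is one of the tied stages (it virtually always is);
#' otherwise the tied stage earliest in canonical order is taken, so the
#' consensus stage always carries at least as many votes as any other.
#' Epochs scored by no one are unscored in the consensus.
#'
#' @param panel A [scorer_panel()] with >= 3 scorers.
#' @return A [hypnogram()].
#' @export
consensus_hypnogram <- function(panel) {
  stopifnot(inherits(panel, "scorer_panel"))
  if (n_scorers(panel) < 3) stop("consensus needs >= 3 scorers")
  ref <- most_reliable(panel)
  n <- n_epochs(panel$hypnograms[[1]])
  k <- n_scorers(panel)
  lab <- matrix(vapply(panel$hypnograms, function(h) {
    ifelse(h$scored, h$stages, NA_character_)
  }, character(n)), nrow = n)
  out <- character(n)
  ref_lab <- lab[, ref]
  for (e in seq_len(n)) {
    votes <- lab[e, ]
    votes <- votes[!is.na(votes)]
    if (length(votes) == 0) { out[e] <- UNSCORED; next }
    tab <- table(factor(votes, levels = stages()))
    top <- stages()[tab == max(tab)]
    out[e] <- if (length(top) == 1) {
      top
    } else if (!is.na(ref_lab[e]) && ref_lab[e] %in% top) {
      ref_lab[e]
    } else {
      top[1]
    }
  }
  hypnogram(out, epoch_len_s = panel$hypnograms[[1]]$epoch_len_s)
}

#' Leave-one-out (unbiased) consensus
#'
#' Consensus of the N-1 scorers remaining after excluding one — the
#' reference against which that scorer can be evaluated without
#' self-agreement bias. Ties are broken by the most reliable of the N-1
#' remaining scorers.
#'
#' @param panel A [scorer_panel()] with >= 4 scorers.
#' @param excluded Index of the scorer to leave out.
#' @return A [hypnogram()].
#' @export
loo_consensus <- function(panel, excluded) {
  stopifnot(inherits(panel, "scorer_panel"))
  if (n_scorers(panel) < 4) stop("leave-one-out consensus needs >= 4 scorers")
  stopifnot(excluded >= 1, excluded <= n_scorers(panel))
  rest <- scorer_panel(panel$hypnograms[-excluded],
                       panel$scorer_ids[-excluded])
  consensus_hypnogram(rest)
}
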