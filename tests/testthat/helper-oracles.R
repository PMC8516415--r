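# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately take the most naive route available
# (per-epoch loops, indicator covariances, textbook step-down) so they share
# no code path with the functions under test.

oracle_confusion <- function(ref, pred) {
  cm <- matrix(0L, 5, 5, dimnames = list(stages(), stages()))
  for (e in seq_along(ref$stages)) {
    if (ref$scored[e] && pred$scored[e]) {
      i <- match(ref$stages[e], stages())
      j <- match(pred$stages[e], stages())
      cm[i, j] <- cm[i, j] + 1L
    }
  }
  cm
}

# accuracy/kappa from observed vs chance agreement; MCC from the indicator
# covariance definition (a route independent of the confusion-count formula)
oracle_scores <- function(cm) {
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kap <- if (abs(1 - pe) < 1e-15) {
    if (abs(acc - 1) < 1e-15) 1 else 0
  } else {
    (acc - pe) / (1 - pe)
  }
  # rebuild label vectors and compute MCC as the correlation of one-hot codes
  refs <- rep(rep(seq_len(5), 5), times = as.vector(t(cm)))
  preds <- rep(rep(seq_len(5), each = 5), times = as.vector(t(cm)))
  X <- outer(refs, 1:5, "==") * 1
  Y <- outer(preds, 1:5, "==") * 1
  cov_sum <- function(A, B) {
    sum(vapply(1:5, function(k) {
      stats::cov(A[, k], B[, k]) * (n - 1)
    }, numeric(1)))
  }
  den <- sqrt(cov_sum(X, X) * cov_sum(Y, Y))
  mcc <- if (den == 0) 0 else cov_sum(X, Y) / den
  c(accuracy = acc, kappa = kap, mcc = mcc)
}

oracle_f1 <- function(cm) {
  out <- rep(NA_real_, 5)
  for (k in 1:5) {
    tp <- cm[k, k]
    pred_k <- sum(cm[, k]); ref_k <- sum(cm[k, ])
    if (pred_k + ref_k == 0) next
    prec <- if (pred_k > 0) tp / pred_k else 0
    sens <- if (ref_k > 0) tp / ref_k else 0
    out[k] <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  }
  names(out) <- stages()
  out
}

oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}

oracle_transition_mask <- function(hyp, half = 3) {
  s <- hyp$stages
  n <- length(s)
  mask <- logical(n)
  for (e in seq_len(n)) {
    for (b in seq_len(n - 1)) {
      if (s[b] != s[b + 1] && b >= e - half && b <= e + half - 1) {
        mask[e] <- TRUE
        break
      }
    }
  }
  mask
}

# plurality vote with most-reliable tie-break, written as plain loops
oracle_consensus <- function(panel) {
  k <- length(panel$hypnograms)
  n <- n_epochs(panel$hypnograms[[1]])
  A <- matrix(1, k, k)
  for (i in 1:k) for (j in 1:k) {
    hi <- panel$hypnograms[[i]]; hj <- panel$hypnograms[[j]]
    both <- hi$scored & hj$scored
    A[i, j] <- mean(hi$stages[both] == hj$stages[both])
  }
  rel <- sapply(1:k, function(i) mean(A[i, -i]))
  best <- which.max(round(rel, 12))
  out <- character(n)
  for (e in 1:n) {
    votes <- character(0)
    for (i in 1:k) {
      if (panel$hypnograms[[i]]$scored[e]) {
        votes <- c(votes, panel$hypnograms[[i]]$stages[e])
      }
    }
    if (!length(votes)) { out[e] <- "UNS"; next }
    counts <- sapply(stages(), function(st) sum(votes == st))
    top <- stages()[counts == max(counts)]
    if (length(top) == 1) {
      out[e] <- top
    } else {
      rl <- panel$hypnograms[[best]]
      out[e] <- if (rl$scored[e] && rl$stages[e] %in% top) rl$stages[e] else top[1]
    }
  }
  out
}

random_hypnogram <- function(n, epoch_len_s = 30, p_uns = 0) {
  labs <- sample(stages(), n, replace = TRUE)
  if (p_uns > 0) {
    labs[stats::runif(n) < p_uns] <- "UNS"
  }
  hypnogram(labs, epoch_len_s = epoch_len_s)
}

random_confusion <- function(max_count = 20) {
  cm <- matrix(sample(0:max_count, 25, replace = TRUE), 5, 5)
  if (sum(cm) == 0) cm[1, 1] <- 1L
  storage.mode(cm) <- "integer"
  dimnames(cm) <- list(stages(), stages())
  cm
}
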