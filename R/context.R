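#' Triangular window weights
#'
#' Symmetric triangular weights for the centered rolling average: a linear
#' ramp in steps of `1/((n+1)/2)` up to 1 at the center and back down. For
#' `n = 15` (the default 7.5-min window of 30-s epochs) this is
#' `c(0.125, 0.25, ..., 0.875, 1, 0.875, ..., 0.125)`.
#'
#' @param n Odd window length in epochs.
#' @return Numeric vector of length `n`.
#' @export
triangular_weights <- function(n) {
  if (n %% 2 == 0 || n < 1) stop("`n` must be odd and >= 1")
  half <- (n + 1) / 2
  ramp <- seq_len(half) / half
  c(ramp, rev(ramp)[-1])
}

#' Smoothing configuration
#'
#' @param centered_len_epochs Length of the centered triangular window in
#'   epochs (odd; default 15 = 7.5 min of 30-s epochs).
#' @param past_len_epochs Length of the trailing mean window in epochs
#'   (default 4 = 2 min), excluding the current epoch.
#' @return List with the window lengths and the centered weights.
#' @export
smoothing_config <- function(centered_len_epochs = 15, past_len_epochs = 4) {
  stopifnot(centered_len_epochs %% 2 == 1, past_len_epochs >= 1)
  list(centered_len_epochs = centered_len_epochs,
       past_len_epochs = past_len_epochs,
       centered_weights = triangular_weights(centered_len_epochs))
}

#' Smooth a feature table with a rolling window
#'
#' Two temporal-context smoothers are available. `"centered_triangular"`
#' replaces each epoch's value by the triangular-weighted average over the
#' centered window; at the night's edges the window is truncated to
#' in-range epochs and the weights renormalized (no padding, the window
#' never looks outside the night). `"past_mean"` replaces each value by the
#' unweighted mean of up to `past_len_epochs` epochs strictly before the
#' current one; the first epoch, having no past, keeps its own value.
#'
#' @param ft Data frame of per-epoch features (all columns numeric).
#' @param mode `"centered_triangular"` or `"past_mean"`.
#' @param cfg A [smoothing_config()].
#' @return Data frame of the same shape.
#' @export
smooth_features <- function(ft, mode = c("centered_triangular", "past_mean"),
                            cfg = smoothing_config()) {
  mode <- match.arg(mode)
  X <- as.matrix(ft)
  n <- nrow(X)
  if (n < 1) stop("empty feature table")
  out <- switch(mode,
    centered_triangular = smooth_centered(X, cfg$centered_weights),
    past_mean = smooth_past(X, cfg$past_len_epochs)
  )
  res <- as.data.frame(out)
  names(res) <- names(ft)
  res
}

smooth_centered <- function(X, w) {
  n <- nrow(X)
  half <- (length(w) - 1) / 2
  out <- matrix(0, n, ncol(X))
  full <- X * 0
  # interior epochs share one weight vector; edge epochs renormalize over
  # the in-range subset
  for (e in seq_len(n)) {
    lo <- max(1, e - half); hi <- min(n, e + half)
    wi <- w[(lo - e + half + 1):(hi - e + half + 1)]
    wi <- wi / sum(wi)
    out[e, ] <- wi %*% X[lo:hi, , drop = FALSE]
  }
  out
}

smooth_past <- function(X, k) {
  n <- nrow(X)
  cs <- rbind(0, apply(X, 2, cumsum))
  out <- matrix(0, n, ncol(X))
  out[1, ] <- X[1, ]                       # no past: fall back to current
  for (e in 2:max(2, n)) {
    if (e > n) break
    lo <- max(1, e - k)
    out[e, ] <- (cs[e, ] - cs[lo, ]) / (e - lo)
  }
  out
}

#' Z-score features across the night
#'
#' Expresses each column as a deviation from the night's mean in units of
#' the night's standard deviation, accommodating between-individual
#' differences in absolute signal characteristics. Zero-variance columns
#' map to all-zeros.
#'
#' @param ft Data frame of per-epoch features (>= 2 epochs).
#' @return Data frame of the same shape with columns of mean 0 and (when
#'   non-degenerate) standard deviation 1.
#' @export
znorm_night <- function(ft) {
  X <- as.matrix(ft)
  if (nrow(X) < 2) stop("per-night z-scoring needs >= 2 epochs")
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  Z <- sweep(X, 2, mu)
  Z <- sweep(Z, 2, ifelse(sd_ > 0, sd_, 1), "/")
  Z[, sd_ == 0] <- 0
  res <- as.data.frame(Z)
  names(res) <- names(ft)
  res
}

#' Assemble the full per-night feature matrix
#'
#' Builds the final design matrix from the raw per-epoch features: the raw
#' columns (untouched, for temporal specificity and cross-night
#' comparability), a centered-triangular-smoothed copy and a trailing-mean
#' copy — both z-scored across the night (suffixes `_c7min_norm` and
#' `_p2min_norm`) — plus `time_elapsed` (epoch index normalized 0 to 1
#' across the night) and, when supplied, constant `age` and `sex`
#' covariates (`sex`: 1 = male, 0 = female).
#'
#' @param ft_raw Raw feature data frame from [extract_features()].
#' @param cfg A [smoothing_config()].
#' @param meta Optional list with numeric `age` (years) and `sex` (0/1).
#' @return Data frame with deterministic column order.
#' @export
assemble_features <- function(ft_raw, cfg = smoothing_config(), meta = NULL) {
  n <- nrow(ft_raw)
  if (n < 2) stop("need >= 2 epochs to assemble a night's features")
  if (n < cfg$centered_len_epochs) {
    warning("night (", n, " epochs) shorter than the centered smoothing ",
            "window (", cfg$centered_len_epochs, "); windows fully truncated")
  }
  cent <- znorm_night(smooth_features(ft_raw, "centered_triangular", cfg))
  past <- znorm_night(smooth_features(ft_raw, "past_mean", cfg))
  names(cent) <- paste0(names(ft_raw), "_c7min_norm")
  names(past) <- paste0(names(ft_raw), "_p2min_norm")
  out <- cbind(ft_raw, cent, past,
               time_elapsed = (seq_len(n) - 1) / (n - 1))
  if (!is.null(meta)) {
    if (is.null(meta$age) || is.null(meta$sex)) {
      stop("`meta` must supply both `age` and `sex`")
    }
    out$age <- as.numeric(meta$age)
    out$sex <- as.numeric(meta$sex)
  }
  out
}
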