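#' Default spectral bands
#'
#' The six contiguous frequency bands partitioning 0.4-30 Hz used for
#' relative spectral power: slow (0.4-1), delta (1-4), theta (4-8),
#' alpha (8-12), sigma (12-16) and beta (16-30 Hz).
#'
#' @return A data frame with columns `name`, `low`, `high`.
#' @export
default_bands <- function() {
  data.frame(
    name = c("slow", "delta", "theta", "alpha", "sigma", "beta"),
    low  = c(0.4, 1, 4, 8, 12, 16),
    high = c(1, 4, 8, 12, 16, 30),
    stringsAsFactors = FALSE
  )
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("name", "low", "high") %in% names(bands)))
  if (any(bands$low >= bands$high)) stop("band low must be < high")
  invisible(bands)
}

# ---- time-domain features ---------------------------------------------------

#' Time-domain features of one epoch
#'
#' Computes the ten per-epoch time-domain descriptors used by the staging
#' model: standard deviation, interquartile range, skewness, kurtosis
#' (excess), number of zero-crossings, Hjorth mobility and complexity,
#' normalized permutation entropy (order 3, delay 1), and the Petrosian and
#' Higuchi fractal dimensions.
#'
#' Degenerate (constant) input is guarded: variance-based quantities,
#' zero-crossings, permutation entropy and Higuchi's slope are all defined
#' as 0 so every output is finite.
#'
#' @param x Numeric vector, one epoch of signal (>= 100 samples).
#' @return Named numeric vector of length 10.
#' @examples
#' fs <- 100
#' x <- sin(2 * pi * 10 * seq(1 / fs, 30, by = 1 / fs))
#' time_domain_features(x)[["std"]]  # ~ 1/sqrt(2)
#' @export
time_domain_features <- function(x) {
  if (length(x) < 100) stop("epoch too short: ", length(x), " samples (need >= 100)")
  out <- time_features_mat(matrix(x, nrow = 1))
  stats::setNames(as.numeric(out[1, ]), colnames(out))
}

# vectorized implementation over an epochs-by-samples matrix; the single
# epoch API above is a one-row view of this
time_features_mat <- function(X) {
  n <- ncol(X)
  n_ep <- nrow(X)
  mu <- rowMeans(X)
  xc <- X - mu
  m2 <- rowSums(xc^2) / n
  sd_ <- sqrt(rowSums(xc^2) / (n - 1))
  m3 <- rowSums(xc^3) / n
  m4 <- rowSums(xc^4) / n
  skew <- ifelse(m2 > 0, m3 / m2^1.5, 0)
  kurt <- ifelse(m2 > 0, m4 / m2^2 - 3, 0)
  iqr_ <- apply(X, 1, function(r) diff(stats::quantile(r, c(0.25, 0.75), names = FALSE)))

  # zero-crossings: strict sign changes; exact zeros carry the previous sign
  nzc <- apply(X, 1, zero_crossings)

  # Hjorth parameters from first and second differences
  d1 <- X[, -1, drop = FALSE] - X[, -n, drop = FALSE]
  d2 <- d1[, -1, drop = FALSE] - d1[, -(n - 1), drop = FALSE]
  v0 <- rowSums(xc^2) / (n - 1)
  v1 <- apply(d1, 1, stats::var)
  v2 <- apply(d2, 1, stats::var)
  mob <- ifelse(v0 > 0, sqrt(v1 / v0), 0)
  mob1 <- ifelse(v1 > 0, sqrt(v2 / v1), 0)
  comp <- ifelse(mob > 0, mob1 / mob, 0)

  pe <- perm_entropy_mat(X)
  pfd <- petrosian_mat(X, d1)
  hfd <- higuchi_mat(X)

  cbind(std = sd_, iqr = iqr_, skew = skew, kurt = kurt, nzc = nzc,
        hmob = mob, hcomp = comp, perm = pe, petrosian = pfd, higuchi = hfd)
}

zero_crossings <- function(x) {
  s <- sign(x)
  nz <- s != 0
  if (!any(nz)) return(0)
  s <- s[nz]                      # zeros inherit the previous sign
  sum(s[-1] != s[-length(s)])
}

# normalized permutation entropy, order 3, delay 1; Lehmer-coded ordinal
# patterns with strict comparisons, vectorized across epochs
perm_entropy_mat <- function(X) {
  n <- ncol(X)
  x1 <- X[, 1:(n - 2), drop = FALSE]
  x2 <- X[, 2:(n - 1), drop = FALSE]
  x3 <- X[, 3:n, drop = FALSE]
  code <- 2 * ((x2 < x1) + (x3 < x1)) + (x3 < x2)
  total <- ncol(code)
  H <- numeric(nrow(X))
  for (k in 0:5) {
    p <- rowSums(code == k) / total
    H <- H - ifelse(p > 0, p * log(p), 0)
  }
  H / log(6)
}

petrosian_mat <- function(X, d1 = NULL) {
  n <- ncol(X)
  if (is.null(d1)) d1 <- X[, -1, drop = FALSE] - X[, -n, drop = FALSE]
  nd <- apply(d1, 1, zero_crossings)
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

# Higuchi fractal dimension, k_max = 10, slope of log curve length against
# log(1/k); all-k curve lengths computed with column-sliced matrix ops
higuchi_mat <- function(X, kmax = 10) {
  n <- ncol(X)
  L <- matrix(0, nrow(X), kmax)
  for (k in seq_len(kmax)) {
    Lm <- 0
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      ni <- length(idx)
      norm <- (n - 1) / ((ni - 1) * k)
      Lm <- Lm + rowSums(abs(X[, idx[-1], drop = FALSE] -
                             X[, idx[-ni], drop = FALSE])) * norm / k
    }
    L[, k] <- Lm / k
  }
  lx <- log(1 / seq_len(kmax))
  ly <- log(L)
  degenerate <- !is.finite(rowSums(ly))
  ly[degenerate, ] <- 0
  slope <- as.vector((ly - rowMeans(ly)) %*% (lx - mean(lx))) /
    sum((lx - mean(lx))^2)
  slope[degenerate] <- 0
  slope
}

# ---- frequency-domain features ----------------------------------------------

# Welch PSD with 5-s Hamming segments, 50% overlap and median averaging
# across segments (robust to transient artifacts). Returns freq + psd.
welch_psd_mat <- function(X, rate, win_s = 5) {
  n <- ncol(X)
  win <- round(win_s * rate)
  if (n < win) stop("epoch shorter than one Welch segment (", win_s, " s)")
  step <- win %/% 2
  nseg <- (n - win) %/% step + 1
  n_ep <- nrow(X)
  h <- 0.54 - 0.46 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  U <- sum(h^2)
  nf <- win %/% 2 + 1
  segs <- matrix(0, win, nseg * n_ep)
  for (s in seq_len(nseg)) {
    idx <- ((s - 1) * step + 1):((s - 1) * step + win)
    seg <- t(X[, idx, drop = FALSE])
    seg <- (seg - rep(colMeans(seg), each = win)) * h
    segs[, ((s - 1) * n_ep + 1):(s * n_ep)] <- seg
  }
  Fm <- stats::mvfft(segs)
  P <- Mod(Fm[1:nf, , drop = FALSE])^2 / (rate * U)
  if (nf > 2) P[2:(nf - 1), ] <- 2 * P[2:(nf - 1), ]
  # median over segments, per (freq, epoch) cell
  psd <- segment_median(P, nf, n_ep, nseg)
  list(freq = seq(0, rate / 2, length.out = nf), psd = psd)
}

# median across nseg segment-PSDs; pmin/pmax bubble sorting network over the
# segment dimension (nseg is small and odd in the default configuration)
segment_median <- function(P, nf, n_ep, nseg) {
  cols <- lapply(seq_len(nseg), function(s) {
    as.vector(P[, ((s - 1) * n_ep + 1):(s * n_ep), drop = FALSE])
  })
  k <- nseg
  for (i in seq_len(k - 1)) {
    for (j in seq_len(k - i)) {
      a <- cols[[j]]; b <- cols[[j + 1]]
      cols[[j]] <- pmin(a, b); cols[[j + 1]] <- pmax(a, b)
    }
  }
  med <- if (k %% 2 == 1) {
    cols[[(k + 1) %/% 2]]
  } else {
    (cols[[k %/% 2]] + cols[[k %/% 2 + 1]]) / 2
  }
  matrix(med, nf, n_ep)
}

#' Spectral features of one epoch
#'
#' Welch periodogram features: relative power in each band (default six
#' bands, [default_bands()]), log10 absolute broadband (0.4-30 Hz) power,
#' and the four power ratios delta/theta, delta/sigma, delta/beta and
#' alpha/theta computed from the relative powers with a zero-denominator
#' guard.
#'
#' The periodogram uses 5-s Hamming segments with 50% overlap (0.20 Hz
#' frequency resolution at any rate) and median averaging across segments.
#' Each frequency bin is assigned to the band whose `[low, high)` interval
#' contains its center; the last band is closed at its upper edge, so the
#' band relative powers always sum to exactly 1.
#'
#' @param x Numeric vector, one epoch.
#' @param rate Sampling rate in Hz.
#' @param bands Band definition data frame (default [default_bands()]).
#' @return Named numeric vector: `relpow_<band>` per band, `abspow`, and the
#'   four ratios.
#' @export
spectral_features <- function(x, rate, bands = default_bands()) {
  out <- spectral_features_mat(matrix(x, nrow = 1), rate, bands)
  stats::setNames(as.numeric(out[1, ]), colnames(out))
}

spectral_features_mat <- function(X, rate, bands = default_bands()) {
  validate_bands(bands)
  if (rate / 2 < max(bands$high)) {
    stop("rate ", rate, " Hz too low for band edge ", max(bands$high), " Hz")
  }
  w <- welch_psd_mat(X, rate)
  df <- w$freq[2] - w$freq[1]
  nb <- nrow(bands)
  lo_all <- min(bands$low); hi_all <- max(bands$high)
  bp <- matrix(0, nrow(X), nb)
  for (b in seq_len(nb)) {
    sel <- w$freq >= bands$low[b] & w$freq < bands$high[b]
    if (b == nb) sel <- sel | abs(w$freq - bands$high[b]) < df / 2
    bp[, b] <- colSums(w$psd[sel, , drop = FALSE]) * df
  }
  total <- rowSums(bp)
  rel <- bp / ifelse(total > 0, total, 1)
  abspow <- log10(total + 1e-12)
  g <- function(nm) rel[, match(nm, bands$name)]
  ratio <- function(a, b) a / (b + 1e-12)
  out <- cbind(rel, abspow,
               ratio(g("delta"), g("theta")),
               ratio(g("delta"), g("sigma")),
               ratio(g("delta"), g("beta")),
               ratio(g("alpha"), g("theta")))
  colnames(out) <- c(paste0("relpow_", bands$name), "abspow",
                     "ratio_delta_theta", "ratio_delta_sigma",
                     "ratio_delta_beta", "ratio_alpha_theta")
  out
}

# ---- per-channel extraction -------------------------------------------------

#' Extract the raw per-epoch feature table from epoched channels
#'
#' Computes the full time-domain + spectral feature set for every epoch of
#' every channel. Column names follow the `{role}_{feature}` contract, with
#' the channel role lowercased (e.g. `eeg_relpow_delta`). The same feature
#' set is computed for EEG, EOG and EMG channels.
#'
#' @param channels Epoched channels from [epoch_recording()].
#' @param bands Spectral band definitions.
#' @return A data frame with one row per epoch ("raw" feature variant only).
#' @export
extract_features <- function(channels, bands = default_bands()) {
  if (length(channels) == 0) stop("no channels supplied")
  n_ep <- unique(vapply(channels, function(ch) nrow(ch$epochs), integer(1)))
  if (length(n_ep) != 1L) stop("channels are not epoch-aligned")
  blocks <- lapply(channels, function(ch) {
    td <- time_features_mat(ch$epochs)
    sp <- spectral_features_mat(ch$epochs, ch$rate, bands)
    blk <- cbind(td, sp)
    colnames(blk) <- paste(tolower(ch$role), colnames(blk), sep = "_")
    blk
  })
  out <- as.data.frame(do.call(cbind, blocks))
  if (any(!is.finite(as.matrix(out)))) {
    stop("non-finite feature values produced; check input signal")
  }
  out
}
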