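#' Resample all channels of a recording to a common rate
#'
#' Downsamples every channel to `target_rate` by rational polyphase
#' resampling with an anti-aliasing FIR (via [signal::resample()]).
#' Upsampling is refused: the analysis rate (100 Hz by default across the
#' package) is always at or below the native PSG rates.
#'
#' @param rec A [recording()].
#' @param target_rate Target rate in Hz (default 100).
#' @return A recording with all channels at `target_rate`.
#' @export
resample_recording <- function(rec, target_rate = 100) {
  stopifnot(inherits(rec, "psg_recording"), target_rate > 0)
  chans <- lapply(rec$channels, function(ch) {
    if (target_rate > ch$rate + 1e-9) {
      stop("upsampling not supported: channel '", ch$label, "' is at ",
           ch$rate, " Hz < target ", target_rate, " Hz")
    }
    if (abs(ch$rate - target_rate) < 1e-9) return(ch)
    frac <- rational_approx(target_rate / ch$rate)
    y <- polyphase_resample(ch$samples, frac[1], frac[2])
    list(label = ch$label, role = ch$role, samples = as.numeric(y),
         rate = target_rate)
  })
  recording(chans, start_time = rec$start_time)
}

# smallest p/q with p/q == x for the rate ratios seen in PSG hardware
rational_approx <- function(x, max_den = 4096) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("cannot express rate ratio ", x, " as a small rational")
}

# Rational p/q polyphase resampler with a Hamming anti-alias FIR designed at
# the upsampled rate (cutoff at the smaller of the two Nyquists, ~53 dB
# stopband). The prototype filter is decomposed into p phase branches so the
# signal is never materialized at the upsampled rate; edges are replicated
# to avoid zero-padding transients.
polyphase_resample <- function(x, p, q) {
  n <- length(x)
  wc <- min(1 / p, 1 / q)           # in units of the upsampled Nyquist
  ntaps <- ceiling(6.6 / (0.1 * wc))
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  h <- p * signal::fir1(ntaps - 1, wc)
  delay <- (ntaps - 1) / 2
  npad <- ceiling(ntaps / p) + 1
  xp <- c(rep(x[1], npad), x, rep(x[n], npad))
  n_out <- floor(n * p / q)
  m <- 0:(n_out - 1)
  up <- m * q + delay + npad * p    # position in the upsampled grid
  phase <- up %% p
  s <- up %/% p                     # 0-based index into xp
  y <- numeric(n_out)
  for (r in unique(phase)) {
    g <- h[seq(r + 1, ntaps, by = p)]
    yr <- signal::fftfilt(g, xp)    # causal: yr[i] = sum_k g[k+1] xp[i-k]
    sel <- phase == r
    y[sel] <- yr[s[sel] + 1]
  }
  y
}

# linear-phase Hamming FIR bandpass; transition widths min(low, 2) Hz at the
# lower edge and 5 Hz at the upper edge set the filter length
design_bandpass_fir <- function(low, high, rate) {
  tw <- min(low, 2)
  ntaps <- ceiling(3.3 / (tw / rate))
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  signal::fir1(ntaps - 1, c(low, high) / (rate / 2), type = "pass")
}

# zero-phase FIR filtering: forward pass then reversed pass, both via
# FFT overlap-add convolution; reflective padding absorbs edge transients
zero_phase_fir <- function(b, x) {
  npad <- length(b)
  n <- length(x)
  if (n <= npad) {
    pad_l <- rev(2 * x[1] - x)
    pad_r <- rev(2 * x[n] - x)
  } else {
    pad_l <- 2 * x[1] - x[(npad + 1):2]
    pad_r <- 2 * x[n] - x[(n - 1):(n - npad)]
  }
  xp <- c(pad_l, x, pad_r)
  y <- signal::fftfilt(b, xp)
  y <- rev(signal::fftfilt(b, rev(y)))
  # the reversed second pass cancels the forward pass's group delay, so the
  # payload sits exactly where the unpadded signal was
  y[(length(pad_l) + 1):(length(pad_l) + n)]
}

#' Bandpass filter all channels of a recording
#'
#' Applies a zero-phase (forward-backward) linear-phase Hamming FIR bandpass
#' to every channel. Defaults follow the staging pipeline: 0.40-30 Hz.
#'
#' @param rec A [recording()].
#' @param low,high Band edges in Hz; requires `0 < low < high < rate/2`.
#' @return Filtered recording.
#' @export
bandpass_recording <- function(rec, low = 0.4, high = 30) {
  stopifnot(inherits(rec, "psg_recording"))
  chans <- lapply(rec$channels, function(ch) {
    if (!(low > 0 && low < high && high < ch$rate / 2)) {
      stop("invalid band [", low, ", ", high, "] Hz for rate ", ch$rate,
           " Hz (need 0 < low < high < rate/2)")
    }
    b <- design_bandpass_fir(low, high, ch$rate)
    ch$samples <- zero_phase_fir(b, ch$samples)
    ch
  })
  recording(chans, start_time = rec$start_time)
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts each channel into consecutive non-overlapping epochs of
#' `epoch_len_s` seconds (30 s, the sleep-scoring unit, by default). A
#' trailing partial epoch is dropped, not padded: sleep scoring is defined
#' on complete epochs only.
#'
#' @param rec A [recording()]; all channels must share one rate.
#' @param epoch_len_s Epoch length in seconds.
#' @return A list of epoched channels, each a list with `role`, `epochs`
#'   (matrix, `n_epochs x samples_per_epoch`), `rate` and `epoch_len_s`.
#' @export
epoch_recording <- function(rec, epoch_len_s = 30) {
  stopifnot(inherits(rec, "psg_recording"), epoch_len_s > 0)
  rates <- vapply(rec$channels, `[[`, numeric(1), "rate")
  if (length(unique(rates)) != 1L) {
    stop("all channels must share one rate before epoching; resample first")
  }
  spe <- rates[1] * epoch_len_s
  if (abs(spe - round(spe)) > 1e-9) {
    stop("epoch_len_s * rate must be an integer number of samples")
  }
  spe <- as.integer(round(spe))
  n_ep <- length(rec$channels[[1]]$samples) %/% spe
  if (n_ep < 1) stop("recording shorter than one epoch (", epoch_len_s, " s)")
  lapply(rec$channels, function(ch) {
    m <- matrix(ch$samples[seq_len(n_ep * spe)], nrow = n_ep, ncol = spe,
                byrow = TRUE)
    list(role = ch$role, label = ch$label, epochs = m, rate = ch$rate,
         epoch_len_s = epoch_len_s)
  })
}
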