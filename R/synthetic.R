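# Reproducible synthetic PSG: a time-inhomogeneous Markov hypnogram plus
# stage-conditioned EEG/EOG/EMG synthesized as band-shaped noise, so the
# spectral and amplitude structure that the staging features discriminate
# (delta-dominant N3, sigma activity in N2, alpha-rich wake, REM atonia on
# the EMG) is present without any clinical data.

# substream derivation: one master seed reproduces a whole experiment;
# derived seeds stay below 2^31
derive_seed <- function(master, ...) {
  ids <- c(...)
  s <- as.numeric(master) %% 2147483647
  for (i in ids) s <- (s * 31013 + as.numeric(i) * 7919 + 17) %% 2147483647
  as.integer(s)
}

#' Hypnogram generator model
#'
#' A first-order Markov chain over the five stages with a night-long
#' time-inhomogeneity: transition probabilities into N3 are inflated early
#' in the night and deflated late (and symmetrically R late vs early),
#' emulating the physiological predominance of deep NREM sleep in the first
#' half of the night and of REM sleep in the second half. The default
#' transition matrix produces realistic stage proportions
#' (roughly 10-15% W, 5-10% N1, 40-50% N2, 10-20% N3, 15-20% R) with
#' strongly persistent stages.
#'
#' @param transition 5x5 row-stochastic matrix (canonical stage order).
#' @param initial Initial stage distribution (default: start awake).
#' @param n_epochs Night length in epochs (default 960 = 8 h).
#' @param inhomogeneity Strength `b` of the early/late bias: the N3 column
#'   is scaled by `exp(b * (0.5 - f))` and the R column by
#'   `exp(b * (f - 0.5))` at night fraction `f`, rows renormalized.
#'   Default 0.8.
#' @return List of class `"hypnogram_model"`.
#' @export
hypnogram_model <- function(transition = default_transition_matrix(),
                            initial = c(1, 0, 0, 0, 0),
                            n_epochs = 960, inhomogeneity = 0.8) {
  transition <- as.matrix(transition)
  stopifnot(nrow(transition) == 5, ncol(transition) == 5)
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8)) {
    stop("transition matrix must be row-stochastic")
  }
  if (n_epochs < 15) stop("night length must be >= 15 epochs")
  stopifnot(length(initial) == 5, all(initial >= 0), sum(initial) > 0)
  structure(list(transition = transition, initial = initial / sum(initial),
                 n_epochs = n_epochs, inhomogeneity = inhomogeneity),
            class = "hypnogram_model")
}

#' @rdname hypnogram_model
#' @export
default_transition_matrix <- function() {
  m <- matrix(c(
    # to:  W     N1     N2     N3     R        from:
         0.88,  0.09,  0.02,  0.00,  0.01,   # W
         0.07,  0.60,  0.30,  0.00,  0.03,   # N1
         0.02,  0.03,  0.85,  0.06,  0.04,   # N2
         0.01,  0.01,  0.09,  0.89,  0.00,   # N3
         0.03,  0.04,  0.05,  0.00,  0.88),  # R
    nrow = 5, byrow = TRUE)
  dimnames(m) <- list(stages(), stages())
  m
}

#' Long-run stage distribution of a hypnogram model
#'
#' Stationary distribution of the (time-homogeneous) base chain, computed
#' from the leading left eigenvector of the transition matrix.
#'
#' @param hm A [hypnogram_model()].
#' @return Named probability vector over the five stages.
#' @export
stationary_distribution <- function(hm) {
  e <- eigen(t(hm$transition))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  stats::setNames(v / sum(v), stages())
}

#' Generate a synthetic hypnogram
#'
#' Simulates the (optionally time-inhomogeneous) Markov chain of a
#' [hypnogram_model()]. Deterministic for a fixed seed.
#'
#' @param hm A [hypnogram_model()].
#' @param seed Integer seed.
#' @return A [hypnogram()].
#' @export
generate_hypnogram <- function(hm, seed = 1) {
  stopifnot(inherits(hm, "hypnogram_model"))
  set.seed(derive_seed(seed, 1))
  n <- hm$n_epochs
  s <- integer(n)
  s[1] <- sample.int(5, 1, prob = hm$initial)
  i_n3 <- match("N3", stages()); i_r <- match("R", stages())
  for (e in 2:n) {
    f <- (e - 1) / (n - 1)
    p <- hm$transition[s[e - 1], ]
    p[i_n3] <- p[i_n3] * exp(hm$inhomogeneity * (0.5 - f))
    p[i_r] <- p[i_r] * exp(hm$inhomogeneity * (f - 0.5))
    s[e] <- sample.int(5, 1, prob = p / sum(p))
  }
  hypnogram(stages()[s])
}

#' Stage-conditioned signal model
#'
#' Per-stage, per-channel spectral profiles and amplitudes for the PSG
#' synthesizer. Each stage/channel pair has a target relative-power profile
#' over the six default bands (nonnegative, summing to 1) and an RMS
#' amplitude in microvolts. Defaults encode the canonical stage signatures:
#' N3 delta-dominant at high amplitude, a sigma (spindle-band) bump in N2,
#' alpha-rich wake, low-amplitude mixed-frequency N1/REM on the EEG; slow
#' eye-movement/REM-rich EOG in W, N1 and R; and a marked EMG amplitude
#' drop in REM (muscle atonia).
#'
#' @param profiles Named list (`EEG`, `EOG`, `EMG`) of 5x6 matrices (stage
#'   x band) of relative-power targets, rows summing to 1.
#' @param amplitudes Named list of length-5 RMS amplitude vectors (µV).
#' @param tilt Within-band spectral tilt exponent (power density
#'   proportional to `f^-tilt` inside each band, band totals preserved);
#'   default 0 (flat within band).
#' @param profile_jitter Log-normal sd of the per-epoch, per-band
#'   multiplicative jitter applied to the stage profile (within-stage
#'   spectral variability); 0 disables it.
#' @param amplitude_jitter Log-normal sd of the per-epoch RMS amplitude
#'   jitter; 0 disables it.
#' @param transition_blend Fraction of the *previous* stage's profile and
#'   amplitude mixed into the first epoch after every stage change
#'   (transitional-epoch ambiguity, the main driver of staging errors);
#'   0 disables it.
#' @return List of class `"stage_signal_model"`.
#' @export
stage_signal_model <- function(profiles = default_stage_profiles(),
                               amplitudes = default_stage_amplitudes(),
                               tilt = 0, profile_jitter = 0.4,
                               amplitude_jitter = 0.2,
                               transition_blend = 0.5) {
  for (role in names(profiles)) {
    P <- profiles[[role]]
    stopifnot(nrow(P) == 5, ncol(P) == 6)
    if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) {
      stop("profile rows for ", role, " must be nonnegative and sum to 1")
    }
  }
  stopifnot(identical(sort(names(profiles)), sort(names(amplitudes))),
            profile_jitter >= 0, amplitude_jitter >= 0,
            transition_blend >= 0, transition_blend <= 1)
  structure(list(profiles = profiles, amplitudes = amplitudes, tilt = tilt,
                 profile_jitter = profile_jitter,
                 amplitude_jitter = amplitude_jitter,
                 transition_blend = transition_blend),
            class = "stage_signal_model")
}

#' @rdname stage_signal_model
#' @export
default_stage_profiles <- function() {
  bn <- default_bands()$name
  mk <- function(...) {
    m <- matrix(c(...), nrow = 5, byrow = TRUE,
                dimnames = list(stages(), bn))
    m / rowSums(m)
  }
  list(
    #          slow  delta theta alpha sigma beta
    EEG = mk(0.06, 0.14, 0.14, 0.38, 0.08, 0.20,   # W: alpha-rich
             0.12, 0.23, 0.32, 0.14, 0.07, 0.12,   # N1: theta, LAMF
             0.15, 0.28, 0.20, 0.09, 0.18, 0.10,   # N2: sigma bump
             0.18, 0.60, 0.08, 0.05, 0.05, 0.04,   # N3: delta-dominant
             0.10, 0.20, 0.30, 0.10, 0.06, 0.24),  # R: mixed-frequency
    EOG = mk(0.35, 0.25, 0.12, 0.18, 0.04, 0.06,   # W: eye movements
             0.45, 0.25, 0.12, 0.08, 0.04, 0.06,   # N1: slow eye movements
             0.25, 0.35, 0.15, 0.10, 0.10, 0.05,   # N2: attenuated EEG
             0.30, 0.45, 0.10, 0.05, 0.05, 0.05,   # N3
             0.50, 0.25, 0.10, 0.05, 0.03, 0.07),  # R: rapid eye movements
    EMG = mk(0.03, 0.07, 0.10, 0.15, 0.20, 0.45,   # broadband muscle tone,
             0.03, 0.07, 0.10, 0.15, 0.20, 0.45,   # same shape all stages
             0.03, 0.07, 0.10, 0.15, 0.20, 0.45,
             0.03, 0.07, 0.10, 0.15, 0.20, 0.45,
             0.03, 0.07, 0.10, 0.15, 0.20, 0.45)
  )
}

#' @rdname stage_signal_model
#' @export
default_stage_amplitudes <- function() {
  list(
    EEG = c(W = 18, N1 = 22, N2 = 32, N3 = 55, R = 20),
    EOG = c(W = 35, N1 = 25, N2 = 12, N3 = 10, R = 40),
    EMG = c(W = 18, N1 = 12, N2 = 10, N3 = 9, R = 4)
  )
}

#' Generate stage-conditioned PSG signals for a hypnogram
#'
#' Synthesizes EEG, EOG and EMG channels epoch by epoch: Gaussian noise is
#' shaped in the frequency domain so each epoch's expected band-power
#' composition follows the stage's profile, then scaled to the stage's RMS
#' amplitude. Three realism mechanisms perturb the clean per-stage targets
#' (all configurable through [stage_signal_model()]): per-epoch log-normal
#' jitter of the band profile and of the amplitude (within-stage
#' variability), and blending of the previous stage's profile into the
#' first epoch after each stage change (transitional ambiguity).
#' Deterministic for a fixed seed.
#'
#' @param hyp A [hypnogram()] (unscored epochs are synthesized as W).
#' @param sm A [stage_signal_model()].
#' @param rate Sampling rate in Hz (default 100; must be at least twice the
#'   highest band edge).
#' @param seed Integer seed.
#' @return A [recording()] with channels `C4-M1` (EEG), `EOG-L` (EOG) and
#'   `EMG-Chin` (EMG).
#' @export
generate_psg <- function(hyp, sm = stage_signal_model(), rate = 100,
                         seed = 1) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(sm, "stage_signal_model"))
  bands <- default_bands()
  if (rate < 2 * max(bands$high)) {
    stop("rate must be >= twice the highest band edge (",
         2 * max(bands$high), " Hz)")
  }
  ne <- as.integer(round(hyp$epoch_len_s * rate))
  n_ep <- n_epochs(hyp)
  codes <- stage_codes(hyp)
  codes[is.na(codes)] <- 1L   # synthesize unscored epochs as wake
  labels <- c(EEG = "C4-M1", EOG = "EOG-L", EMG = "EMG-Chin")
  nf <- ne %/% 2 + 1
  freqs <- seq(0, rate / 2, length.out = nf)
  # band membership of every frequency bin (0 = outside the modeled bands)
  bin_band <- integer(nf)
  bin_dens <- rep(1e-12, nf)
  for (b in seq_len(nrow(bands))) {
    sel <- freqs >= bands$low[b] & freqs < bands$high[b]
    if (b == nrow(bands)) sel <- sel | abs(freqs - bands$high[b]) < 1e-9
    bin_band[sel] <- b
    dens <- if (sm$tilt > 0) {
      d <- freqs[sel]^(-sm$tilt); d / sum(d)
    } else {
      rep(1 / sum(sel), sum(sel))
    }
    bin_dens[sel] <- dens
  }
  # first epoch of every stage run inherits part of the previous spectrum
  prev_codes <- c(codes[1], codes[-n_ep])
  blend <- ifelse(codes != prev_codes, sm$transition_blend, 0)
  roles <- names(sm$profiles)
  chans <- vector("list", length(roles))
  for (ci in seq_along(roles)) {
    role <- roles[ci]
    set.seed(derive_seed(seed, 2, ci))
    prof <- sm$profiles[[role]]
    # per-epoch band weights: stage profile, transition-blended, jittered
    W <- prof[codes, , drop = FALSE] * (1 - blend) +
      prof[prev_codes, , drop = FALSE] * blend
    if (sm$profile_jitter > 0) {
      W <- W * exp(matrix(stats::rnorm(n_ep * 6, sd = sm$profile_jitter),
                          n_ep, 6))
    }
    W <- W / rowSums(W)
    amp <- sm$amplitudes[[role]][codes] * (1 - blend) +
      sm$amplitudes[[role]][prev_codes] * blend
    if (sm$amplitude_jitter > 0) {
      amp <- amp * exp(stats::rnorm(n_ep, sd = sm$amplitude_jitter))
    }
    # per-epoch per-bin gains realizing the jittered band targets
    G <- matrix(1e-6, nf, n_ep)
    inb <- bin_band > 0
    G[inb, ] <- sqrt(t(W[, bin_band[inb], drop = FALSE]) * bin_dens[inb])
    Z <- matrix(stats::rnorm(nf * n_ep), nf, n_ep) +
      1i * matrix(stats::rnorm(nf * n_ep), nf, n_ep)
    Z <- Z * G
    full <- rbind(Z, Conj(Z[(nf - 1):2, , drop = FALSE]))
    sig <- Re(stats::mvfft(full, inverse = TRUE)) / ne
    rms <- sqrt(colMeans(sig^2))
    sig <- sig * rep(amp / pmax(rms, 1e-12), each = ne)
    chans[[ci]] <- list(label = unname(labels[role]), role = role,
                        samples = as.vector(sig), rate = rate)
  }
  recording(chans)
}

#' Generate a panel of imperfect synthetic scorers
#'
#' Each scorer is the truth corrupted independently: every epoch is
#' replaced, with probability `error_rate`, by a stage drawn from an
#' adjacent-stage confusion kernel (never the true stage itself, so the
#' expected disagreement with truth equals `error_rate`). The kernel
#' reflects plausible human confusions (W-N1, N1-N2, N2-N3, N2-R, N1-R).
#'
#' @param truth A [hypnogram()].
#' @param error_rate Per-epoch corruption probability in \[0, 1).
#' @param n_scorers Number of scorers (>= 3).
#' @param seed Integer seed.
#' @return A [scorer_panel()].
#' @export
generate_scorer_panel <- function(truth, error_rate = 0.2, n_scorers = 5,
                                  seed = 1) {
  stopifnot(inherits(truth, "hypnogram"))
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (n_scorers < 3) stop("need >= 3 scorers")
  K <- matrix(c(
    # to:  W     N1     N2     N3     R       true:
         0.00,  0.70,  0.15,  0.00,  0.15,  # W
         0.30,  0.00,  0.50,  0.00,  0.20,  # N1
         0.00,  0.50,  0.00,  0.30,  0.20,  # N2
         0.00,  0.00,  1.00,  0.00,  0.00,  # N3
         0.10,  0.50,  0.40,  0.00,  0.00), # R
    nrow = 5, byrow = TRUE)
  codes <- stage_codes(truth)
  n <- n_epochs(truth)
  hyps <- lapply(seq_len(n_scorers), function(si) {
    set.seed(derive_seed(seed, 3, si))
    s <- codes
    flip <- stats::runif(n) < error_rate & !is.na(codes)
    for (e in which(flip)) {
      s[e] <- sample.int(5, 1, prob = K[codes[e], ])
    }
    out <- ifelse(is.na(s), UNSCORED, stages()[s])
    hypnogram(out, epoch_len_s = truth$epoch_len_s)
  })
  scorer_panel(hyps)
}

#' Simulate one synthetic night
#'
#' Convenience wrapper: draws a hypnogram from the (default) hypnogram
#' model and synthesizes the matching PSG recording.
#'
#' @param seed Integer seed (one seed determines the whole night).
#' @param n_epochs Night length in epochs.
#' @param hm Optional [hypnogram_model()] override.
#' @param sm Optional [stage_signal_model()] override.
#' @param rate Sampling rate (Hz).
#' @return List with elements `hypnogram` and `recording`.
#' @export
simulate_night <- function(seed = 1, n_epochs = 960,
                           hm = NULL, sm = stage_signal_model(),
                           rate = 100) {
  if (is.null(hm)) hm <- hypnogram_model(n_epochs = n_epochs)
  hyp <- generate_hypnogram(hm, seed = seed)
  rec <- generate_psg(hyp, sm, rate = rate, seed = derive_seed(seed, 4))
  list(hypnogram = hyp, recording = rec)
}
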