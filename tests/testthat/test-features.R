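test_that("constant input activates every degenerate-signal guard", {
  f <- time_domain_features(rep(3.7, 3000))
  expect_equal(f[["std"]], 0)
  expect_equal(f[["iqr"]], 0)
  expect_equal(f[["nzc"]], 0)
  expect_equal(f[["hmob"]], 0)
  expect_equal(f[["hcomp"]], 0)
  expect_equal(f[["perm"]], 0)
  expect_equal(f[["higuchi"]], 0)
  expect_true(all(is.finite(f)))
  expect_error(time_domain_features(rnorm(50)), "too short")
})

test_that("sinusoid statistics match closed forms (std = A/sqrt(2), nzc = 2f*T)", {
  x <- sine_epoch(10, rate = 100, dur = 30)
  f <- time_domain_features(x)
  expect_equal(f[["std"]], 1 / sqrt(2), tolerance = 0.001)
  expect_lte(abs(f[["nzc"]] - 600), 1)
})

test_that("zero-crossings count strict sign changes, zeros inheriting the previous sign", {
  x <- c(1, 2, 0, 0, -1, -2, 0, 3, rep(1, 100))
  # signs: + + (+) (+) - - (-) +  => two changes
  expect_equal(unname(time_domain_features(x)["nzc"]), 2)
})

test_that("permutation entropy is 0 on monotone ramps and ~1 on iid noise", {
  ramp <- seq_len(3000) * 0.5
  expect_equal(time_domain_features(ramp)[["perm"]], 0)
  set.seed(11)
  noise <- runif(3000)
  expect_gte(time_domain_features(noise)[["perm"]], 0.99)
})

test_that("Hjorth parameters follow their variance-ratio definitions", {
  set.seed(2)
  x <- cumsum(rnorm(3000))
  f <- time_domain_features(x)
  mob_oracle <- sqrt(var(diff(x)) / var(x))
  mob_d1 <- sqrt(var(diff(diff(x))) / var(diff(x)))
  expect_equal(f[["hmob"]], mob_oracle, tolerance = 1e-10)
  expect_equal(f[["hcomp"]], mob_d1 / mob_oracle, tolerance = 1e-10)
})

test_that("fractal dimensions behave: ~1 for smooth curves, ~2 for noise", {
  set.seed(3)
  smooth <- sine_epoch(1, rate = 100, dur = 30)
  noisy <- rnorm(3000)
  fs <- time_domain_features(smooth)
  fn <- time_domain_features(noisy)
  expect_lt(fs[["higuchi"]], 1.3)
  expect_gt(fn[["higuchi"]], 1.8)
  expect_lt(fs[["petrosian"]], fn[["petrosian"]])
})

test_that("a pure tone concentrates its spectral power in its own band", {
  x <- sine_epoch(2, rate = 100, dur = 30)
  f <- spectral_features(x, 100)
  expect_gte(f[["relpow_delta"]], 0.95)
  expect_lte(f[["relpow_beta"]], 0.01)
})

test_that("the Welch estimator has 0.20 Hz frequency resolution", {
  w <- somnostage:::welch_psd_mat(matrix(rnorm(3000), 1), rate = 100)
  expect_equal(w$freq[2] - w$freq[1], 0.20, tolerance = 1e-12)
})

test_that("white-noise relative band powers track bandwidth fractions", {
  set.seed(21)
  f <- spectral_features(rnorm(3000), 100)
  bands <- default_bands()
  for (b in seq_len(nrow(bands))) {
    expected <- (bands$high[b] - bands$low[b]) / 29.6
    expect_lt(abs(f[[paste0("relpow_", bands$name[b])]] - expected), 0.05)
  }
})

test_that("the six relative band powers always sum to one (partition property)", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(3000) + sine_epoch(sample(1:30, 1), rate = 100, dur = 30)
    f <- spectral_features(x, 100)
    rel <- f[paste0("relpow_", default_bands()$name)]
    expect_equal(unname(sum(rel)), 1, tolerance = 1e-6)
    expect_true(all(rel >= 0 & rel <= 1))
  }
})

test_that("power ratios come from relative powers with a zero-denominator guard", {
  set.seed(13)
  x <- rnorm(3000)
  f <- spectral_features(x, 100)
  expect_equal(f[["ratio_delta_theta"]],
               f[["relpow_delta"]] / (f[["relpow_theta"]] + 1e-12),
               tolerance = 1e-12)
  expect_error(spectral_features(rnorm(3000), 40), "too low")
})

test_that("features scale correctly under amplitude rescaling", {
  set.seed(5)
  x <- rnorm(3000) * 10 + sine_epoch(6, rate = 100, dur = 30) * 20
  f1 <- c(time_domain_features(x), spectral_features(x, 100))
  f10 <- c(time_domain_features(10 * x), spectral_features(10 * x, 100))
  expect_equal(f10[["std"]], 10 * f1[["std"]], tolerance = 1e-9)
  expect_equal(f10[["iqr"]], 10 * f1[["iqr"]], tolerance = 1e-9)
  expect_equal(f10[["abspow"]], f1[["abspow"]] + 2, tolerance = 1e-6)
  invariant <- c("skew", "kurt", "nzc", "hmob", "hcomp", "perm", "petrosian",
                 "higuchi", paste0("relpow_", default_bands()$name),
                 "ratio_delta_theta", "ratio_alpha_theta")
  for (nm in invariant) {
    expect_equal(f10[[nm]], f1[[nm]], tolerance = 1e-6, label = nm)
  }
})

test_that("extraction yields 21 named features per channel, rows tracking epochs", {
  set.seed(8)
  fs <- 100
  mk_ch <- function(role) list(
    label = role, role = role,
    epochs = matrix(rnorm(10 * 3000), 10, 3000), rate = fs, epoch_len_s = 30
  )
  ft1 <- extract_features(list(mk_ch("EEG")))
  expect_equal(dim(ft1), c(10L, 21L))
  expect_true(all(startsWith(names(ft1), "eeg_")))
  ft3 <- extract_features(list(mk_ch("EEG"), mk_ch("EOG"), mk_ch("EMG")))
  expect_equal(ncol(ft3), 63L)
  expect_error(extract_features(list()), "no channels")
})

test_that("raw feature extraction is local: permuting epochs permutes rows", {
  set.seed(4)
  ep <- matrix(rnorm(8 * 3000), 8, 3000)
  ch <- list(label = "EEG", role = "EEG", epochs = ep, rate = 100,
             epoch_len_s = 30)
  ft <- extract_features(list(ch))
  perm <- c(5, 1, 8, 2, 7, 3, 6, 4)
  ch_p <- ch; ch_p$epochs <- ep[perm, ]
  ft_p <- extract_features(list(ch_p))
  expect_equal(as.matrix(ft_p), as.matrix(ft)[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("synthetic stages separate in band power as designed", {
  night <- fixture_night()
  ft <- fixture_features()
  st <- night$hypnogram$stages
  expect_gt(mean(ft$eeg_relpow_delta[st == "N3"]),
            mean(ft$eeg_relpow_delta[st == "W"]))
  expect_gt(mean(ft$eeg_relpow_sigma[st == "N2"]),
            mean(ft$eeg_relpow_sigma[st == "R"]))
})
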