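test_that("bipolar derivation rejects common-mode and keeps differences", {
  x <- matrix(rnorm(400), 100, 4)
  same <- x[, c(1, 1, 1, 1)]
  expect_true(all(bipolar_derive(same) == 0))
  const <- cbind(rep(1, 50), 0, 0, 0)
  d <- bipolar_derive(const)
  expect_equal(unname(d[, "LFP01"]), rep(1, 50))
  expect_equal(unname(d[, "LFP12"]), rep(0, 50))
  expect_equal(unname(d[, "LFP23"]), rep(0, 50))
  expect_error(bipolar_derive(x[, 1:3]), "4 contacts")
})

test_that("channel selection picks the derivation with peak beta power", {
  fs <- 256
  n <- fs * 40
  t <- seq_len(n) / fs
  set.seed(5)
  base <- matrix(rnorm(3 * n, sd = 1), n, 3,
                 dimnames = list(NULL, c("LFP01", "LFP12", "LFP23")))
  base[, 2] <- base[, 2] + 2 * sin(2 * pi * 20 * t)   # beta tone on LFP12
  sel <- select_channel(base, fs)
  expect_equal(attr(sel, "channel"), "LFP12")
  # tie: identical channels resolve to the first by order
  tied <- base[, c(1, 1, 1)]
  colnames(tied) <- c("LFP01", "LFP12", "LFP23")
  expect_equal(attr(select_channel(tied, fs), "channel"), "LFP01")
  expect_warning(sel0 <- select_channel(matrix(0, n, 3), fs), "zero")
})

test_that("Fourier resampling preserves passband tones and kills aliases", {
  fs <- 1024
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  tone10 <- sin(2 * pi * 10 * t)
  y <- resample_signal(tone10, fs, 250)
  expect_equal(length(y), 2500)
  expect_lt(abs(max(abs(y)) - 1), 0.01)            # amplitude within 1%
  tone200 <- sin(2 * pi * 200 * t)
  y2 <- resample_signal(tone200, fs, 250)
  # residual power relative to the original tone, in dB
  db <- 10 * log10(mean(y2^2) / mean(tone200^2))
  expect_lt(db, -40)
  expect_error(resample_signal(tone10, fs, 1024), "below")
})

test_that("downsampling a session truncates the band scheme at Nyquist", {
  cfg <- sim_config(session_hours = 1 / 30, seed = 2)
  s <- simulate_session(cfg, 1)
  s250 <- downsample(s, 250)
  expect_equal(s250$fs, 250)
  expect_equal(nrow(s250$contacts), nrow(s$contacts) * 250 / 1024)
  f <- extract_features(s250)
  sch <- band_scheme(250)
  expect_equal(feature_bands(f), sch$band)
  expect_equal(nrow(sch), 7)
  expect_error(downsample(s, 2048), "below")
})

test_that("spectrogram satisfies Parseval, non-negativity and determinism", {
  set.seed(8)
  fs <- 256
  x <- rnorm(fs * 35)
  sp <- compute_spectrogram(x, fs)
  expect_equal(diff(sp$freq)[1], 0.5)
  expect_true(all(sp$power >= 0))
  # integral of the one-sided PSD over frequency ~ signal variance
  expect_lt(abs(sum(colMeans(sp$power)) * 0.5 - var(x)) / var(x), 0.05)
  sp2 <- compute_spectrogram(x, fs)
  expect_identical(sp$power, sp2$power)
  expect_identical(compute_spectrogram(numeric(fs * 16), fs)$power,
                   matrix(0, 1, fs + 1))
  expect_error(compute_spectrogram(rnorm(10), fs), "window")
})

fake_spectrogram <- function(power, fs = 1024) {
  structure(list(power = power, freq = seq(0, fs / 2, by = 0.5),
                 frame_seconds = 15, fs = fs), class = "spectrogram")
}

test_that("band powers average the right PSD bins per 30-s epoch", {
  sch <- band_scheme()
  hyp <- hypnogram(c("W", "N2"))
  flat <- fake_spectrogram(matrix(1, 4, 1025))
  bp <- band_powers(flat, sch, hyp)
  expect_equal(nrow(bp), 2)
  expect_true(all(abs(as.matrix(bp[, sch$band]) - 1) < 1e-12))
  # power only in the 0.5-2.5 Hz bins -> delta only
  p <- matrix(0, 2, 1025)
  p[, 2:6] <- 3
  bp2 <- band_powers(fake_spectrogram(p), sch, hypnogram("W"))
  expect_gt(bp2$delta, 0)
  expect_true(all(as.matrix(bp2[, sch$band[-1]]) == 0))
})

test_that("band powers partition the integrated PSD (brute-force bin sum)", {
  set.seed(13)
  sch <- band_scheme()
  power <- matrix(rexp(6 * 1025), 6, 1025)
  sp <- fake_spectrogram(power)
  bp <- band_powers(sp, sch, hypnogram(c("W", "N1", "N2")))
  nbins <- vapply(seq_len(nrow(sch)), function(i)
    sum(sp$freq >= sch$f_low[i] & sp$freq < sch$f_high[i] & sp$freq > 0), 0)
  got <- as.matrix(bp[, sch$band]) %*% (nbins * 0.5)
  # oracle: direct sum over every non-DC bin below 350 Hz, per epoch
  sel <- sp$freq > 0 & sp$freq < 350
  want <- vapply(seq_len(3), function(e)
    sum((power[2 * e - 1, sel] + power[2 * e, sel]) / 2) * 0.5, 0)
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("epochs with incomplete frames are dropped and reported", {
  sch <- band_scheme()
  sp <- fake_spectrogram(matrix(1, 3, 1025))   # 3 frames = 1.5 epochs
  bp <- band_powers(sp, sch, hypnogram(c("W", "N2")))
  expect_equal(nrow(bp), 1)
  expect_equal(attr(bp, "dropped"), 1L)        # 0-based epoch index
  # a band whose only candidate bin is DC is empty after DC exclusion
  dc_only <- data.frame(band = "dc_only", f_low = 0, f_high = 0.4)
  expect_error(band_powers(sp, dc_only, hypnogram("W")), "dc_only")
})

test_that("per-subject normalization matches hand arithmetic", {
  f <- data.frame(subject = "a", epoch = 0:2, stage = "W",
                  delta = c(1, 2, 3))
  z <- normalize_features(f)
  expect_equal(mean(z$delta), 0)
  expect_equal(sd(z$delta), 1)
  # two subjects normalize independently
  f2 <- rbind(f, data.frame(subject = "b", epoch = 0:2, stage = "W",
                            delta = c(10, 20, 30)))
  z2 <- normalize_features(f2)
  expect_lt(abs(mean(z2$delta[z2$subject == "a"])), 1e-8)
  expect_lt(abs(mean(z2$delta[z2$subject == "b"])), 1e-8)
  # variance scaling option
  zv <- normalize_features(f, scale = "var")
  expect_equal(zv$delta, (c(1, 2, 3) - 2) / 1)   # var = 1 here
  zv2 <- normalize_features(data.frame(subject = "a", epoch = 0:2,
                                       stage = "W", delta = c(2, 4, 6)),
                            scale = "var")
  expect_equal(zv2$delta, (c(2, 4, 6) - 4) / 4)
})

test_that("stored statistics reproduce the training transform on new epochs", {
  # 4-epoch toy table: stats from the first two epochs only
  train <- data.frame(subject = "a", epoch = 0:1, stage = "W",
                      theta = c(4, 8))
  test <- data.frame(subject = "a", epoch = 2:3, stage = "N2",
                     theta = c(6, 2))
  tr <- normalize_features(train)
  te <- normalize_features(test, stats = attr(tr, "stats"))
  # hand: mean 6, sd = sqrt(8); (6-6)/2.828 = 0, (2-6)/2.828 = -1.414
  expect_equal(te$theta, c(0, -4 / sqrt(8)))
  # pooled recomputation would give different values
  pooled <- normalize_features(rbind(train, test))
  expect_false(isTRUE(all.equal(pooled$theta[3:4], te$theta)))
  expect_error(normalize_features(test, stats = list(subjects = list())),
               "statistics")
})

test_that("zero-variance features fall back to divisor 1 with a warning", {
  f <- data.frame(subject = "a", epoch = 0:2, stage = "W",
                  delta = c(5, 5, 5), theta = c(1, 2, 3))
  expect_warning(z <- normalize_features(f), "zero-variance")
  expect_equal(z$delta, c(0, 0, 0))
  expect_equal(sd(z$theta), 1)
})

test_that("the normalized feature pipeline is invariant to a global gain", {
  cfg <- sim_config(session_hours = 1 / 30, seed = 6)
  s <- simulate_session(cfg, 1)
  f1 <- normalize_features(extract_features(s))
  s$contacts <- s$contacts * 3.7
  f2 <- normalize_features(extract_features(s))
  expect_lt(max(abs(as.matrix(f1[, feature_bands(f1)]) -
                      as.matrix(f2[, feature_bands(f2)]))), 1e-6)
})
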