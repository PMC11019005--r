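test_that("baseline correction subtracts the prestimulus mean", {
  times <- seq(-200, 800, by = 2)
  # constant offset -> all zero
  ep <- make_epochs(rep(3, length(times)))
  bc <- baseline_correct(ep)
  expect_lt(max(abs(bc$data)), 1e-12)

  # zero-mean baseline -> unchanged
  sig <- ifelse(times >= 0, 5, 0)
  ep <- make_epochs(sig)
  bc <- baseline_correct(ep)
  expect_equal(bc$data, ep$data, tolerance = 1e-12)

  # ramp: closed-form subtraction of the baseline mean
  ramp <- times / 100
  ep <- make_epochs(ramp)
  bc <- baseline_correct(ep)
  bl_mean <- mean(ramp[times >= -200 & times < 0])
  expect_equal(bc$data[1, , 1], ramp - bl_mean, tolerance = 1e-12)
  # post-correction baseline mean is zero
  expect_lt(abs(mean(bc$data[1, times >= -200 & times < 0, 1])), 1e-9)

  expect_error(baseline_correct(ep, window = c(-500, -300)), "no samples")
})

test_that("artifact screening applies both channel-wise criteria", {
  times <- seq(-200, 800, by = 2)
  n <- length(times)

  # single-sample jump of 120 uV: 120 uV / 2 ms = 60 uV/ms > 50
  sig <- rep(0, n); sig[300] <- 120
  sc <- screen_artifacts(make_epochs(sig))
  expect_false(sc$retained)
  expect_equal(sc$rejection_reason, "voltage_step")

  # smooth 70 uV peak-to-peak: retained
  sig <- 35 * sin(2 * pi * (times + 200) / 1000)
  sc <- screen_artifacts(make_epochs(sig))
  expect_true(sc$retained)
  expect_equal(sc$rejection_reason, "none")

  # 85 uV slow drift: range violation without a step violation
  sig <- 85 * (times + 200) / 1000
  sc <- screen_artifacts(make_epochs(sig))
  expect_false(sc$retained)
  expect_equal(sc$rejection_reason, "range")

  # individual-channel mode: artifact on one channel rejects the trial
  clean <- rep(0, n); dirty <- clean; dirty[100] <- 200
  ep <- make_epochs(clean)
  ep$data[2, , 1] <- dirty
  expect_false(screen_artifacts(ep)$retained)
})

test_that("peak extraction matches the windowed-Gaussian closed form", {
  times <- seq(-200, 800, by = 2)
  sig <- 5 * exp(-(times - 104)^2 / (2 * 12^2))
  pk <- extract_peak(sig, times, c(90, 120), "+")
  expect_equal(pk$latency, 104)
  expect_equal(pk$mean_amp, gaussian_window_mean(5, 12), tolerance = 1e-9)

  # flat epoch: zero amplitude, latency at the first window sample
  pk0 <- extract_peak(rep(0, length(times)), times, c(90, 120), "+")
  expect_equal(pk0$mean_amp, 0)
  expect_equal(pk0$latency, 90)

  # two equal maxima: earliest wins
  sig2 <- rep(0, length(times))
  sig2[times == 100] <- 1
  sig2[times == 110] <- 1
  expect_equal(extract_peak(sig2, times, c(90, 120), "+")$latency, 100)

  # negative polarity
  pkn <- extract_peak(-sig, times, c(90, 120), "-")
  expect_equal(pkn$latency, 104)
  expect_equal(pkn$mean_amp, -gaussian_window_mean(5, 12), tolerance = 1e-9)

  expect_error(extract_peak(sig, times, c(900, 1000), "+"), "outside")
})

test_that("channel combination averages amplitudes", {
  f <- combine_channels(list(latency = 100, mean_amp = 4),
                        list(latency = 110, mean_amp = 6))
  expect_equal(f$mean_amp, 5)
  expect_equal(f$latency, 105)
  f2 <- combine_channels(list(latency = 104, mean_amp = 3),
                         list(latency = 104, mean_amp = 3))
  expect_equal(f2$mean_amp, 3)
})

test_that("unequal channel gains average to the midpoint amplitude", {
  times <- seq(-200, 800, by = 2)
  sig <- 5 * exp(-(times - 104)^2 / (2 * 12^2))
  ep <- make_epochs(sig, gains = c(1.0, 0.8))
  feats <- extract_erp_features(ep)
  expect_equal(feats$p1_amp, 0.9 * gaussian_window_mean(5, 12),
               tolerance = 1e-9)
})

test_that("full extraction round-trips noiseless rendered epochs", {
  set.seed(31)
  tr <- data.frame(subject = 1, condition = "LR", trial_index = 1:20,
                   p1_amp = runif(20, 2, 8), n1_amp = runif(20, -8, -2))
  eff <- erp_effect_config(latency_jitter = 0, epoch_noise_sd = 0)
  ep <- render_epochs(tr, eff)
  feats <- extract_erp_features(ep)
  expect_true(all(feats$retained))
  expect_equal(feats$p1_latency, rep(104, 20))
  expect_equal(feats$n1_latency, rep(154, 20))
  # the P1/N1 components overlap (centers 50 ms apart), so the expected
  # window mean is the two-component closed form, not the isolated Gaussian
  expect_equal(feats$p1_amp,
               two_component_window_mean(tr$p1_amp, tr$n1_amp, 104),
               tolerance = 1e-9)
  expect_equal(feats$n1_amp,
               two_component_window_mean(tr$p1_amp, tr$n1_amp, 154),
               tolerance = 1e-9)
  expect_true(all(feats$p1_amp >= 0))
  expect_true(all(feats$n1_amp <= 0))

  # with jitter, latency moves by at most the configured bound
  epj <- render_epochs(tr, erp_effect_config(epoch_noise_sd = 0), seed = 8)
  fj <- extract_erp_features(epj)
  expect_true(all(abs(fj$p1_latency - 104) <= 8))
})

test_that("standardization is per subject, pooled across blocks", {
  f <- data.frame(subject = rep(1:2, each = 3),
                  p1_amp = c(1, 2, 3, 10, 20, 30),
                  n1_amp = c(-1, -2, -3, -4, -5, -6))
  z <- standardize_amplitudes(f, min_trials = 3)
  expect_equal(z$p1_z[1:3], c(-1, 0, 1))
  expect_equal(z$p1_z[4:6], c(-1, 0, 1))
  # location invariance
  f2 <- f; f2$p1_amp <- f2$p1_amp + 100
  z2 <- standardize_amplitudes(f2, min_trials = 3)
  expect_equal(z2$p1_z, z$p1_z)
  # per-subject moments
  for (s in 1:2) {
    expect_lt(abs(mean(z$p1_z[z$subject == s])), 1e-9)
    expect_equal(stats::sd(z$p1_z[z$subject == s]), 1, tolerance = 1e-9)
  }
  # degenerate scale errors out
  f3 <- f; f3$p1_amp <- 5
  expect_error(standardize_amplitudes(f3, min_trials = 3), "variance")
  expect_error(standardize_amplitudes(f, min_trials = 30), "retained")
})

test_that("pooled and per-block z-scores differ when block means differ", {
  f <- data.frame(subject = 1,
                  condition = rep(c("LR", "HP"), each = 50),
                  p1_amp = c(rnorm(50, 2), rnorm(50, 6)))
  pooled <- standardize_amplitudes(f, cols = c(p1_z = "p1_amp"),
                                   min_trials = 30)
  # pooled z preserves the block difference; per-block z would erase it
  expect_gt(mean(pooled$p1_z[f$condition == "HP"]),
            mean(pooled$p1_z[f$condition == "LR"]))
})

test_that("short-SSD stop trials are removed inclusively at the boundary", {
  tr <- data.frame(is_stop = c(1, 1, 1, 1, 1, 0),
                   ssd = c(100, 150, 151, 200, 500, NA))
  out <- filter_short_ssd(tr)
  expect_equal(out$ssd[out$is_stop == 1], c(151, 200, 500))
  expect_equal(sum(out$is_stop == 0), 1)

  # all-go table unchanged
  go <- data.frame(is_stop = rep(0, 5), ssd = rep(NA_real_, 5))
  expect_equal(nrow(filter_short_ssd(go)), 5)
})

test_that("staircase-simulated blocks lose few trials to the SSD filter", {
  tr <- do.call(rbind, lapply(1:4, function(i)
    simulate_block(seed = 400 + i, condition = "LR")))
  kept <- filter_short_ssd(tr)
  expect_lt(1 - nrow(kept) / nrow(tr), 0.05)
})

test_that("identical epochs yield identical features", {
  tr <- data.frame(subject = 1, condition = "LR", trial_index = 1:5,
                   p1_amp = 1:5, n1_amp = -(1:5))
  ep <- render_epochs(tr, erp_effect_config(epoch_noise_sd = 1), seed = 12)
  expect_identical(extract_erp_features(ep), extract_erp_features(ep))
})
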