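test_that("codebook presets match the two stimulation paradigms", {
  beta <- make_codebook("beta")
  expect_equal(n_targets(beta), 40L)
  expect_equal(beta$frequencies, seq(8, 15.8, by = 0.2))
  expect_equal(beta$delta_f_stim, 0.2)
  expect_equal(beta$phases[1:4], c(0, 0.5, 1, 1.5) * pi)
  expect_true(all(beta$phases >= 0 & beta$phases < 2 * pi))

  ssm <- make_codebook("ssmvep")
  expect_equal(n_targets(ssm), 35L)
  expect_equal(ssm$frequencies, seq(3, 20, by = 0.5))
  expect_equal(ssm$delta_f_stim, 0.5)
  expect_true(all(ssm$phases == 0.5 * pi))
})

test_that("custom codebooks validate their frequency grid", {
  cb <- make_codebook("custom", f_min = 10, f_max = 12, step = 0.5)
  expect_equal(n_targets(cb), 5L)
  expect_equal(cb$delta_f_stim, 0.5)
  expect_error(make_codebook("custom", f_min = 10, f_max = 10, step = 1),
               "f_max")
  expect_error(make_codebook("custom", f_min = 1, f_max = 2, step = -1),
               "step")
})

test_that("noiseless single-harmonic epochs reproduce the closed-form sinusoid", {
  cb <- codebook8()
  cfg <- cfg8(noise_snr_db = Inf, harmonic_amps = 1, latency_sd_s = 0,
              n_blocks = 1)
  ep <- simulate_epochs(cb, cfg)
  fs <- cfg$fs
  s0 <- round_away((cfg$pre_stim_s + cfg$latency_mean_s) * fs)
  n_stim <- round(cfg$stim_s * fs)
  t <- (0:(n_stim - 1)) / fs
  for (k in c(1L, 5L, 8L)) {
    expected <- ep$channel_gains[2] *
      sin(2 * pi * cb$frequencies[k] * t + cb$phases[k])
    got <- ep$values[2, (s0 + 1):(s0 + n_stim), 1, k]
    expect_lt(max(abs(got - expected)), 1e-9)
  }
  # pre-stimulus segment is silent when noise is off
  expect_equal(max(abs(ep$values[, 1:s0, 1, 1])), 0)
})

test_that("simulation is deterministic given seed and config", {
  cb <- codebook8()
  ep1 <- simulate_epochs(cb, cfg8(seed = 7))
  ep2 <- simulate_epochs(cb, cfg8(seed = 7))
  expect_identical(ep1$values, ep2$values)
  ep3 <- simulate_epochs(cb, cfg8(seed = 8))
  expect_false(identical(ep1$values, ep3$values))

  rec1 <- simulate_continuous(cb, cfg8(seed = 7), trial_s = 4, rest_s = 2)
  rec2 <- simulate_continuous(cb, cfg8(seed = 7), trial_s = 4, rest_s = 2)
  expect_identical(rec1$values, rec2$values)
})

test_that("generation rejects harmonics at or above Nyquist", {
  cb <- make_codebook("custom", f_min = 20, f_max = 30, step = 1)
  cfg <- sim_config("custom", fs = 100, harmonic_amps = c(1, 0.5))
  expect_error(simulate_epochs(cb, cfg), "Nyquist")
})

test_that("two-harmonic epochs put their largest PSD peaks at f and 2f", {
  cb <- codebook8()
  cfg <- cfg8(noise_snr_db = Inf, harmonic_amps = c(1, 0.5),
              latency_sd_s = 0, n_blocks = 1)
  ep <- simulate_epochs(cb, cfg)
  segs <- sliding_segments(ep, 2.0, latency_s = cfg$latency_mean_s,
                           step_s = 0.1, stimuli = 3L)
  x <- segs[[1]]$values[1, ]
  n_total <- padded_length(cfg$fs, cb$delta_f_stim)
  p <- psd(x, cfg$fs, n_total)
  half <- p$values[1:(n_total %/% 2)]
  # two tallest local maxima (the fundamental's leakage shoulders on the
  # fine grid are not local maxima)
  i <- 2:(length(half) - 1)
  peaks <- i[half[i] > half[i - 1] & half[i] > half[i + 1]]
  top2 <- peaks[order(half[peaks], decreasing = TRUE)[1:2]]
  f_k <- cb$frequencies[3]
  expect_setequal(p$bin_hz[top2], c(f_k, 2 * f_k))
})

test_that("realized SNR stays within 1 dB of the configured value", {
  cb <- codebook8()
  target_db <- -5
  cfg_noisy <- cfg8(noise_snr_db = target_db, n_blocks = 13)  # 104 trials
  cfg_clean <- cfg8(noise_snr_db = Inf, n_blocks = 13)
  noisy <- simulate_epochs(cb, cfg_noisy)
  clean <- simulate_epochs(cb, cfg_clean)   # same seed: identical draws
  fs <- cfg_noisy$fs
  snr_db <- c()
  for (b in seq_len(13)) {
    s0 <- round_away((cfg_noisy$pre_stim_s + noisy$latency_s[b]) * fs)
    idx <- (s0 + 1):(s0 + round(cfg_noisy$stim_s * fs))
    for (k in seq_len(n_targets(cb))) {
      sig <- clean$values[1, idx, b, k]
      noise <- noisy$values[1, idx, b, k] - sig
      snr_db <- c(snr_db, 10 * log10(mean(sig^2) / mean(noise^2)))
    }
  }
  expect_gt(length(snr_db), 100)
  expect_lt(abs(mean(snr_db) - target_db), 1)
})

test_that("cross-correlation recovers the drawn per-block latency", {
  cb <- codebook8()
  cfg <- cfg8(n_blocks = 4, latency_sd_s = 0.02, seed = 3)
  ep <- simulate_epochs(cb, cfg)
  fs <- cfg$fs
  n_stim <- round(cfg$stim_s * fs)
  on0 <- round_away(cfg$pre_stim_s * fs)
  for (b in seq_len(4)) {
    # noiseless zero-latency template, correlated against the noisy trial
    lag_range <- round(fs * (cfg$latency_mean_s + c(-1, 1) * 0.06))
    best <- vapply(seq_len(n_targets(cb)), function(k) {
      t <- (0:(n_stim - 1)) / fs
      tmpl <- response_template(cb, k, t, cfg$harmonic_amps)
      score <- vapply(lag_range[1]:lag_range[2], function(lag) {
        idx <- on0 + lag + seq_len(n_stim)
        sum(vapply(1:cfg$n_channels, function(ch)
          sum(ep$values[ch, idx, b, k] * tmpl), numeric(1)))
      }, numeric(1))
      (lag_range[1]:lag_range[2])[which.max(score)]
    }, numeric(1))
    drawn <- round_away((cfg$pre_stim_s + ep$latency_s[b]) * fs) - on0
    expect_lte(max(abs(best - drawn)), 1)
  }
})
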