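test_that("band-pass rejects DC and stopband tones but passes the band", {
  fs <- 250
  spec <- filter_spec(5, 100)
  n <- fs * 4
  t <- (0:(n - 1)) / fs
  steady <- (n / 2):n  # skip the causal transient

  dc <- apply_bandpass(matrix(1, 1, n), spec, fs = fs)
  expect_lt(max(abs(dc[1, steady])), 0.01)

  inband <- apply_bandpass(matrix(sin(2 * pi * 10 * t), 1, n), spec, fs = fs)
  # steady-state amplitude close to unity (within the designed response)
  h10 <- freq_response_mag(spec, fs, 10)
  expect_lt(abs(max(abs(inband[1, steady])) - h10), 0.02)
  expect_gt(h10, 0.95)

  low <- apply_bandpass(matrix(sin(2 * pi * 0.5 * t), 1, n), spec, fs = fs)
  expect_lt(max(abs(low[1, steady])), 0.1)

  expect_error(apply_bandpass(matrix(0, 1, 10), filter_spec(5, 130), fs = fs),
               "Nyquist")
})

test_that("channel selection preserves order, duplicates and errors on absences", {
  m <- matrix(seq_len(64 * 10), 64, 10)
  rownames(m) <- c(occipital_channels(), sprintf("X%02d", 1:55))
  sel <- select_channels(m, occipital_channels())
  expect_equal(dim(sel), c(9L, 10L))
  expect_equal(rownames(sel), occipital_channels())

  dup <- select_channels(m, c("Oz", "Oz"))
  expect_equal(dup[1, ], dup[2, ])

  expect_error(select_channels(m[1:9, ], "Cz"), "Cz")
})

test_that("filtering and channel selection commute", {
  set.seed(1)
  m <- matrix(rnorm(5 * 500), 5, 500,
              dimnames = list(c("Pz", "Oz", "O1", "O2", "Cz"), NULL))
  spec <- filter_spec(5, 100)
  a <- select_channels(apply_bandpass(m, spec, fs = 250), c("Oz", "Pz"))
  b <- apply_bandpass(select_channels(m, c("Oz", "Pz")), spec, fs = 250)
  expect_equal(a, b, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("continuous recordings carry one onset marker per trial at exact spacing", {
  cb <- make_codebook("ssmvep")
  cfg <- sim_config("ssmvep", fs = 200, n_blocks = 1, seed = 2)
  rec <- simulate_continuous(cb, cfg, trial_s = 5, rest_s = 2)
  ev <- rec$values[nrow(rec$values), ]
  onsets <- which(ev >= 1 & ev <= 35)
  expect_length(onsets, 35L)
  expect_true(all(diff(onsets) == 5 * cfg$fs))
  expect_length(which(ev == 251), 35L)
  # every target appears exactly once
  expect_setequal(ev[onsets], 1:35)
})

test_that("parse_continuous inverts simulate_continuous sample-for-sample", {
  cb <- make_codebook("custom", f_min = 5, f_max = 8, step = 1)
  cfg <- sim_config("custom", fs = 100, n_channels = 2, n_blocks = 2,
                    stim_s = 2, seed = 5)
  rec <- simulate_continuous(cb, cfg, trial_s = 3, rest_s = 1)
  ep <- parse_continuous(rec, pre_s = 0.5, stim_s = 2, post_s = 0.5)
  expect_s3_class(ep, "epoch_array")
  expect_equal(dim(ep$values), c(2L, 300L, 2L, 4L))
  expect_equal(ep$stim_onset_s, 0.5)

  # each epoch's samples equal the corresponding slice of the recording
  ev <- rec$values[3, ]
  onsets <- which(ev >= 1 & ev <= 4)
  i <- 6L  # block 2, second trial
  k <- ev[onsets[i]]
  span <- (onsets[i] - 50):(onsets[i] + 249)
  expect_identical(ep$values[, , 2, k], unname(rec$values[1:2, span]))

  # SSMVEP-style layout arithmetic: 1 s + 3 s + 1 s at 1000 Hz = 5000 samples
  cfg2 <- sim_config("ssmvep", fs = 1000, n_blocks = 1, n_channels = 1,
                     seed = 1)
  rec2 <- simulate_continuous(make_codebook("ssmvep"), cfg2,
                              trial_s = 5, rest_s = 2)
  ep2 <- parse_continuous(rec2, pre_s = 1, stim_s = 3, post_s = 1)
  expect_equal(dim(ep2$values)[2], 5000L)
  expect_equal(dim(ep2$values)[4], 35L)

  # corrupting one marker is detected
  bad <- rec
  bad$values[3, onsets[2]] <- 0
  expect_error(parse_continuous(bad, 0.5, 2, 0.5), "marker|once")
})

test_that("sliding-window counts follow floor((stim - window)/step) + 1", {
  cb <- make_codebook("custom", f_min = 8, f_max = 9, step = 0.5)
  grid <- expand.grid(stim_s = c(1, 1.5, 2, 2.5, 3),
                      window_s = c(0.3, 0.5, 0.8, 1),
                      step_s = c(0.1, 0.2, 0.25, 0.4, 0.5))
  grid <- grid[grid$window_s <= grid$stim_s, ]
  expect_gte(nrow(grid), 90)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- sim_config("custom", fs = 40, n_channels = 1, n_blocks = 1,
                      stim_s = g$stim_s, noise_snr_db = Inf,
                      harmonic_amps = 1, post_stim_s = 1.2)
    ep <- simulate_epochs(cb, cfg)
    segs <- sliding_segments(ep, g$window_s, latency_s = 0.13,
                             step_s = g$step_s, stimuli = 1L)
    expect_equal(length(segs),
                 floor((g$stim_s - g$window_s) / g$step_s + 1e-9) + 1,
                 info = sprintf("stim=%g win=%g step=%g",
                                g$stim_s, g$window_s, g$step_s))
  }
})

test_that("sliding windows start at the latency-shifted onset", {
  cb <- codebook8()
  cfg <- cfg8(fs = 250, noise_snr_db = Inf, n_blocks = 1, latency_sd_s = 0)
  ep <- simulate_epochs(cb, cfg)
  # BETA-style arithmetic: onset 0.5 s + latency 0.13 s at 250 Hz -> 158
  segs <- sliding_segments(ep, 1.0, latency_s = 0.13, step_s = 0.1,
                           stimuli = 1L)
  expect_length(segs, 11L)       # floor((2 - 1)/0.1) + 1
  first_sample <- round_away((0.5 + 0.13) * 250)
  expect_equal(first_sample, 158)
  expect_identical(segs[[1]]$values[1, ],
                   ep$values[1, (first_sample + 1):(first_sample + 250), 1, 1])
  one <- sliding_segments(ep, cfg$stim_s, latency_s = 0.13, stimuli = 1L)
  expect_length(one, 1L)
  expect_error(sliding_segments(ep, 3.0, latency_s = 0.13), "window_s")
})

test_that("downsampling decimates with anti-aliasing and validates the factor", {
  fs <- 1000
  t <- (0:(fs * 2 - 1)) / fs
  x <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 10 * t + 1))
  expect_equal(decimation_factor(1000, 250), 4L)
  expect_error(decimation_factor(1000, 300), "integer")
  y <- downsample(x, 4)
  expect_equal(ncol(y), 500L)
  # a 10 Hz tone survives decimation to 250 Hz essentially unchanged
  t4 <- t[seq(1, length(t), by = 4)]
  expect_lt(max(abs(y[1, 100:400] - sin(2 * pi * 10 * t4)[100:400])), 0.02)
  expect_identical(downsample(x, 1), x)
  expect_error(downsample(x, 2.5), "integer")
})

test_that("time-to-index rounding is half away from zero", {
  expect_equal(round_away(c(0.5, 1.5, 2.5, -0.5, -1.5)), c(1, 2, 3, -1, -2))
  expect_equal(round_away(0.49), 0)
})
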