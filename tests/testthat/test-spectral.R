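test_that("padded_length aligns the bin grid with the stimulation grid", {
  expect_equal(padded_length(250, 0.2), 1250L)
  expect_equal(padded_length(1000, 0.5), 2000L)
  expect_equal(padded_length(250, 250), 1L)
  expect_error(padded_length(250, 0.3), "integer")
})

test_that("zero_pad appends exact zeros and preserves energy", {
  expect_identical(zero_pad(c(1, 2), 5), c(1, 2, 0, 0, 0))
  x <- rnorm(4)
  expect_identical(zero_pad(x, 4), x)
  expect_equal(sum(zero_pad(x, 64)^2), sum(x^2))
  expect_error(zero_pad(x, 3), "truncate")
})

test_that("fast DFT equals the direct transform sum", {
  x <- c(1, 1, 1, 1)
  X <- dft_spectrum(x, fs = 4)
  expect_equal(X$values[1], 4 + 0i)
  expect_lt(max(Mod(X$values[2:4])), 1e-12)

  n <- 32; k <- 5
  xc <- cos(2 * pi * k * (0:(n - 1)) / n)
  Xc <- dft_spectrum(xc, fs = n)
  expect_equal(Mod(Xc$values[k + 1]), n / 2, tolerance = 1e-9)

  set.seed(3)
  for (len in c(7, 16, 33)) {
    xr <- rnorm(len)
    expect_lt(max(Mod(dft_spectrum(xr, 1)$values - direct_dft(xr))), 1e-9)
  }
  expect_error(dft_spectrum(numeric(0), 1), "empty")
})

test_that("zero-padding samples the same spectrum on a finer grid", {
  # at coincident frequencies, padded and unpadded transforms agree exactly
  set.seed(11)
  for (case in 1:200) {
    n <- sample(8:64, 1)
    mult <- sample(2:5, 1)
    x <- rnorm(n)
    xu <- stats::fft(x)
    xp <- stats::fft(zero_pad(x, mult * n))
    m <- 0:(n - 1)
    expect_lt(max(Mod(xp[m * mult + 1] - xu[m + 1])), 1e-9)
  }
})

test_that("PSD follows |X|^2/(fs N) including the on-bin cosine closed form", {
  expect_equal(psd(numeric(16), 10)$values, numeric(16))
  fs <- 100; n <- 200; k <- 20; A <- 1.7
  x <- A * cos(2 * pi * k * (0:(n - 1)) / n)
  p <- psd(x, fs)
  expect_equal(p$values[k + 1], (A * n / 2)^2 / (fs * n), tolerance = 1e-9)
  expect_true(all(p$values >= 0))
  expect_error(psd(x, fs = 0), "fs")

  # padding scales the PSD by the 1/N factor of the padded length
  n_tot <- 4 * n
  pp <- psd(x, fs, n_tot)
  expect_equal(pp$values[4 * k + 1], p$values[k + 1] * n / n_tot,
               tolerance = 1e-9)
})

test_that("leakage envelope is N/2 times sinc(k - m)", {
  expect_equal(leakage_amplitude(10, 10, 100), 50)
  expect_equal(leakage_amplitude(10.5, 10, 100), 100 / pi, tolerance = 1e-12)
  expect_equal(leakage_amplitude(12, 10, 100), 0, tolerance = 1e-12)
  # matches the measured DFT of an off-bin cosine away from the image term
  n <- 1024; k <- 100.25
  x <- cos(2 * pi * k * (0:(n - 1)) / n)
  X <- Mod(stats::fft(x))
  for (m in 98:103)
    expect_equal(X[m + 1], abs(leakage_amplitude(k, m, n)),
                 tolerance = 0.02)
})

test_that("band bins land exactly on the harmonic frequencies", {
  beta <- make_codebook("beta")
  n_tot <- padded_length(250, 0.2)
  b1 <- band_bins(beta, 1, 250, n_tot)
  expect_equal(b1, 40:79)
  expect_equal((0.2 * b1), beta$frequencies)
  b2 <- band_bins(beta, 2, 250, n_tot)
  expect_equal(0.2 * b2, 2 * beta$frequencies)
  expect_equal(range(0.2 * b2), c(16, 31.6))

  ssm <- make_codebook("ssmvep")
  n_tot2 <- padded_length(1000, 0.5)
  expect_equal(0.5 * band_bins(ssm, 1, 1000, n_tot2), seq(3, 20, by = 0.5))

  expect_error(band_bins(beta, 8, 250, n_tot), "Nyquist")
  expect_error(band_bins(beta, 1, 250, 1000), "align")
})

test_that("feature matrices have the documented shape and [0,1] scaling", {
  beta <- make_codebook("beta")
  cfg <- sim_config("beta", noise_snr_db = 0, n_blocks = 1, seed = 2)
  ep <- simulate_epochs(beta, cfg)
  seg <- sliding_segments(ep, 1.0, latency_s = 0.13, stimuli = 7L)[[1]]
  fm <- build_feature_matrix(seg, beta, n_bands = 2)
  expect_equal(dim(fm$values), c(80L, 9L))
  expect_equal(range(fm$values), c(0, 1))
  expect_equal(fm$label, 7L)
  expect_equal(fm$band_layout$freq_hz[1:40], beta$frequencies)
  expect_equal(fm$band_layout$freq_hz[41:80], 2 * beta$frequencies)

  ssm <- make_codebook("ssmvep")
  seg2 <- list(values = matrix(rnorm(9 * 700), 9), fs = 1000)
  fm2 <- build_feature_matrix(seg2$values, ssm, n_bands = 2, fs = 1000)
  expect_equal(dim(fm2$values), c(70L, 9L))

  # degenerate rescale: constant segment maps to the all-zero matrix
  fm3 <- build_feature_matrix(matrix(0, 2, 250), beta, fs = 250)
  expect_true(all(fm3$values == 0))
})

test_that("feature matrices are invariant to input gain", {
  cb <- codebook8()
  cfg <- cfg8(n_blocks = 1, seed = 9)
  ep <- simulate_epochs(cb, cfg)
  seg <- sliding_segments(ep, 1.0, latency_s = 0.13, stimuli = 2L)[[1]]
  f1 <- build_feature_matrix(seg, cb)
  seg$values <- 3.7 * seg$values
  f2 <- build_feature_matrix(seg, cb)
  expect_equal(f1$values, f2$values, tolerance = 1e-12)
})

test_that("noiseless class-k segments peak in feature row k", {
  for (preset in c("beta", "ssmvep")) {
    cb <- make_codebook(preset)
    cfg <- sim_config(preset, noise_snr_db = Inf, latency_sd_s = 0,
                      n_blocks = 1, seed = 1)
    ep <- simulate_epochs(cb, cfg)
    segs <- sliding_segments(ep, 1.0, latency_s = cfg$latency_mean_s,
                             step_s = cfg$stim_s)  # one window per target
    for (seg in segs) {
      fm <- build_feature_matrix(seg, cb, n_bands = 1)
      expect_equal(unname(apply(fm$values, 2, which.max)),
                   rep(seg$label, ncol(fm$values)),
                   info = paste(preset, "target", seg$label))
    }
  }
})

test_that("zero-padded features separate adjacent classes better than unpadded", {
  # three adjacent 0.2 Hz targets; mean between-class distance of the
  # class-average feature matrices, padded vs unpadded
  cb <- codebook8()
  cfg <- cfg8(fs = 250, n_channels = 2, n_blocks = 10, noise_snr_db = -5,
              seed = 4)
  ep <- simulate_epochs(cb, cfg)
  classes <- 3:5
  dist_between <- function(pad) {
    feats <- lapply(classes, function(k) {
      segs <- sliding_segments(ep, 1.0, latency_s = 0.13, step_s = 0.05,
                               stimuli = k)
      mats <- lapply(segs, function(s)
        build_feature_matrix(s, cb, n_bands = 2, pad = pad)$values)
      Reduce(`+`, mats) / length(mats)
    })
    pairs <- utils::combn(seq_along(classes), 2)
    mean(apply(pairs, 2, function(ij)
      sqrt(sum((feats[[ij[1]]] - feats[[ij[2]]])^2))))
  }
  expect_gt(dist_between(TRUE), dist_between(FALSE))
})
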