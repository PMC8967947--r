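#' The nine occipito-parietal electrode labels used for frequency recognition
#'
#' SSVEP/SSMVEP responses are strongest over visual cortex; analyses in this
#' package default to the standard nine-electrode montage Pz, PO5, PO3, POz,
#' PO4, PO6, O1, Oz, O2.
#'
#' @return Character vector of length 9.
#' @export
occipital_channels <- function() {
  c("Pz", "PO5", "PO3", "POz", "PO4", "PO6", "O1", "Oz", "O2")
}

#' Configuration for the synthetic EEG generator
#'
#' The generator emulates the statistical structure the spectral classifier
#' relies on: per-class sinusoidal responses at the stimulation frequency and
#' its harmonics (phase-coded), delayed by a per-block visual latency, on top
#' of a 1/f-plus-white background.  Presets mirror the two recording setups
#' the package targets:
#'
#' * `"beta"`: 250 Hz, 9 channels, epochs of 0.5 s pre-stimulus + 2 s
#'   stimulation + 0.5 s post-stimulus, 4 blocks, strong second harmonic
#'   (`harmonic_amps = c(1, 0.5)`), 130 ms mean visual latency.
#' * `"ssmvep"`: 1000 Hz, 9 channels, 1 s + 3 s + 1 s epochs, 3 blocks,
#'   near-absent second harmonic (`c(1, 0.05)`), 107.61 ms mean latency
#'   (reported subject average for the motion paradigm, SD 16.63 ms).
#'
#' Harmonic amplitudes are relative to the fundamental (`harmonic_amps[1]`).
#' `noise_snr_db` is the ratio, in dB, of oscillatory signal power to total
#' background-noise power over the stimulation segment of each channel;
#' `Inf` disables noise.  The background mixes pink noise (power spectrum
#' proportional to 1/f^`pink_exponent`) and white noise in equal power.
#'
#' @param preset `"beta"`, `"ssmvep"`, or `"custom"` (take the defaults
#'   below, then override).
#' @param fs Sampling rate in Hz.
#' @param n_channels Number of EEG channels.
#' @param harmonic_amps Numeric vector of relative harmonic amplitudes,
#'   entry `h` scaling the component at `h` times the stimulation frequency.
#' @param noise_snr_db Signal-to-noise ratio in dB (see above).
#' @param pink_exponent Spectral exponent of the pink-noise component.
#' @param latency_mean_s,latency_sd_s Mean and SD (seconds) of the visual
#'   latency, drawn once per block.
#' @param pre_stim_s,stim_s,post_stim_s Epoch layout in seconds.
#' @param n_blocks Number of repetition blocks (one trial per target each).
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(preset = c("custom", "beta", "ssmvep"),
                       fs = NULL, n_channels = 9L, harmonic_amps = NULL,
                       noise_snr_db = -5, pink_exponent = 1,
                       latency_mean_s = NULL, latency_sd_s = 0.01,
                       pre_stim_s = NULL, stim_s = NULL, post_stim_s = NULL,
                       n_blocks = NULL, seed = 1L) {
  preset <- match.arg(preset)
  def <- switch(preset,
    beta   = list(fs = 250, harmonic_amps = c(1, 0.5),
                  latency_mean_s = 0.13, pre_stim_s = 0.5, stim_s = 2,
                  post_stim_s = 0.5, n_blocks = 4L),
    ssmvep = list(fs = 1000, harmonic_amps = c(1, 0.05),
                  latency_mean_s = 0.10761, latency_sd_s = 0.01663,
                  pre_stim_s = 1, stim_s = 3, post_stim_s = 1,
                  n_blocks = 3L),
    custom = list(fs = 250, harmonic_amps = c(1, 0.5),
                  latency_mean_s = 0.13, pre_stim_s = 0.5, stim_s = 2,
                  post_stim_s = 0.5, n_blocks = 4L))
  pick <- function(x, d) if (is.null(x)) d else x
  cfg <- list(fs = pick(fs, def$fs),
              n_channels = as.integer(n_channels),
              harmonic_amps = pick(harmonic_amps, def$harmonic_amps),
              noise_snr_db = noise_snr_db,
              pink_exponent = pink_exponent,
              latency_mean_s = pick(latency_mean_s, def$latency_mean_s),
              latency_sd_s = if (preset == "ssmvep" && missing(latency_sd_s))
                def$latency_sd_s else latency_sd_s,
              pre_stim_s = pick(pre_stim_s, def$pre_stim_s),
              stim_s = pick(stim_s, def$stim_s),
              post_stim_s = pick(post_stim_s, def$post_stim_s),
              n_blocks = as.integer(pick(n_blocks, def$n_blocks)),
              seed = as.integer(seed),
              preset = preset)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$fs > 0, cfg$n_channels >= 1,
            cfg$pre_stim_s >= 0, cfg$stim_s > 0, cfg$post_stim_s >= 0,
            cfg$n_blocks >= 1)
  if (any(cfg$harmonic_amps < 0)) stop("harmonic_amps must be nonnegative")
  if (cfg$latency_mean_s < 0) stop("latency_mean_s must be nonnegative")
  if (cfg$latency_sd_s < 0) stop("latency_sd_s must be nonnegative")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config '%s'> fs=%g Hz, %d ch, %d blocks, ",
                     "SNR=%g dB, harmonics [%s], latency %g+/-%g s\n"),
              x$preset, x$fs, x$n_channels, x$n_blocks, x$noise_snr_db,
              paste(x$harmonic_amps, collapse = ", "),
              x$latency_mean_s, x$latency_sd_s))
  invisible(x)
}

# Evaluate an expression with a private, restored RNG stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Unit-power pink noise (power ~ 1/f^exponent) via spectral shaping of a
# white Gaussian series; consumes exactly n normal deviates.
pink_noise_unit <- function(n, exponent = 1) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w / stats::sd(w))
  X <- stats::fft(w)
  # symmetric |frequency| per bin; DC removed
  k <- c(0, pmin(seq_len(n - 1L), n - seq_len(n - 1L)))
  scale <- c(0, k[-1]^(-exponent / 2))
  p <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  p / sqrt(mean(p^2))
}

# Background noise with unit power: equal-power pink + white mixture.
background_noise_unit <- function(n, pink_exponent) {
  pk <- pink_noise_unit(n, pink_exponent)
  wh <- stats::rnorm(n)
  wh <- wh / sqrt(mean(wh^2))
  x <- sqrt(0.5) * pk + sqrt(0.5) * wh
  x / sqrt(mean(x^2))
}

#' Noise-free response template of one stimulation target
#'
#' The multi-harmonic waveform
#' `sum_h harmonic_amps[h] * sin(2 pi h f_k t + h phi_k)` the generator
#' embeds for target `k`, sampled at times `t` (seconds after response
#' onset).  Useful as a matched template, e.g. for latency estimation by
#' cross-correlation.
#'
#' @param codebook A [make_codebook()] object.
#' @param k Target index.
#' @param t Numeric vector of times in seconds.
#' @param harmonic_amps Relative harmonic amplitudes.
#' @return Numeric vector, `length(t)`.
#' @export
response_template <- function(codebook, k, t, harmonic_amps = c(1, 0.5)) {
  response_wave(t, codebook$frequencies[k], codebook$phases[k],
                harmonic_amps)
}

# Multi-harmonic response waveform for target k, sampled at t seconds after
# response onset.
response_wave <- function(t, f_k, phi_k, harmonic_amps) {
  s <- numeric(length(t))
  for (h in seq_along(harmonic_amps)) {
    if (harmonic_amps[h] == 0) next
    s <- s + harmonic_amps[h] * sin(2 * pi * h * f_k * t + h * phi_k)
  }
  s
}

check_nyquist <- function(codebook, cfg) {
  h_max <- length(cfg$harmonic_amps)
  top <- h_max * max(codebook$frequencies)
  if (top >= cfg$fs / 2)
    stop(sprintf("harmonic at %g Hz is at or above Nyquist (fs/2 = %g Hz)",
                 top, cfg$fs / 2))
}

#' Simulate epoched multichannel SSVEP/SSMVEP recordings
#'
#' Produces a 4-D epoch array in the `channels x samples x blocks x targets`
#' layout.  For target `k` the stimulation segment of every channel carries
#' `sum_h harmonic_amps[h] * sin(2 pi h f_k t + h phi_k)`, shifted by a
#' visual latency drawn once per block from
#' `Normal(latency_mean_s, latency_sd_s)`; the pre- and post-stimulus
#' segments are background noise only.  Each channel applies an independent
#' gain drawn uniformly from `[0.5, 1]` to the oscillatory component and
#' adds independent pink-plus-white noise scaled to `noise_snr_db`.
#'
#' Output is deterministic given `cfg$seed`; the global RNG state is left
#' untouched.  The drawn per-block latencies are stored in the result
#' (`$latency_s`) as simulation ground truth.
#'
#' @param codebook A [make_codebook()] object.
#' @param cfg A [sim_config()] object.
#' @return Object of class `epoch_array`: list with `values` (4-D array),
#'   `fs`, `channel_labels`, `codebook`, `stim_onset_s` (stimulation onset
#'   within the epoch, seconds), `stim_s`, `latency_s`, `config`.
#' @export
simulate_epochs <- function(codebook, cfg) {
  stopifnot(inherits(codebook, "stim_codebook"), inherits(cfg, "sim_config"))
  check_nyquist(codebook, cfg)
  K <- n_targets(codebook)
  fs <- cfg$fs
  len <- round((cfg$pre_stim_s + cfg$stim_s + cfg$post_stim_s) * fs)
  n_stim <- round(cfg$stim_s * fs)
  labels <- if (cfg$n_channels == 9L) occipital_channels() else
    sprintf("Ch%02d", seq_len(cfg$n_channels))

  with_seed(cfg$seed, {
    gains <- stats::runif(cfg$n_channels, 0.5, 1)
    lat <- pmax(0, stats::rnorm(cfg$n_blocks, cfg$latency_mean_s,
                                cfg$latency_sd_s))
    sigma_scale <- if (is.infinite(cfg$noise_snr_db)) 0 else
      10^(-cfg$noise_snr_db / 20)
    vals <- array(0, dim = c(cfg$n_channels, len, cfg$n_blocks, K))
    for (b in seq_len(cfg$n_blocks)) {
      s0 <- round_away((cfg$pre_stim_s + lat[b]) * fs)  # 0-based onset
      idx <- s0 + seq_len(min(n_stim, len - s0))        # 1-based sample ids
      t <- (seq_along(idx) - 1L) / fs
      for (k in seq_len(K)) {
        wave <- response_wave(t, codebook$frequencies[k],
                              codebook$phases[k], cfg$harmonic_amps)
        sig_pow <- mean(wave^2)
        for (ch in seq_len(cfg$n_channels)) {
          noise <- background_noise_unit(len, cfg$pink_exponent)
          x <- sigma_scale * sqrt(sig_pow) * gains[ch] * noise
          x[idx] <- x[idx] + gains[ch] * wave
          vals[ch, , b, k] <- x
        }
      }
    }
    structure(list(values = vals, fs = fs, channel_labels = labels,
                   codebook = codebook, stim_onset_s = cfg$pre_stim_s,
                   stim_s = cfg$stim_s, latency_s = lat,
                   channel_gains = gains, config = cfg),
              class = "epoch_array")
  })
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(paste0("<epoch_array> %d ch x %d samples x %d blocks x %d ",
                     "targets @ %g Hz (stim onset %g s)\n"),
              d[1], d[2], d[3], d[4], x$fs, x$stim_onset_s))
  invisible(x)
}

#' Simulate a raw continuous recording with an event/label channel
#'
#' Emulates an unsegmented acquisition: per block, every codebook target is
#' presented once in random order; a trial lasts `trial_s` seconds
#' (`stim_s` of stimulation followed by `rest_s` of rest).  The last channel
#' of the output is an event track: the sample at which stimulation of
#' target `k` starts carries marker code `k`, and the sample at which it
#' ends carries code 251.  The evoked response follows stimulation onset by
#' the per-block visual latency.  A rest-only lead-in of `rest_s` seconds
#' precedes the first trial so that epoching with a pre-stimulus span is
#' always possible.
#'
#' @param codebook A [make_codebook()] object.
#' @param cfg A [sim_config()] object (its `stim_s` is used).
#' @param trial_s Total trial duration in seconds; must equal
#'   `cfg$stim_s + rest_s`.
#' @param rest_s Rest duration after each stimulation, seconds (>= 0).
#' @return Object of class `continuous_recording`: list with `values`
#'   (`(n_channels + 1) x samples`, last row the event track), `fs`,
#'   `channel_labels` (last entry `"EVENT"`), `codebook`, plus ground-truth
#'   `latency_s` and `target_order`.
#' @export
simulate_continuous <- function(codebook, cfg, trial_s, rest_s) {
  stopifnot(inherits(codebook, "stim_codebook"), inherits(cfg, "sim_config"))
  if (rest_s < 0) stop("rest_s must be nonnegative")
  if (abs(trial_s - (cfg$stim_s + rest_s)) > 1e-9)
    stop("trial_s must equal cfg$stim_s + rest_s")
  check_nyquist(codebook, cfg)
  K <- n_targets(codebook)
  fs <- cfg$fs
  n_trial <- round(trial_s * fs)
  n_stim <- round(cfg$stim_s * fs)
  lead <- round(rest_s * fs)         # rest-only lead-in before trial 1
  total <- n_trial * K * cfg$n_blocks + lead
  labels <- c(if (cfg$n_channels == 9L) occipital_channels() else
                sprintf("Ch%02d", seq_len(cfg$n_channels)), "EVENT")

  with_seed(cfg$seed, {
    gains <- stats::runif(cfg$n_channels, 0.5, 1)
    lat <- pmax(0, stats::rnorm(cfg$n_blocks, cfg$latency_mean_s,
                                cfg$latency_sd_s))
    order <- vapply(seq_len(cfg$n_blocks), function(b) sample.int(K),
                    integer(K))                       # K x n_blocks
    sigma_scale <- if (is.infinite(cfg$noise_snr_db)) 0 else
      10^(-cfg$noise_snr_db / 20)
    eeg <- matrix(0, cfg$n_channels, total)
    events <- numeric(total)
    sig_pow_acc <- 0
    # oscillatory layer first, so noise can be scaled to mean signal power
    for (b in seq_len(cfg$n_blocks)) {
      lat_n <- round_away(lat[b] * fs)
      for (j in seq_len(K)) {
        k <- order[j, b]
        t0 <- lead + (b - 1L) * K * n_trial + (j - 1L) * n_trial  # 0-based
        events[t0 + 1L] <- k
        events[t0 + n_stim + 1L] <- 251
        idx <- t0 + lat_n + seq_len(min(n_stim, total - t0 - lat_n))
        t <- (seq_along(idx) - 1L) / fs
        wave <- response_wave(t, codebook$frequencies[k],
                              codebook$phases[k], cfg$harmonic_amps)
        sig_pow_acc <- sig_pow_acc + mean(wave^2)
        for (ch in seq_len(cfg$n_channels))
          eeg[ch, idx] <- eeg[ch, idx] + gains[ch] * wave
      }
    }
    mean_sig_pow <- sig_pow_acc / (K * cfg$n_blocks)
    for (ch in seq_len(cfg$n_channels)) {
      noise <- background_noise_unit(total, cfg$pink_exponent)
      eeg[ch, ] <- eeg[ch, ] +
        sigma_scale * sqrt(mean_sig_pow) * gains[ch] * noise
    }
    vals <- rbind(eeg, events)
    dimnames(vals) <- list(labels, NULL)
    structure(list(values = vals, fs = fs,
                   channel_labels = labels, codebook = codebook,
                   latency_s = lat, target_order = order, config = cfg,
                   stim_s = cfg$stim_s, rest_s = rest_s),
              class = "continuous_recording")
  })
}

#' @export
print.continuous_recording <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<continuous_recording> %d ch (+event) x %d samples @ %g Hz\n",
              d[1] - 1L, d[2], x$fs))
  invisible(x)
}
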