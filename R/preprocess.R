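#' Round half away from zero
#'
#' All time-to-sample-index conversions in the package use round-half-away-
#' from-zero (the convention of most DSP environments), not banker's
#' rounding.
#'
#' @param x Numeric vector.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @examples
#' round_away(c(0.5, 1.5, -0.5))  # 1  2 -1
#' @export
round_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' IIR band-pass filter specification
#'
#' A causal Butterworth band-pass, the workhorse for removing drift and
#' line/muscle noise before spectral feature extraction.  Typical choices:
#' 5--100 Hz for 250 Hz epoched recordings, 2--102 Hz for 1000 Hz raw
#' recordings.
#'
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz`.
#' @param order Filter order (default 4).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz, high_hz, order = 4L) {
  stopifnot(low_hz > 0, high_hz > low_hz, order >= 1)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 kind = "butterworth-bandpass"),
            class = "filter_spec")
}

#' Apply a causal IIR band-pass filter channel-wise
#'
#' Single-pass (causal) filtering, matching the semantics of a conventional
#' `filter()` call in DSP environments; zero-phase forward-backward
#' filtering is available behind `zero_phase = TRUE` but is off by default.
#' Accepts a channels-by-samples matrix, an [epoch_array][simulate_epochs]
#' (each epoch filtered independently) or a
#' [continuous_recording][simulate_continuous] (the event track is left
#' untouched).
#'
#' @param x Matrix, `epoch_array`, or `continuous_recording`.
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz (taken from the object when it carries one).
#' @param zero_phase Use forward-backward filtering instead of causal.
#' @return Same shape/class as the input.
#' @export
apply_bandpass <- function(x, spec, fs = NULL, zero_phase = FALSE) {
  stopifnot(inherits(spec, "filter_spec"))
  if (inherits(x, "epoch_array")) {
    flt <- design_bandpass(spec, x$fs)
    v <- x$values
    d <- dim(v)
    for (b in seq_len(d[3])) for (k in seq_len(d[4]))
      v[, , b, k] <- filter_rows(v[, , b, k, drop = FALSE][, , 1, 1],
                                 flt, zero_phase)
    x$values <- v
    return(x)
  }
  if (inherits(x, "continuous_recording")) {
    flt <- design_bandpass(spec, x$fs)
    n <- nrow(x$values)
    x$values[-n, ] <- filter_rows(x$values[-n, , drop = FALSE], flt,
                                  zero_phase)
    return(x)
  }
  if (is.null(fs)) stop("fs is required for plain matrix input")
  flt <- design_bandpass(spec, fs)
  filter_rows(as.matrix(x), flt, zero_phase)
}

#' Magnitude response of a designed band-pass filter at given frequencies
#'
#' Evaluates `|H(e^{i 2 pi f / fs})|` of the Butterworth band-pass that
#' [apply_bandpass()] would apply, e.g. to verify passband gain or stopband
#' attenuation.
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz.
#' @param freq_hz Frequencies at which to evaluate, Hz.
#' @return Numeric vector of magnitudes.
#' @export
freq_response_mag <- function(spec, fs, freq_hz) {
  flt <- design_bandpass(spec, fs)
  w <- 2 * pi * freq_hz / fs
  vapply(w, function(wi) {
    z <- exp(-1i * wi * (seq_along(flt$b) - 1))
    zp <- exp(-1i * wi * (seq_along(flt$a) - 1))
    Mod(sum(flt$b * z) / sum(flt$a * zp))
  }, numeric(1))
}

design_bandpass <- function(spec, fs) {
  nyq <- fs / 2
  if (spec$high_hz >= nyq)
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                 spec$high_hz, nyq))
  signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                 type = "pass")
}

filter_rows <- function(m, flt, zero_phase) {
  out <- m
  for (i in seq_len(nrow(m))) {
    out[i, ] <- if (zero_phase) signal::filtfilt(flt, m[i, ])
    else as.numeric(signal::filter(flt, m[i, ]))
  }
  out
}

#' Select (and reorder) channels by label
#'
#' Returns the requested rows in the requested order; a label may be
#' repeated.  Missing labels raise an error naming the absent channels.
#'
#' @param x Matrix with rownames, `epoch_array`, or `continuous_recording`
#'   (the event track is preserved as the final channel).
#' @param labels Character vector of channel labels to keep, in order.
#' @param channel_labels Labels of the rows of `x` when `x` is a plain
#'   matrix without rownames.
#' @return Same class as input, restricted to the requested channels.
#' @export
select_channels <- function(x, labels, channel_labels = NULL) {
  if (inherits(x, "epoch_array")) {
    idx <- match_channels(labels, x$channel_labels)
    x$values <- x$values[idx, , , , drop = FALSE]
    x$channel_labels <- labels
    return(x)
  }
  if (inherits(x, "continuous_recording")) {
    have <- x$channel_labels
    idx <- match_channels(labels, have[-length(have)])
    x$values <- x$values[c(idx, nrow(x$values)), , drop = FALSE]
    x$channel_labels <- c(labels, "EVENT")
    return(x)
  }
  have <- if (!is.null(channel_labels)) channel_labels else rownames(x)
  if (is.null(have)) stop("channel labels are required for matrix input")
  x[match_channels(labels, have), , drop = FALSE]
}

match_channels <- function(labels, have) {
  idx <- match(labels, have)
  if (anyNA(idx))
    stop("channels not present: ",
         paste(labels[is.na(idx)], collapse = ", "))
  idx
}

#' Cut a continuous recording into a 4-D epoch array using its event track
#'
#' Scans the last (event) channel for stimulation-onset markers (codes
#' `1..K`), checks that every target appears exactly once per block, and
#' cuts epochs of `pre_s` seconds before onset, the stimulation period, and
#' `post_s` seconds after stimulation end.
#'
#' @param rec A [simulate_continuous()] object (or compatible list).
#' @param pre_s,stim_s,post_s Epoch layout in seconds.
#' @return An [epoch_array][simulate_epochs] with
#'   `samples = round((pre_s + stim_s + post_s) * fs)` per epoch and
#'   `stim_onset_s = pre_s`.
#' @export
parse_continuous <- function(rec, pre_s, stim_s, post_s) {
  stopifnot(inherits(rec, "continuous_recording") || is.list(rec))
  K <- n_targets(rec$codebook)
  fs <- rec$fs
  ev <- rec$values[nrow(rec$values), ]
  onsets <- which(ev >= 1 & ev <= K)        # 1-based onset samples
  codes <- ev[onsets]
  if (length(onsets) %% K != 0)
    stop(sprintf("expected a multiple of %d onset markers, found %d",
                 K, length(onsets)))
  n_blocks <- length(onsets) %/% K
  for (b in seq_len(n_blocks)) {
    blk <- codes[((b - 1L) * K + 1L):(b * K)]
    if (!setequal(blk, seq_len(K)))
      stop(sprintf("block %d does not contain each target exactly once", b))
  }
  n_pre <- round_away(pre_s * fs)
  n_len <- round((pre_s + stim_s + post_s) * fs)
  n_ch <- nrow(rec$values) - 1L
  total <- ncol(rec$values)
  vals <- array(0, dim = c(n_ch, n_len, n_blocks, K))
  for (i in seq_along(onsets)) {
    b <- (i - 1L) %/% K + 1L
    k <- codes[i]
    start <- onsets[i] - n_pre              # 1-based epoch start
    if (start < 1L || start + n_len - 1L > total)
      stop("epoch extends beyond the recording; reduce pre_s/post_s")
    vals[, , b, k] <- rec$values[seq_len(n_ch), start:(start + n_len - 1L)]
  }
  structure(list(values = vals, fs = fs,
                 channel_labels = rec$channel_labels[seq_len(n_ch)],
                 codebook = rec$codebook, stim_onset_s = pre_s,
                 stim_s = stim_s, latency_s = rec$latency_s,
                 config = rec$config),
            class = "epoch_array")
}

#' Cut latency-shifted sliding windows out of epochs
#'
#' A window of `window_s` seconds slides in steps of `step_s` over the
#' stimulation period of each epoch, shifted by the subject's visual latency:
#' the first window starts at sample
#' `round((stim_onset_s + latency_s) * fs)` and the analysis span ends at
#' `round((stim_onset_s + latency_s + stim_s) * fs)`, so every epoch yields
#' `floor((stim_s - window_s) / step_s) + 1` windows.  Windows are half-open
#' sample ranges.
#'
#' @param epochs An [epoch_array][simulate_epochs].
#' @param window_s Window length in seconds (must not exceed the
#'   stimulation duration).
#' @param latency_s Visual latency in seconds (defaults: 0.13 for the
#'   40-target flicker setup, 0.10761 for the 35-target motion setup).
#' @param step_s Slide step in seconds (default 0.1).
#' @param blocks,stimuli Optional integer subsets of blocks / targets.
#' @return List of `segment` objects, each a list with `values`
#'   (channels x samples), `fs`, `label` (target index), `window_s`,
#'   `block`.
#' @export
sliding_segments <- function(epochs, window_s, latency_s = 0.13,
                             step_s = 0.1, blocks = NULL, stimuli = NULL) {
  stopifnot(inherits(epochs, "epoch_array"))
  stim_s <- epochs$stim_s
  if (window_s > stim_s) stop("window_s must not exceed the stimulation span")
  if (latency_s < 0) stop("latency_s must be nonnegative")
  fs <- epochs$fs
  d <- dim(epochs$values)
  if (is.null(blocks)) blocks <- seq_len(d[3])
  if (is.null(stimuli)) stimuli <- seq_len(d[4])
  n_win <- floor((stim_s - window_s) / step_s + 1e-9) + 1L
  w_len <- round(window_s * fs)
  step_n <- round_away(step_s * fs)
  first <- round_away((epochs$stim_onset_s + latency_s) * fs)  # 0-based
  out <- vector("list", length(blocks) * length(stimuli) * n_win)
  i <- 0L
  for (b in blocks) for (k in stimuli) for (w in seq_len(n_win)) {
    s0 <- first + (w - 1L) * step_n
    if (s0 + w_len > d[2]) stop("window extends beyond the epoch")
    i <- i + 1L
    v <- epochs$values[, (s0 + 1L):(s0 + w_len), b, k, drop = FALSE]
    dim(v) <- dim(v)[1:2]
    rownames(v) <- epochs$channel_labels
    out[[i]] <- structure(
      list(values = v, fs = fs, label = k, window_s = window_s, block = b),
      class = "segment")
  }
  out
}

#' Decimate a multichannel signal by an integer factor
#'
#' Anti-alias filters (8th-order Chebyshev type I low-pass, the standard
#' `decimate` design) and keeps every `factor`-th sample of each row.
#'
#' @param x Channels-by-samples matrix.
#' @param factor Positive integer decimation factor; `1` is the identity.
#' @return Matrix with `ceiling(ncol(x) / factor)` columns.
#' @export
downsample <- function(x, factor) {
  if (length(factor) != 1 || factor < 1 || abs(factor - round(factor)) > 1e-9)
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  x <- as.matrix(x)
  if (factor == 1L) return(x)
  out <- NULL
  for (i in seq_len(nrow(x))) {
    y <- signal::decimate(x[i, ], factor)
    if (is.null(out)) out <- matrix(0, nrow(x), length(y))
    out[i, ] <- y
  }
  rownames(out) <- rownames(x)
  out
}

#' Decimation factor for a target sampling rate
#'
#' @param fs Current sampling rate (Hz).
#' @param target_fs Desired rate (Hz); must divide `fs` evenly.
#' @return Integer factor such that `fs / factor == target_fs`.
#' @export
decimation_factor <- function(fs, target_fs) {
  f <- fs / target_fs
  if (abs(f - round(f)) > 1e-9)
    stop(sprintf("%g Hz is not an integer decimation of %g Hz", target_fs, fs))
  as.integer(round(f))
}
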