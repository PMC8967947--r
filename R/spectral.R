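#' Transform length that aligns DFT bins with the stimulation grid
#'
#' The DFT of an `n`-point signal samples its spectrum every `fs / n` Hz
#' (the picket fence effect: off-bin peaks are invisible).  Appending zeros
#' before the transform samples the same spectrum on a finer grid; choosing
#' the padded length `n_total = fs / delta_f_target` puts a bin exactly on
#' every stimulation frequency when the stimulation grid has spacing
#' `delta_f_target`.
#'
#' @param fs Sampling rate in Hz.
#' @param delta_f_target Desired bin spacing in Hz (the minimum gap between
#'   stimulation frequencies).
#' @return Integer transform length `round(fs / delta_f_target)`.
#' @examples
#' padded_length(250, 0.2)   # 1250
#' padded_length(1000, 0.5)  # 2000
#' @export
padded_length <- function(fs, delta_f_target) {
  stopifnot(fs > 0, delta_f_target > 0)
  ratio <- fs / delta_f_target
  if (abs(ratio - round(ratio)) > 1e-6 * max(1, ratio))
    stop(sprintf(
      "fs/delta_f_target = %g is not an integer; bins cannot align with the stimulation grid",
      ratio))
  as.integer(round(ratio))
}

#' Zero-pad a signal to a given transform length
#'
#' Appends `n_total - length(x)` zeros.  Padding adds no energy and no new
#' information; it only refines the frequency grid on which the DFT samples
#' the signal's spectrum.
#'
#' @param x Numeric vector.
#' @param n_total Target length, at least `length(x)`.
#' @return Numeric vector of length `n_total`.
#' @export
zero_pad <- function(x, n_total) {
  n <- length(x)
  if (n_total < n) stop("n_total must be at least length(x); padding never truncates")
  c(x, numeric(n_total - n))
}

#' Discrete Fourier transform with bin frequencies
#'
#' `values[m + 1] = sum_n x[n] exp(-i 2 pi n m / N)` (bins indexed from
#' `m = 0`), computed with a fast transform.
#'
#' @param x Numeric vector (finite, non-empty).
#' @param fs Sampling rate in Hz.
#' @return Object of class `zp_spectrum`: list with complex `values`,
#'   `bin_hz` (`m * fs / N`), and `fs`.
#' @export
dft_spectrum <- function(x, fs) {
  if (length(x) == 0) stop("empty input")
  if (!all(is.finite(x))) stop("input must be finite")
  n <- length(x)
  structure(list(values = stats::fft(x),
                 bin_hz = (seq_len(n) - 1) * fs / n,
                 fs = fs),
            class = "zp_spectrum")
}

#' Power spectral density of a (possibly zero-padded) signal
#'
#' `P(m) = |X(m)|^2 / (fs * N)` with `N` the transform length after
#' padding.  Only the one-sided part (`m <= N/2`) is meaningful for real
#' signals; no doubling factor is applied.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz (> 0).
#' @param n_total Transform length; defaults to `length(x)` (no padding).
#' @return Object of class `psd_vector`: list with nonnegative `values`,
#'   `bin_hz`, `fs`, `n_signal`, `n_total`.
#' @export
psd <- function(x, fs, n_total = length(x)) {
  if (length(x) == 0) stop("empty input")
  if (fs <= 0) stop("fs must be positive")
  xp <- zero_pad(x, n_total)
  X <- stats::fft(xp)
  structure(list(values = Mod(X)^2 / (fs * n_total),
                 bin_hz = (seq_len(n_total) - 1) * fs / n_total,
                 fs = fs, n_signal = length(x), n_total = n_total),
            class = "psd_vector")
}

#' Spectral-leakage amplitude of an off-bin cosine
#'
#' For a cosine completing `k` (possibly non-integer) cycles in an `n`-point
#' rectangular window, the magnitude of DFT bin `m` is approximately
#' `n/2 * sin(pi (k - m)) / (pi (k - m))`, with limit `n/2` at `k = m`.
#' The sinc envelope quantifies how much of an off-bin component leaks into
#' neighbouring bins.
#'
#' @param k Cycles completed in the window (may be fractional).
#' @param m Bin index.
#' @param n Window length in samples.
#' @return Predicted amplitude (may be negative; the DFT magnitude is its
#'   absolute value).
#' @examples
#' leakage_amplitude(10, 10, 100)    # 50
#' leakage_amplitude(10.5, 10, 100)  # 100/pi
#' @export
leakage_amplitude <- function(k, m, n) {
  stopifnot(n > 0)
  d <- k - m
  out <- ifelse(abs(d) < 1e-12, n / 2, n / 2 * sin(pi * d) / (pi * d))
  as.numeric(out)
}

#' Bin indices of a harmonic band on the zero-padded grid
#'
#' Returns, for harmonic `h`, the DFT bin number (0-based) of `h * f_k` for
#' every codebook frequency `f_k`, on a grid with spacing
#' `delta_f = fs / n_total`.
#'
#' @param codebook A [make_codebook()] object.
#' @param h Harmonic number (1 = fundamental).
#' @param fs Sampling rate in Hz.
#' @param n_total Transform length defining the bin grid.
#' @param align `"exact"` requires every `h * f_k` to fall exactly on a bin
#'   (the zero-padded design); `"nearest"` rounds to the closest bin (used
#'   for unpadded spectra whose grid cannot align).
#' @return Integer vector of 0-based bin numbers, length `K`.  Index into
#'   `psd()$values` with `bins + 1`.
#' @export
band_bins <- function(codebook, h, fs, n_total,
                      align = c("exact", "nearest")) {
  align <- match.arg(align)
  stopifnot(h >= 1)
  delta_f <- fs / n_total
  ratio <- h * codebook$frequencies / delta_f
  if (align == "exact" && any(abs(ratio - round(ratio)) > 1e-6))
    stop("harmonic frequencies do not align with the bin grid; ",
         "zero-pad to n_total = fs/delta_f_stim or use align = 'nearest'")
  bins <- as.integer(round(ratio))
  if (max(bins) > n_total / 2)
    stop(sprintf("harmonic band (up to %g Hz) exceeds Nyquist (%g Hz)",
                 h * max(codebook$frequencies), fs / 2))
  bins
}

#' Build the bins-by-channels feature matrix of one EEG segment
#'
#' For every channel the segment is zero-padded so that the PSD has one bin
#' per stimulation frequency, then the PSD values at the fundamental band
#' (`h = 1`: bins at `f_1..f_K`) and, if requested, higher harmonic bands
#' (`h`: bins at `h*f_1..h*f_K`) are stacked into an
#' `(n_bands * K) x n_channels` matrix.  The whole matrix is min-max
#' rescaled to `[0, 1]`; a constant matrix maps to all zeros.  With the
#' 40-target codebook and two bands this is the 80 x 9 input of the
#' convolutional classifier.
#'
#' @param segment A [sliding_segments()] element, or a channels-by-samples
#'   matrix (then supply `fs` and optionally `label`).
#' @param codebook A [make_codebook()] object.
#' @param n_bands Number of harmonic bands (>= 1, default 2).
#' @param pad If `TRUE` (default) zero-pad so bins align exactly with the
#'   stimulation grid (one row per target and harmonic); if `FALSE` compute
#'   the unpadded PSD and use every native grid bin inside each harmonic
#'   band `[h f_1, h f_K]` (the picket-fence-afflicted baseline: fewer,
#'   coarser rows whose count depends on the window length).
#' @param delta_f_target Bin spacing in Hz when padding; defaults to the
#'   codebook's minimum frequency gap.
#' @param fs,label Used when `segment` is a plain matrix.
#' @return Object of class `feature_matrix`: list with `values`
#'   (`(n_bands*K) x n_channels` in `[0, 1]`), `band_layout` (data frame of
#'   harmonic and bin frequency per row), `label`, `n_bands`, `padded`.
#' @export
build_feature_matrix <- function(segment, codebook, n_bands = 2L,
                                 pad = TRUE,
                                 delta_f_target = codebook$delta_f_stim,
                                 fs = NULL, label = NA_integer_) {
  if (inherits(segment, "segment")) {
    m <- segment$values; fs <- segment$fs; label <- segment$label
  } else {
    m <- as.matrix(segment)
    if (is.null(fs)) stop("fs is required for matrix input")
  }
  stopifnot(n_bands >= 1)
  n <- ncol(m)
  if (pad) {
    unit <- padded_length(fs, delta_f_target)
    n_total <- unit * max(1L, ceiling(n / unit))  # never truncate
    bins <- lapply(seq_len(n_bands), function(h)
      band_bins(codebook, h, fs, n_total))
  } else {
    # native (unpadded) grid: every bin inside each harmonic band
    n_total <- n
    df <- fs / n_total
    bins <- lapply(seq_len(n_bands), function(h) {
      lo <- h * min(codebook$frequencies)
      hi <- h * max(codebook$frequencies)
      b <- seq.int(ceiling(lo / df - 1e-9), floor(hi / df + 1e-9))
      b <- b[b >= 0 & b <= n_total / 2]
      if (!length(b))                         # band narrower than one bin
        b <- unique(pmin(round(h * codebook$frequencies / df),
                         floor(n_total / 2)))
      as.integer(b)
    })
  }
  vals <- matrix(0, sum(lengths(bins)), nrow(m))
  for (ch in seq_len(nrow(m))) {
    p <- psd(m[ch, ], fs, n_total)
    vals[, ch] <- unlist(lapply(bins, function(b) p$values[b + 1L]))
  }
  layout <- data.frame(
    harmonic = rep(seq_len(n_bands), lengths(bins)),
    freq_hz = unlist(bins) * fs / n_total)
  structure(list(values = rescale_zero_one(vals), band_layout = layout,
                 label = label, n_bands = n_bands, padded = pad,
                 n_total = n_total),
            class = "feature_matrix")
}

# Min-max rescale a matrix to [0, 1]; constant matrices map to all zeros.
rescale_zero_one <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(m * 0)
  (m - rng[1]) / (rng[2] - rng[1])
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d bins x %d channels (%d band%s, %s), label %s\n",
              nrow(x$values), ncol(x$values), x$n_bands,
              if (x$n_bands > 1) "s" else "",
              if (x$padded) "zero-padded" else "unpadded",
              as.character(x$label)))
  invisible(x)
}

#' Featurize an epoch array into a classifier-ready dataset
#'
#' Applies [sliding_segments()] and one of three per-segment
#' representations: zero-padded PSD features (`"zpfd"`), unpadded PSD
#' features (`"fd"`), or the min-max rescaled raw time-domain segment
#' (`"raw"`, samples x channels).  `"separable"` uses the same features as
#' `"zpfd"` (the variants differ in the classifier, not the input).
#'
#' @param epochs An [epoch_array][simulate_epochs].
#' @param window_s,latency_s,step_s Passed to [sliding_segments()].
#' @param variant One of `"zpfd"`, `"fd"`, `"raw"`, `"separable"`.
#' @param n_bands Number of harmonic bands for the spectral variants.
#' @param blocks,stimuli Optional subsets, passed through.
#' @return List with `x` (n x (rows*cols) matrix, each row a row-major
#'   flattened input), `y` (integer labels), `rows`, `cols`, `trial`
#'   (integer id grouping windows cut from the same epoch), `variant`, and
#'   `band_layout` (harmonic and bin frequency per feature row; `NULL` for
#'   the raw variant).
#' @export
featurize_epochs <- function(epochs, window_s, latency_s = 0.13,
                             step_s = 0.1,
                             variant = c("zpfd", "fd", "raw", "separable"),
                             n_bands = 2L, blocks = NULL, stimuli = NULL) {
  variant <- match.arg(variant)
  segs <- sliding_segments(epochs, window_s, latency_s, step_s,
                           blocks = blocks, stimuli = stimuli)
  n <- length(segs)
  layout <- NULL
  mk <- function(seg) {
    if (variant == "raw") return(rescale_zero_one(t(seg$values)))
    fm <- build_feature_matrix(seg, epochs$codebook, n_bands = n_bands,
                               pad = variant != "fd")
    if (is.null(layout)) layout <<- fm$band_layout
    fm$values
  }
  first <- mk(segs[[1]])
  x <- matrix(0, n, length(first))
  x[1, ] <- as.vector(t(first))
  y <- integer(n); y[1] <- segs[[1]]$label
  trial <- integer(n)
  trial_id <- function(seg) seg$block * 10000L + seg$label
  trial[1] <- trial_id(segs[[1]])
  if (n > 1) for (i in 2:n) {
    x[i, ] <- as.vector(t(mk(segs[[i]])))
    y[i] <- segs[[i]]$label
    trial[i] <- trial_id(segs[[i]])
  }
  list(x = x, y = y, rows = nrow(first), cols = ncol(first),
       trial = trial, variant = variant, band_layout = layout)
}
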