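#' Stimulus codebook: the frequencies and phases that define the classes
#'
#' A codebook lists the `K` stimulation frequencies (and their encoding
#' phases) presented by the speller interface.  Every downstream stage is
#' tied to it: the synthetic generator produces one oscillatory response per
#' entry, and the spectral module places one feature bin per entry and
#' harmonic.  Two presets are built in:
#'
#' * `"beta"`: 40 targets, 8.0--15.8 Hz in 0.2 Hz steps, phases starting at
#'   0 and advancing by 0.5\eqn{\pi} per target (joint frequency/phase
#'   coding used by 40-character matrix spellers).
#' * `"ssmvep"`: 35 targets, 3.0--20.0 Hz in 0.5 Hz steps, all phases
#'   0.5\eqn{\pi} (radial-motion checkerboard paradigm).
#'
#' @param preset `"beta"`, `"ssmvep"`, or `"custom"`.
#' @param f_min,f_max,step Frequency grid in Hz for `preset = "custom"`;
#'   `step` must be positive and `f_min < f_max`.
#' @param phase0 First phase in radians (custom preset).
#' @param phase_step Phase increment in radians between consecutive targets
#'   (custom preset); phases are reduced modulo \eqn{2\pi}.
#' @param name Label stored with a custom codebook.
#'
#' @return An object of class `stim_codebook`: a list with `frequencies`
#'   (strictly increasing, Hz), `phases` (radians in `[0, 2pi)`),
#'   `delta_f_stim` (the minimum gap between stimulation frequencies, equal
#'   to the grid step), and `name`.
#' @examples
#' cb <- make_codebook("beta")
#' length(cb$frequencies)  # 40
#' cb$delta_f_stim         # 0.2
#' @export
make_codebook <- function(preset = c("beta", "ssmvep", "custom"),
                          f_min = NULL, f_max = NULL, step = NULL,
                          phase0 = 0, phase_step = 0, name = "custom") {
  preset <- match.arg(preset)
  if (preset == "beta") {
    return(new_codebook(seq(8, 15.8, by = 0.2),
                        (0.5 * pi * (0:39)) %% (2 * pi), "beta"))
  }
  if (preset == "ssmvep") {
    return(new_codebook(seq(3, 20, by = 0.5),
                        rep(0.5 * pi, 35L), "ssmvep"))
  }
  if (is.null(f_min) || is.null(f_max) || is.null(step))
    stop("custom codebook requires f_min, f_max and step")
  if (step <= 0) stop("step must be positive")
  if (f_max <= f_min) stop("f_max must exceed f_min")
  k <- round((f_max - f_min) / step) + 1L
  freqs <- f_min + step * (seq_len(k) - 1L)
  phases <- (phase0 + phase_step * (seq_len(k) - 1L)) %% (2 * pi)
  new_codebook(freqs, phases, name)
}

new_codebook <- function(frequencies, phases, name) {
  stopifnot(length(frequencies) == length(phases),
            all(diff(frequencies) > 0))
  structure(list(frequencies = frequencies,
                 phases = phases,
                 delta_f_stim = if (length(frequencies) > 1L)
                   min(diff(frequencies)) else frequencies,
                 name = name),
            class = "stim_codebook")
}

#' Restrict a codebook to a subset of its targets
#'
#' Handy for fixture-scale experiments on the first few targets of a
#' preset grid.
#'
#' @param codebook A [make_codebook()] object.
#' @param idx Integer indices of the targets to keep (in increasing order).
#' @return A `stim_codebook` with the selected targets.
#' @export
subset_codebook <- function(codebook, idx) {
  stopifnot(all(idx >= 1), all(idx <= n_targets(codebook)),
            !is.unsorted(idx))
  new_codebook(codebook$frequencies[idx], codebook$phases[idx],
               paste0(codebook$name, "[", length(idx), "]"))
}

#' Number of targets in a codebook
#' @param codebook A [make_codebook()] object.
#' @return Integer count of stimulation targets.
#' @export
n_targets <- function(codebook) length(codebook$frequencies)

#' @export
print.stim_codebook <- function(x, ...) {
  cat(sprintf("<stim_codebook '%s'> %d targets, %.1f-%.1f Hz, delta f = %g Hz\n",
              x$name, n_targets(x), min(x$frequencies), max(x$frequencies),
              x$delta_f_stim))
  invisible(x)
}
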