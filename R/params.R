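#' Detection parameters
#'
#' Bundle of all tunables for oscillation event detection.  Defaults follow
#' common practice for broadband analysis of field potentials: 7-cycle Morlet
#' wavelets on nonoverlapping 10-s windows, a linear frequency grid from 0.25
#' to 250 Hz in 0.25-Hz steps, a moderate power threshold of 4x the
#' per-frequency median, and merging of events whose bounding boxes overlap
#' by more than half of the smaller box.
#'
#' @param freq_min,freq_max,freq_step Frequency grid (Hz).  `freq_max` must
#'   stay below the Nyquist frequency of the analyzed signal.
#' @param wavelet_width Morlet width in cycles (the Gaussian envelope has
#'   temporal s.d. `wavelet_width / (2 * pi * f)`).  Must be >= 3.
#' @param window_len Length of the nonoverlapping analysis windows, seconds.
#' @param threshold Detection threshold as a multiple of per-frequency median
#'   power; must be > 1.
#' @param merge_overlap Fraction of the smaller bounding-box area that the
#'   intersection must exceed (strictly) for two events to be merged.
#' @return An object of class `oe_params` (a validated list).
#' @examples
#' p <- detection_params(freq_max = 100)
#' p$threshold
#' @export
detection_params <- function(freq_min = 0.25, freq_max = 250,
                             freq_step = 0.25, wavelet_width = 7,
                             window_len = 10, threshold = 4,
                             merge_overlap = 0.5) {
  stopifnot(freq_min > 0, freq_min <= freq_max, freq_step > 0,
            wavelet_width >= 3, window_len > 0,
            threshold > 1, merge_overlap > 0, merge_overlap < 1)
  structure(list(freq_min = freq_min, freq_max = freq_max,
                 freq_step = freq_step, wavelet_width = wavelet_width,
                 window_len = window_len, threshold = threshold,
                 merge_overlap = merge_overlap),
            class = "oe_params")
}

#' Physiological frequency-band scheme
#'
#' Standard auditory-cortex band intervals used to classify events by peak
#' frequency: delta (0.5,4], theta (4,9], alpha (9,15], beta (15,30],
#' low gamma (30,40], gamma (40,80], high gamma (80,200] Hz.  Intervals are
#' open on the lower bound and closed on the upper bound; the printed gaps
#' between beta/low gamma and gamma/high gamma are closed so that the scheme
#' is contiguous.  The `"combined"` scheme merges low gamma and gamma into a
#' single (30,80] gamma band, which gives a wide enough band for
#' cross-frequency analyses.
#'
#' @param scheme `"default"` (7 bands) or `"combined"` (merged gamma).
#' @return data.frame with columns `band`, `low`, `high` (Hz).
#' @export
band_scheme <- function(scheme = c("default", "combined")) {
  scheme <- match.arg(scheme)
  if (scheme == "default") {
    data.frame(band = c("delta", "theta", "alpha", "beta",
                        "lgamma", "gamma", "hgamma"),
               low  = c(0.5, 4, 9, 15, 30, 40, 80),
               high = c(4, 9, 15, 30, 40, 80, 200),
               stringsAsFactors = FALSE)
  } else {
    data.frame(band = c("delta", "theta", "alpha", "beta",
                        "gamma", "hgamma"),
               low  = c(0.5, 4, 9, 15, 30, 80),
               high = c(4, 9, 15, 30, 80, 200),
               stringsAsFactors = FALSE)
  }
}

#' Per-band analysis windows for interevent-interval statistics
#'
#' Window lengths (seconds) used when computing per-window CV2 and Fano
#' factor, sized so that each window holds a similar number of events
#' (roughly 12-18) in every band: longer windows for the slow bands, short
#' ones for the fast bands.
#'
#' @return Named numeric vector, seconds, one entry per band of
#'   [band_scheme()].
#' @export
band_windows <- function() {
  c(delta = 44.0, theta = 30.0, alpha = 24.0, beta = 10.7,
    lgamma = 12.0, gamma = 3.6, hgamma = 1.3)
}

#' @export
print.oe_params <- function(x, ...) {
  cat("Oscillation event detection parameters\n")
  cat(sprintf("  frequency grid : %g-%g Hz, step %g Hz\n",
              x$freq_min, x$freq_max, x$freq_step))
  cat(sprintf("  wavelet width  : %g cycles\n", x$wavelet_width))
  cat(sprintf("  window length  : %g s\n", x$window_len))
  cat(sprintf("  threshold      : %gx median power\n", x$threshold))
  cat(sprintf("  merge overlap  : %g\n", x$merge_overlap))
  invisible(x)
}

# internal: frequency grid from params
param_freqs <- function(params) {
  seq(params$freq_min, params$freq_max, by = params$freq_step)
}

# internal: run code with a temporary RNG seed, restoring global state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(if (had) assign(".Random.seed", old, envir = .GlobalEnv)
          else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}
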