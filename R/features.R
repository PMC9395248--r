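#' Classify a peak frequency into a physiological band
#'
#' Bands are half-open intervals, open on the lower bound and closed on the
#' upper bound, so e.g. 4 Hz is delta and 4.25 Hz is theta.  Frequencies
#' outside every band are `"unclassified"`.
#'
#' @param peakF Numeric vector of peak frequencies, Hz (> 0).
#' @param scheme Band scheme data.frame, see [band_scheme()].
#' @return Character vector of band labels.
#' @examples
#' classify_band(c(10, 4, 300))
#' @export
classify_band <- function(peakF, scheme = band_scheme()) {
  stopifnot(all(peakF > 0))
  out <- rep("unclassified", length(peakF))
  for (b in seq_len(nrow(scheme))) {
    hit <- peakF > scheme$low[b] & peakF <= scheme$high[b]
    out[hit] <- scheme$band[b]
  }
  out
}

#' Logarithmic frequency span
#'
#' `Fspan = ln(maxF / minF)`; an Fspan of `x` corresponds to `x / ln(2)`
#' octaves, so the broadband-exclusion threshold of 1.5 equals 2.17 octaves.
#'
#' @param minF,maxF Event frequency bounds, Hz, `0 < minF <= maxF`.
#' @return Natural-log frequency span (>= 0).
#' @export
fspan <- function(minF, maxF) {
  stopifnot(all(minF > 0), all(maxF >= minF))
  log(maxF / minF)
}

#' Zero-phase bandpass filter for an event
#'
#' Butterworth bandpass (two second-order sections, overall order 4)
#' applied forward and backward so the net phase shift is zero.  The
#' pass-band is `[max(minF, 0.1), maxF]` Hz; when `minF == maxF` the band is
#' widened by one frequency-grid step on each side.
#'
#' @param x Signal segment (typically the event's full analysis window).
#' @param minF,maxF Event frequency bounds, Hz; must lie below Nyquist.
#' @param fs Sampling rate, Hz.
#' @param freq_step Grid step used to widen degenerate bands, Hz.
#' @return The filtered signal, same length as `x`.
#' @export
bandpass_event <- function(x, minF, maxF, fs, freq_step = 0.25) {
  lo <- max(minF, 0.1)
  hi <- maxF
  if (minF == maxF) {
    lo <- max(0.1, minF - freq_step)
    hi <- maxF + freq_step
  }
  if (lo >= fs / 2) stop("pass band entirely above Nyquist")
  hi <- min(hi, 0.99 * fs / 2)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Filter-match between raw and filtered event waveforms
#'
#' Pearson correlation between an event's raw signal and its band-pass
#' filtered signal over the event span, used as an index of how clearly the
#' oscillation is visible in the raw trace.  Qualitative labels: weak
#' \[0, 0.25\] (negative r is also weak), moderate (0.25, 0.5\], strong/high
#' > 0.5.
#'
#' @param raw_segment,filtered_segment Equal-length numeric vectors
#'   (>= 3 samples), neither constant.
#' @return list with `r` and `label`.
#' @export
filter_match <- function(raw_segment, filtered_segment) {
  stopifnot(length(raw_segment) == length(filtered_segment),
            length(raw_segment) >= 3)
  if (stats::sd(raw_segment) == 0 || stats::sd(filtered_segment) == 0)
    stop("filter-match undefined for constant segments")
  r <- stats::cor(raw_segment, filtered_segment)
  label <- if (r > 0.5) "strong/high" else if (r > 0.25) "moderate" else "weak"
  list(r = r, label = label)
}

#' Count strict local extrema of a filtered waveform
#'
#' @param x Numeric vector, length >= 3.
#' @return Named vector `c(n_peaks, n_troughs)` of strict interior local
#'   maxima and minima.
#' @export
count_extrema <- function(x) {
  stopifnot(length(x) >= 3)
  i <- 2:(length(x) - 1)
  c(n_peaks = sum(x[i] > x[i - 1] & x[i] > x[i + 1]),
    n_troughs = sum(x[i] < x[i - 1] & x[i] < x[i + 1]))
}

#' ERP template
#'
#' Average evoked-response waveform used to score (and exclude) events that
#' look like stimulus-driven transients rather than intrinsic oscillations.
#'
#' @param waveform Numeric vector (finite, non-constant), signal units.
#' @param fs Sampling rate of the template, Hz.
#' @param label Optional label (e.g. the cortical layer / channel) used to
#'   match templates to channels.
#' @return Object of class `oe_erp_template`.
#' @export
erp_template <- function(waveform, fs, label = NULL) {
  stopifnot(is.numeric(waveform), all(is.finite(waveform)), fs > 0)
  if (stats::sd(waveform) == 0) stop("ERP template must not be constant")
  structure(list(waveform = as.numeric(waveform), fs = fs, label = label),
            class = "oe_erp_template")
}

#' Read an ERP template from CSV
#'
#' Expects two columns, time (s) and value; the sampling rate is inferred
#' from the time column.
#'
#' @param path CSV path.
#' @param label Optional template label.
#' @return An [erp_template()].
#' @export
read_erp_template <- function(path, label = NULL) {
  d <- utils::read.csv(path)
  dt <- stats::median(diff(d[[1]]))
  erp_template(d[[2]], fs = 1 / dt, label = label)
}

#' ERP score of an event waveform
#'
#' Maximum over all full-overlap lags of the zero-mean, unit-norm sliding
#' correlation between the template and the event waveform (the shorter
#' slid across the longer).  The signed maximum is returned: 1 for a scaled
#' copy of the template, near 0 for unrelated waveforms.
#'
#' @param event_raw Raw event waveform (numeric vector).
#' @param template An [erp_template()] (resampled to `fs` if needed).
#' @param fs Sampling rate of `event_raw`, Hz.
#' @return Score in \[-1, 1\].
#' @export
erp_score <- function(event_raw, template, fs) {
  stopifnot(inherits(template, "oe_erp_template"))
  tw <- template$waveform
  if (abs(template$fs - fs) > 1e-9) {
    t_old <- (seq_along(tw) - 1) / template$fs
    n_new <- max(3, floor(t_old[length(t_old)] * fs) + 1)
    tw <- stats::approx(t_old, tw, xout = (seq_len(n_new) - 1) / fs)$y
  }
  a <- event_raw
  if (stats::sd(a) == 0 || stats::sd(tw) == 0)
    stop("ERP score undefined for constant inputs")
  short <- if (length(a) <= length(tw)) a else tw
  long <- if (length(a) <= length(tw)) tw else a
  ns <- length(short)
  s <- short - mean(short)
  s <- s / sqrt(sum(s^2))
  best <- -Inf
  for (lag in 0:(length(long) - ns)) {
    seg <- long[(lag + 1):(lag + ns)]
    seg <- seg - mean(seg)
    nrm <- sqrt(sum(seg^2))
    if (nrm == 0) next
    best <- max(best, sum(s * seg) / nrm)
  }
  best
}

#' Flag ERP-like and broadband events
#'
#' Sets `flag_erp` when an event's ERP score exceeds 0.8 and its duration
#' lies within 75-300 ms, and `flag_broadband` when its frequency span
#' exceeds `Fspan = 1.5` (2.17 octaves).  Flagged events are excluded from
#' downstream statistics but retained in the table.  When no ERP scores are
#' available (no templates), the ERP rule is skipped.  The two flags are
#' independent, so applying them in either order gives the same table.
#'
#' @param events Event table with `duration`, `Fspan` and (optionally)
#'   `erp_score` columns.
#' @param erp_cut ERP score threshold (default 0.8).
#' @param erp_duration Duration window for the ERP rule, seconds.
#' @param fspan_cut Broadband threshold on the natural-log frequency span.
#' @return The event table with `flag_erp` and `flag_broadband` set.
#' @export
apply_exclusions <- function(events, erp_cut = 0.8,
                             erp_duration = c(0.075, 0.300),
                             fspan_cut = 1.5) {
  ev <- events
  score <- if ("erp_score" %in% names(ev)) ev$erp_score
           else rep(NA_real_, nrow(ev))
  ev$flag_erp <- !is.na(score) & score > erp_cut &
    ev$duration >= erp_duration[1] & ev$duration <= erp_duration[2]
  ev$flag_broadband <- ev$Fspan > fspan_cut
  ev
}

# internal: events not flagged for exclusion
unflagged <- function(events) {
  keep <- !(events$flag_erp %in% TRUE) & !(events$flag_broadband %in% TRUE)
  events[keep, , drop = FALSE]
}

#' Zero-phase alignment time of an event
#'
#' Time of the filtered-waveform local maximum (wavelet phase 0, a crest)
#' closest to the event's power peak; used as the 0-ms reference when
#' plotting event waveforms.
#'
#' @param filtered Filtered waveform of the event span.
#' @param fs Sampling rate, Hz.
#' @param t_peak Time of event peak power, seconds (same clock as `t0`).
#' @param t0 Time of `filtered[1]`, seconds.
#' @return Crest time, seconds.
#' @export
align_zero_phase <- function(filtered, fs, t_peak, t0 = 0) {
  stopifnot(length(filtered) >= 3)
  i <- 2:(length(filtered) - 1)
  crest <- which(filtered[i] > filtered[i - 1] & filtered[i] > filtered[i + 1]) + 1
  if (!length(crest)) stop("no local maximum in event span")
  tc <- t0 + (crest - 1) / fs
  tc[which.min(abs(tc - t_peak))]
}
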