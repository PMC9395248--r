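#' Instantaneous phase and amplitude for phase-amplitude coupling
#'
#' Filters the whole recording by convolution with complex Morlet wavelets
#' of width 3: the instantaneous phase is taken at the geometric center
#' frequency of the phase band (a single wavelet), and the amplitude is the
#' mean magnitude over a grid of wavelets spanning the amplitude band
#' (default 5-Hz spacing).  Width-3 wavelets trade frequency resolution for
#' the temporal resolution needed to follow fast amplitude fluctuations.
#'
#' @param rec An [recording()].
#' @param channel Channel index or label.
#' @param f_phase Phase band, Hz, e.g. `c(0.5, 4)` (delta) or `c(4, 8)`
#'   (theta).
#' @param f_amp Amplitude band, Hz, default `c(30, 200)` (gamma).
#' @param width Wavelet width in cycles (default 3).
#' @param amp_step Spacing of the amplitude-band wavelet grid, Hz.
#' @return list with `phase` (radians), `amp`, `times` (s) and `fs`.
#' @export
phase_amp_series <- function(rec, channel = 1, f_phase = c(0.5, 4),
                             f_amp = c(30, 200), width = 3, amp_step = 5) {
  stopifnot(inherits(rec, "oe_recording"))
  if (is.character(channel)) channel <- match(channel, rec$channel_labels)
  if (max(f_amp) >= rec$fs / 2)
    stop("amplitude band extends to or above Nyquist")
  x <- rec$samples[channel, ]
  x <- x - mean(x)
  fc <- sqrt(f_phase[1] * f_phase[2])
  z <- morlet_coef(x, rec$fs, fc, width)
  grid <- seq(f_amp[1], f_amp[2], by = amp_step)
  amp <- rowMeans(vapply(grid, function(f)
    Mod(morlet_coef(x, rec$fs, f, width)), numeric(length(x))))
  list(phase = Arg(z), amp = amp,
       times = rec$t0 + (seq_along(x) - 1) / rec$fs, fs = rec$fs)
}

#' Modulation index
#'
#' Modulus of the complex mean of the amplitude-weighted unit phasors,
#' `|mean(amp * exp(i * phase))|`.  Zero when amplitude is unrelated to
#' phase; for `amp = 1 + cos(phase)` over whole cycles it equals 0.5.
#' Scaling the amplitude by c scales the index by c.
#'
#' @param phase Phase series, radians.
#' @param amp Amplitude series, same length.
#' @return Modulation index (>= 0).
#' @export
modulation_index <- function(phase, amp) {
  stopifnot(length(phase) == length(amp), length(phase) > 0)
  Mod(mean(amp * exp(1i * phase)))
}

#' Compare phase-amplitude coupling during and outside low-frequency events
#'
#' Computes the modulation index separately for every segment spanned by a
#' low-frequency event and for an equal number of equally long event-free
#' segments (placed uniformly at random, without overlap, in the time not
#' covered by any detected event), then compares the two sets of
#' modulation indices with an unpaired two-sample t test.
#'
#' @param rec An [recording()].
#' @param events Event table from [detect()] for the same channel.
#' @param band_low `"delta"` or `"theta"`: which low-frequency events
#'   define the segments (phase band 0.5-4 or 4-8 Hz).
#' @param channel Channel index or label.
#' @param f_amp Amplitude band, Hz.
#' @param seed Seed for drawing the event-free segments.
#' @param max_tries Rejection-sampling attempts per control segment.
#' @return list with `segments` (data.frame: condition, t_start, t_stop,
#'   mi), `mi_event`, `mi_no_event` (means), `p_value`, `f_phase`, `f_amp`.
#' @export
event_pac_compare <- function(rec, events, band_low = c("delta", "theta"),
                              channel = 1, f_amp = c(30, 200), seed = NULL,
                              max_tries = 1000) {
  band_low <- match.arg(band_low)
  f_phase <- if (band_low == "delta") c(0.5, 4) else c(4, 8)
  ev <- unflagged(events)
  low <- ev[ev$band == band_low, , drop = FALSE]
  if (nrow(low) == 0) stop("no unflagged ", band_low, " events")
  pa <- phase_amp_series(rec, channel, f_phase, f_amp)
  dur <- rec_duration(rec)
  # time not covered by any detected event, as a set of gaps
  gaps <- event_free_gaps(ev, dur, rec$t0)
  ctrl <- with_seed(seed,
    sample_free_segments(low$t_stop - low$t_start, gaps, max_tries))
  seg_mi <- function(t1, t2) {
    i <- which(pa$times >= t1 & pa$times <= t2)
    modulation_index(pa$phase[i], pa$amp[i])
  }
  mi_ev <- mapply(seg_mi, low$t_start, low$t_stop)
  mi_no <- mapply(seg_mi, ctrl$t_start, ctrl$t_stop)
  segs <- rbind(
    data.frame(condition = "event", t_start = low$t_start,
               t_stop = low$t_stop, mi = mi_ev),
    data.frame(condition = "no_event", t_start = ctrl$t_start,
               t_stop = ctrl$t_stop, mi = mi_no))
  p <- if (length(mi_ev) >= 2 && length(mi_no) >= 2)
    stats::t.test(mi_ev, mi_no)$p.value else NA_real_
  list(segments = segs, mi_event = mean(mi_ev), mi_no_event = mean(mi_no),
       p_value = p, f_phase = f_phase, f_amp = f_amp)
}

# internal: complement of event spans within [t0, t0 + duration]
event_free_gaps <- function(events, duration, t0 = 0) {
  if (nrow(events) == 0)
    return(data.frame(lo = t0, hi = t0 + duration))
  o <- order(events$t_start)
  lo <- events$t_start[o]; hi <- events$t_stop[o]
  gaps <- list()
  cursor <- t0
  for (k in seq_along(lo)) {
    if (lo[k] > cursor) gaps[[length(gaps) + 1]] <- c(cursor, lo[k])
    cursor <- max(cursor, hi[k])
  }
  if (cursor < t0 + duration)
    gaps[[length(gaps) + 1]] <- c(cursor, t0 + duration)
  if (!length(gaps)) return(data.frame(lo = numeric(0), hi = numeric(0)))
  g <- do.call(rbind, gaps)
  data.frame(lo = g[, 1], hi = g[, 2])
}

# internal: place segments of given durations in the gaps, uniformly at
# random and without mutual overlap (rejection sampling)
sample_free_segments <- function(durations, gaps, max_tries = 1000) {
  placed <- data.frame(t_start = numeric(0), t_stop = numeric(0))
  for (d in durations) {
    ok_gaps <- which(gaps$hi - gaps$lo >= d)
    if (!length(ok_gaps))
      stop("insufficient event-free time to match segment of ", d, " s")
    done <- FALSE
    for (try in seq_len(max_tries)) {
      g <- ok_gaps[sample.int(length(ok_gaps), 1)]
      t1 <- stats::runif(1, gaps$lo[g], gaps$hi[g] - d)
      t2 <- t1 + d
      if (!nrow(placed) ||
          all(t2 <= placed$t_start | t1 >= placed$t_stop)) {
        placed <- rbind(placed, data.frame(t_start = t1, t_stop = t2))
        done <- TRUE
        break
      }
    }
    if (!done)
      stop("could not place nonoverlapping event-free segments; ",
           "insufficient event-free time")
  }
  placed
}
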