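#' Event rate per band
#'
#' Number of unflagged events of a band divided by the analyzed duration.
#'
#' @param events Event table (see [detect()]).
#' @param band Band label, or `NULL` for all bands pooled.
#' @param total_duration Analyzed duration, seconds (> 0); defaults to the
#'   event table's `total_duration` attribute.
#' @return Rate, events/s.
#' @export
event_rate <- function(events, band = NULL,
                       total_duration = attr(events, "total_duration")) {
  stopifnot(total_duration > 0)
  ev <- unflagged(events)
  if (!is.null(band)) ev <- ev[ev$band == band, , drop = FALSE]
  nrow(ev) / total_duration
}

#' Active-time ratio
#'
#' Fraction of the recording covered by the union of the `[t_start,
#' t_stop]` spans of a band's unflagged events (or of all bands together
#' when `band = NULL`).  Because events of different bands overlap and
#' nest, per-band ATRs can sum to more than 1.
#'
#' @inheritParams event_rate
#' @return Fraction in \[0, 1\].
#' @export
active_time_ratio <- function(events, band = NULL,
                              total_duration = attr(events, "total_duration")) {
  stopifnot(total_duration > 0)
  ev <- unflagged(events)
  if (!is.null(band)) ev <- ev[ev$band == band, , drop = FALSE]
  if (nrow(ev) == 0) return(0)
  o <- order(ev$t_start)
  covered <- 0
  cur_lo <- ev$t_start[o[1]]; cur_hi <- ev$t_stop[o[1]]
  for (k in o[-1]) {
    if (ev$t_start[k] <= cur_hi) {
      cur_hi <- max(cur_hi, ev$t_stop[k])
    } else {
      covered <- covered + (cur_hi - cur_lo)
      cur_lo <- ev$t_start[k]; cur_hi <- ev$t_stop[k]
    }
  }
  covered <- covered + (cur_hi - cur_lo)
  covered / total_duration
}

#' Interevent intervals within a band
#'
#' Successive intervals between a band's unflagged events, either from peak
#' power time to peak power time (`mode = "peak"`) or from the end of one
#' event to the start of the next (`mode = "edge"`).  Edge-mode intervals
#' of overlapping events are negative; they are reported as 0.
#'
#' @inheritParams event_rate
#' @param mode `"peak"` or `"edge"`.
#' @return Numeric vector of intervals, seconds.
#' @export
interevent_intervals <- function(events, band = NULL,
                                 mode = c("peak", "edge")) {
  mode <- match.arg(mode)
  ev <- unflagged(events)
  if (!is.null(band)) ev <- ev[ev$band == band, , drop = FALSE]
  if (nrow(ev) < 2) stop("need at least 2 events to form intervals")
  if (mode == "peak") {
    diff(sort(ev$t_peak))
  } else {
    ev <- ev[order(ev$t_start), , drop = FALSE]
    pmax(ev$t_start[-1] - ev$t_stop[-nrow(ev)], 0)
  }
}

#' Squared coefficient of variation of intervals
#'
#' `CV2 = var / mean^2` with the population (divide-by-n) variance.  A
#' Poisson (exponential-interval) process has CV2 = 1; rhythmic processes
#' have CV2 < 1, bursty ones CV2 > 1.  CV2 is invariant to rescaling the
#' intervals.
#'
#' @param intervals Numeric vector (>= 2 values, positive mean).
#' @return CV2 (>= 0).
#' @examples
#' cv2(c(1, 2, 3))  # (2/3) / 4 = 1/6
#' @export
cv2 <- function(intervals) {
  stopifnot(length(intervals) >= 2)
  m <- mean(intervals)
  if (m <= 0) stop("CV2 undefined for nonpositive mean interval")
  v <- mean((intervals - m)^2)
  v / m^2
}

#' Fano factor of event counts in fixed windows
#'
#' Counts events in consecutive nonoverlapping windows starting at t = 0
#' (a trailing partial window is dropped) and returns the population
#' variance-to-mean ratio of the counts.  1 for a homogeneous Poisson
#' process, < 1 for rhythmic event trains.
#'
#' @param event_times Event times, seconds.
#' @param window_len Window length, seconds.
#' @param total_duration Total duration, seconds (>= 2 windows).
#' @return Fano factor (>= 0).
#' @export
fano_factor <- function(event_times, window_len, total_duration) {
  stopifnot(total_duration >= 2 * window_len)
  n_win <- floor(total_duration / window_len)
  counts <- tabulate(
    findInterval(event_times[event_times >= 0 &
                               event_times < n_win * window_len],
                 seq(0, n_win * window_len, by = window_len),
                 left.open = FALSE),
    nbins = n_win)
  m <- mean(counts)
  if (m == 0) stop("Fano factor undefined: no events in any window")
  mean((counts - m)^2) / m
}

#' One-sided rhythmicity test against the Poisson reference
#'
#' Wilcoxon signed-rank test that the median of per-window CV2 (or FF)
#' values is below 1, the value of a Poisson process.
#'
#' @param values Numeric vector of CV2 or FF values (>= 5).
#' @return One-sided p-value.
#' @export
rhythmicity_test <- function(values) {
  stopifnot(length(values) >= 5)
  if (all(values == 1)) stop("all values equal the Poisson reference")
  suppressWarnings(
    stats::wilcox.test(values, mu = 1, alternative = "less")$p.value)
}

#' Per-band interevent rhythmicity
#'
#' Splits the recording into consecutive nonoverlapping analysis windows
#' (per-band lengths from [band_windows()]), computes CV2 of the interevent
#' intervals inside every window with at least three events, the Fano
#' factor of the per-window counts, and the one-sided signed-rank p-value
#' for mean CV2 below the Poisson value of 1.
#'
#' @inheritParams event_rate
#' @param band Band label.
#' @param window_len Analysis window, seconds (default from
#'   [band_windows()]).
#' @param mode Interval mode, see [interevent_intervals()].
#' @return list with `band`, `window_len`, `cv2_values`, `cv2_mean`,
#'   `cv2_sem`, `fano`, `p_cv2`.
#' @export
band_rhythmicity <- function(events, band,
                             total_duration = attr(events, "total_duration"),
                             window_len = band_windows()[[band]],
                             mode = c("peak", "edge")) {
  mode <- match.arg(mode)
  ev <- unflagged(events)
  ev <- ev[ev$band == band, , drop = FALSE]
  n_win <- floor(total_duration / window_len)
  vals <- numeric(0)
  for (w in seq_len(n_win)) {
    lo <- (w - 1) * window_len; hi <- w * window_len
    sel <- ev[ev$t_peak >= lo & ev$t_peak < hi, , drop = FALSE]
    if (nrow(sel) >= 3)
      vals <- c(vals, cv2(interevent_intervals(sel, mode = mode)))
  }
  ff <- if (nrow(ev)) fano_factor(ev$t_peak, window_len, total_duration)
        else NA_real_
  p <- if (length(vals) >= 5) rhythmicity_test(vals) else NA_real_
  list(band = band, window_len = window_len, cv2_values = vals,
       cv2_mean = if (length(vals)) mean(vals) else NA_real_,
       cv2_sem = if (length(vals) > 1)
         stats::sd(vals) / sqrt(length(vals)) else NA_real_,
       fano = ff, p_cv2 = p)
}

#' Probability of co-occurrence between bands
#'
#' For every pair of distinct bands a, b: the number of a-events that
#' overlap in time with at least one b-event, plus the number of b-events
#' overlapping at least one a-event, divided by the total number of events
#' in the two bands.  Overlap means a nonempty intersection of the
#' `[t_start, t_stop]` spans; each event is counted once no matter how many
#' partners it overlaps.  Uses the combined-gamma scheme by default, since
#' the narrow low-gamma band yields too few band-limited events for stable
#' pairwise counts.
#'
#' @param events Event table (flagged events are dropped).
#' @param scheme Band scheme; events are reclassified by `peakF` under it.
#' @return Symmetric band x band matrix of probabilities (diagonal `NA`).
#' @export
cooccurrence <- function(events, scheme = band_scheme("combined")) {
  ev <- unflagged(events)
  ev$band <- classify_band(ev$peakF, scheme)
  bands <- scheme$band
  out <- matrix(NA_real_, length(bands), length(bands),
                dimnames = list(bands, bands))
  for (a in seq_along(bands)) for (b in seq_along(bands)) {
    if (a >= b) next
    ea <- ev[ev$band == bands[a], , drop = FALSE]
    eb <- ev[ev$band == bands[b], , drop = FALSE]
    if (nrow(ea) + nrow(eb) == 0) next
    hit_a <- vapply(seq_len(nrow(ea)), function(i)
      any(ea$t_start[i] <= eb$t_stop & ea$t_stop[i] >= eb$t_start), TRUE)
    hit_b <- vapply(seq_len(nrow(eb)), function(i)
      any(eb$t_start[i] <= ea$t_stop & eb$t_stop[i] >= ea$t_start), TRUE)
    out[a, b] <- out[b, a] <-
      (sum(hit_a) + sum(hit_b)) / (nrow(ea) + nrow(eb))
  }
  out
}

#' Band-limited and band-spreading event fractions
#'
#' For each band: the fraction of events whose `minF` and `maxF` both stay
#' inside the band of the event's peak (band-limited), the fraction whose
#' `minF` dips below it (spread lower), and the fraction whose `maxF` rises
#' above it (spread higher).  An event may spread in both directions, so
#' the three fractions need not sum to 1.
#'
#' @param events Event table (flagged events are dropped).
#' @param scheme Band scheme data.frame.
#' @return data.frame with `band`, `n`, `limited`, `spread_lower`,
#'   `spread_higher`.
#' @export
band_limited_fraction <- function(events, scheme = band_scheme()) {
  ev <- unflagged(events)
  ev$band <- classify_band(ev$peakF, scheme)
  res <- lapply(seq_len(nrow(scheme)), function(b) {
    sel <- ev[ev$band == scheme$band[b], , drop = FALSE]
    n <- nrow(sel)
    lower <- sel$minF <= scheme$low[b]     # below the open lower bound
    higher <- sel$maxF > scheme$high[b]
    data.frame(band = scheme$band[b], n = n,
               limited = if (n) mean(!lower & !higher) else NA_real_,
               spread_lower = if (n) mean(lower) else NA_real_,
               spread_higher = if (n) mean(higher) else NA_real_)
  })
  do.call(rbind, res)
}
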