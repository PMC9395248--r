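#' Find suprathreshold local spectral peaks
#'
#' A peak is a bin of the median-normalized spectrogram that strictly
#' exceeds all of its neighbors in the local 3 x 3 window and exceeds the
#' detection threshold.  Matrix borders (and window boundaries, since
#' windows are transformed independently) are compared against available
#' neighbors only.  Plateaus of exactly equal adjacent values yield a single
#' peak: the earliest-time, lowest-frequency bin of the plateau.
#'
#' @param spec Normalized `oe_spectrogram`.
#' @param threshold Multiple of median power a peak must exceed.
#' @return data.frame with `f_index`, `t_index` (column in the full
#'   spectrogram) and `peak_power`.
#' @export
find_peaks <- function(spec, threshold = 4) {
  stopifnot(inherits(spec, "oe_spectrogram"), isTRUE(spec$normalized))
  out <- lapply(unique(spec$window_index), function(w) {
    cols <- which(spec$window_index == w)
    pk <- local_maxima(spec$power[, cols, drop = FALSE], threshold)
    if (nrow(pk)) pk$t_index <- pk$t_index + cols[1] - 1L
    pk
  })
  do.call(rbind, out)
}

# internal: strict 3x3 local maxima of matrix m above threshold, with
# plateau tie-breaking (earliest column, then lowest row); sparse — only
# suprathreshold bins are examined
local_maxima <- function(m, threshold) {
  nf <- nrow(m); nt <- ncol(m)
  idx <- which(m > threshold)
  if (!length(idx))
    return(data.frame(f_index = integer(0), t_index = integer(0),
                      peak_power = numeric(0)))
  ri <- ((idx - 1L) %% nf) + 1L
  ci <- ((idx - 1L) %/% nf) + 1L
  v <- m[idx]
  ge <- gt <- rep(TRUE, length(idx))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ok <- ri + di >= 1L & ri + di <= nf & ci + dj >= 1L & ci + dj <= nt
    nbv <- rep(-Inf, length(idx))
    nbv[ok] <- m[idx[ok] + di + dj * nf]
    ge <- ge & v >= nbv
    gt <- gt & v > nbv
  }
  res <- data.frame(f_index = ri[gt], t_index = ci[gt], peak_power = v[gt])
  pl <- which(ge & !gt)
  if (length(pl)) {
    # group adjacent equal-valued plateau candidates; keep one per group
    rows <- ri[pl]; cols <- ci[pl]; vals <- v[pl]
    key <- rep(NA_integer_, length(pl))
    grp <- 0L
    for (k in order(cols, rows)) {
      if (!is.na(key[k])) next
      grp <- grp + 1L
      queue <- k
      key[k] <- grp
      while (length(queue)) {
        q <- queue[[1]]; queue <- queue[-1]
        nb <- which(is.na(key) & abs(rows - rows[q]) <= 1 &
                      abs(cols - cols[q]) <= 1 & vals == vals[q])
        key[nb] <- grp
        queue <- c(queue, nb)
      }
    }
    for (g in seq_len(grp)) {
      members <- which(key == g)
      lead <- members[order(cols[members], rows[members])][1]
      res <- rbind(res, data.frame(f_index = rows[lead],
                                   t_index = cols[lead],
                                   peak_power = vals[lead]))
    }
  }
  res[order(res$t_index, res$f_index), , drop = FALSE]
}

#' Grow a bounding box around a spectral peak
#'
#' Walks outward from the peak along its frequency row (left and right in
#' time) and along its time column (down and up in frequency), including
#' bins while their power stays at or above
#' `bound = min(peak_power / 2, threshold)` — i.e. the smaller of half the
#' event's maximum amplitude and the detection threshold.  The boundary bin
#' is the last bin with power >= bound; the box is clipped to the peak's
#' analysis window.
#'
#' @param spec Normalized `oe_spectrogram`.
#' @param peak One row of [find_peaks()] output (or a list with `f_index`,
#'   `t_index`, `peak_power`).
#' @param threshold Detection threshold (multiple of median power).
#' @return Integer vector `(f_lo, f_hi, t_lo, t_hi)` of bin indices.
#' @export
grow_box <- function(spec, peak, threshold = 4) {
  pw <- spec$power
  fi <- peak$f_index; ti <- peak$t_index
  bound <- min(peak$peak_power / 2, threshold)
  wcols <- range(which(spec$window_index == spec$window_index[ti]))
  t_lo <- ti
  while (t_lo > wcols[1] && pw[fi, t_lo - 1] >= bound) t_lo <- t_lo - 1L
  t_hi <- ti
  while (t_hi < wcols[2] && pw[fi, t_hi + 1] >= bound) t_hi <- t_hi + 1L
  f_lo <- fi
  while (f_lo > 1 && pw[f_lo - 1, ti] >= bound) f_lo <- f_lo - 1L
  f_hi <- fi
  while (f_hi < nrow(pw) && pw[f_hi + 1, ti] >= bound) f_hi <- f_hi + 1L
  c(f_lo = f_lo, f_hi = f_hi, t_lo = as.integer(t_lo), t_hi = as.integer(t_hi))
}

# internal: 2-D flood-fill variant of box growth (sensitivity analysis):
# bounding box of the 4-connected suprathreshold component containing the peak
grow_box_flood <- function(spec, peak, threshold = 4) {
  pw <- spec$power
  bound <- min(peak$peak_power / 2, threshold)
  wcols <- which(spec$window_index == spec$window_index[peak$t_index])
  sub <- pw[, wcols, drop = FALSE] >= bound
  nf <- nrow(sub); nt <- ncol(sub)
  seen <- matrix(FALSE, nf, nt)
  start <- c(peak$f_index, peak$t_index - wcols[1] + 1L)
  stack <- list(start); seen[start[1], start[2]] <- TRUE
  f_rng <- rep(start[1], 2); t_rng <- rep(start[2], 2)
  while (length(stack)) {
    cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    f_rng <- range(f_rng, cur[1]); t_rng <- range(t_rng, cur[2])
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      i <- cur[1] + d[1]; j <- cur[2] + d[2]
      if (i >= 1 && i <= nf && j >= 1 && j <= nt && sub[i, j] && !seen[i, j]) {
        seen[i, j] <- TRUE
        stack[[length(stack) + 1]] <- c(i, j)
      }
    }
  }
  c(f_lo = f_rng[1], f_hi = f_rng[2],
    t_lo = t_rng[1] + wcols[1] - 1L, t_hi = t_rng[2] + wcols[1] - 1L)
}

#' Merge events with heavily overlapping bounding boxes
#'
#' Two events are merged when the area of the intersection of their
#' time-frequency bounding boxes strictly exceeds `merge_overlap` times the
#' smaller of the two box areas.  The merged event takes the union box and
#' the peak attributes (`t_peak`, `peakF`, `peak_power`) of the constituent
#' with the higher peak power.  Merging is repeated to a fixed point and the
#' result is ordered by `t_start`.
#'
#' Extents are treated inclusively: a box's sides are
#' `t_stop - t_start + dt` and `maxF - minF + df`, where `dt` and `df`
#' are the widths of one time/frequency bin (0 for boxes given in purely
#' continuous coordinates, in which case zero-width intersections never
#' merge).
#'
#' @param events data.frame with at least `t_start`, `t_stop`, `minF`,
#'   `maxF`, `t_peak`, `peakF`, `peak_power` (an event table works).
#' @param merge_overlap Overlap fraction in (0, 1).
#' @param dt,df Bin widths (seconds, Hz).
#' @return The merged data.frame.
#' @export
merge_events <- function(events, merge_overlap = 0.5, dt = 0, df = 0) {
  ev <- as.data.frame(events)
  if (nrow(ev) < 2) return(ev)
  repeat {
    merged <- FALSE
    n <- nrow(ev)
    area <- (ev$t_stop - ev$t_start + dt) * (ev$maxF - ev$minF + df)
    for (a in seq_len(n - 1)) {
      ovt <- pmin(ev$t_stop[-(1:a)], ev$t_stop[a]) -
        pmax(ev$t_start[-(1:a)], ev$t_start[a]) + dt
      ovf <- pmin(ev$maxF[-(1:a)], ev$maxF[a]) -
        pmax(ev$minF[-(1:a)], ev$minF[a]) + df
      ov <- pmax(ovt, 0) * pmax(ovf, 0) * (ovt > 0) * (ovf > 0)
      hit <- which(ov > merge_overlap * pmin(area[-(1:a)], area[a]))
      if (length(hit)) {
        b <- hit[1] + a
        keep <- if (ev$peak_power[a] >= ev$peak_power[b]) a else b
        ev$t_start[a] <- min(ev$t_start[a], ev$t_start[b])
        ev$t_stop[a] <- max(ev$t_stop[a], ev$t_stop[b])
        ev$minF[a] <- min(ev$minF[a], ev$minF[b])
        ev$maxF[a] <- max(ev$maxF[a], ev$maxF[b])
        ev$t_peak[a] <- ev$t_peak[keep]
        ev$peakF[a] <- ev$peakF[keep]
        ev$peak_power[a] <- ev$peak_power[keep]
        ev <- ev[-b, , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  ev[order(ev$t_start, ev$minF), , drop = FALSE]
}

# internal: merge within each analysis window (events never span windows,
# so boxes in different windows cannot overlap)
merge_events_by_window <- function(ev, merge_overlap, dt, df) {
  if (nrow(ev) < 2 || !("window" %in% names(ev))) {
    return(merge_events(ev, merge_overlap, dt, df))
  }
  out <- lapply(split(ev, ev$window), merge_events, merge_overlap, dt, df)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$t_start, out$minF), , drop = FALSE]
}

#' Detect oscillation events in a recording
#'
#' Full pipeline for one channel: (optional) decimation to the analysis
#' rate, Morlet spectrogram on nonoverlapping windows, per-frequency median
#' normalization over the whole recording, suprathreshold 3 x 3 local
#' maxima, bounding-box growth, overlap merging, feature extraction and
#' band classification, and flagging of ERP-like and broadband events.
#' Deterministic given its inputs.
#'
#' @param rec An [recording()].
#' @param channel Channel index or label.
#' @param params [detection_params()].
#' @param erp_templates Optional list of [erp_template()] objects (or a
#'   single one).  When given, each event's ERP score is computed against
#'   the template whose label matches the channel label (falling back to the
#'   first template) and the ERP exclusion rule is applied; when absent the
#'   ERP rule is skipped, as for recordings without evoked-response data.
#' @param waveform_features Extract per-event filtered-waveform features
#'   (filter-match, peak/trough counts)?  Skipping them speeds up large
#'   simulation sweeps where only box geometry is needed.
#' @param analysis_fs Internal analysis rate, Hz; the recording is decimated
#'   to this rate when sampled faster (default 1000, comfortably above four
#'   times the 250-Hz maximum analysis frequency).
#' @param box_method `"axis"` (walk the peak row and column, default) or
#'   `"flood"` (bounding box of the 2-D suprathreshold component).
#' @return An event table (class `oe_events`): data.frame with columns
#'   `id, channel, window, t_start, t_stop, t_peak, minF, maxF, peakF,
#'   peak_power, duration, n_cycles, Fspan, band, filter_match, n_peaks,
#'   n_troughs, erp_score, flag_erp, flag_broadband`.  The analyzed
#'   duration, sampling rate and parameters are carried in attributes.
#' @export
detect <- function(rec, channel = 1, params = detection_params(),
                   erp_templates = NULL, waveform_features = TRUE,
                   analysis_fs = 1000, box_method = c("axis", "flood")) {
  box_method <- match.arg(box_method)
  stopifnot(inherits(rec, "oe_recording"))
  if (is.character(channel)) channel <- match(channel, rec$channel_labels)
  if (rec$fs > analysis_fs) rec <- resample_recording(rec, analysis_fs)
  spec <- morlet_power(rec, channel, params)
  spec <- normalize_by_median(spec, zero_median = "zero")
  peaks <- find_peaks(spec, params$threshold)
  ev <- events_from_peaks(spec, peaks, params, box_method)
  ev <- merge_events_by_window(ev, params$merge_overlap,
                               dt = 1 / spec$fs, df = params$freq_step)
  ev <- extract_features(ev, rec, channel, spec, params,
                         erp_templates, waveform_features)
  ev <- apply_exclusions(ev)
  ev$id <- seq_len(nrow(ev))
  rownames(ev) <- NULL
  structure(ev, class = c("oe_events", "data.frame"),
            params = params, fs = spec$fs,
            total_duration = rec_duration(rec),
            channel_label = rec$channel_labels[channel])
}

# internal: turn peaks + boxes into a raw event data.frame (continuous units)
events_from_peaks <- function(spec, peaks, params, box_method = "axis") {
  cols <- c("channel", "window", "t_start", "t_stop", "t_peak",
            "minF", "maxF", "peakF", "peak_power")
  if (is.null(peaks) || nrow(peaks) == 0) {
    ev <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                        cols))
    return(ev)
  }
  grow <- if (box_method == "axis") grow_box else grow_box_flood
  boxes <- t(vapply(seq_len(nrow(peaks)), function(k)
    grow(spec, peaks[k, ], params$threshold), numeric(4)))
  data.frame(
    channel = spec$channel,
    window = spec$window_index[peaks$t_index],
    t_start = spec$times[boxes[, "t_lo"]],
    t_stop = spec$times[boxes[, "t_hi"]],
    t_peak = spec$times[peaks$t_index],
    minF = spec$freqs[boxes[, "f_lo"]],
    maxF = spec$freqs[boxes[, "f_hi"]],
    peakF = spec$freqs[peaks$f_index],
    peak_power = peaks$peak_power)
}

# internal: derived quantities + waveform features for merged events
extract_features <- function(ev, rec, channel, spec, params,
                             erp_templates, waveform_features) {
  n <- nrow(ev)
  ev$duration <- ev$t_stop - ev$t_start
  ev$n_cycles <- ev$duration * ev$peakF
  ev$Fspan <- log(ev$maxF / ev$minF)
  ev$band <- if (n) classify_band(ev$peakF) else character(0)
  ev$filter_match <- rep(NA_real_, n)
  ev$n_peaks <- rep(NA_integer_, n)
  ev$n_troughs <- rep(NA_integer_, n)
  ev$erp_score <- rep(NA_real_, n)
  if (n == 0 || (!waveform_features && is.null(erp_templates))) return(ev)
  x <- rec$samples[channel, ]
  fs <- rec$fs
  nwin_len <- round(params$window_len * fs)
  tpl <- pick_template(erp_templates, rec$channel_labels[channel])
  for (k in seq_len(n)) {
    w <- ev$window[k]
    widx <- ((w - 1) * nwin_len + 1):(w * nwin_len)
    i1 <- max(widx[1], round((ev$t_start[k] - rec$t0) * fs) + 1)
    i2 <- min(widx[length(widx)], round((ev$t_stop[k] - rec$t0) * fs) + 1)
    seg_raw <- x[i1:i2]
    if (waveform_features) {
      # filter the whole window, then cut the event span, to keep filter
      # transients away from the event edges
      filt <- bandpass_event(x[widx], ev$minF[k], ev$maxF[k], fs,
                             freq_step = params$freq_step)
      seg_f <- filt[(i1:i2) - widx[1] + 1]
      if (length(seg_raw) >= 3 && stats::sd(seg_raw) > 0 &&
          stats::sd(seg_f) > 0)
        ev$filter_match[k] <- filter_match(seg_raw, seg_f)$r
      extr <- count_extrema(seg_f)
      ev$n_peaks[k] <- extr[["n_peaks"]]
      ev$n_troughs[k] <- extr[["n_troughs"]]
    }
    if (!is.null(tpl) && length(seg_raw) >= 3 && stats::sd(seg_raw) > 0)
      ev$erp_score[k] <- erp_score(seg_raw, tpl, fs = fs)
  }
  ev
}

pick_template <- function(erp_templates, label) {
  if (is.null(erp_templates)) return(NULL)
  if (inherits(erp_templates, "oe_erp_template")) return(erp_templates)
  labs <- vapply(erp_templates, function(t) t$label %||% "", "")
  hit <- which(labs == label)
  if (length(hit)) erp_templates[[hit[1]]] else erp_templates[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an event table as CSV
#'
#' Columns are written in the fixed order `id, channel, window, t_start,
#' t_stop, t_peak, minF, maxF, peakF, peak_power, duration, n_cycles,
#' Fspan, band, filter_match, n_peaks, n_troughs, erp_score, flag_erp,
#' flag_broadband`.
#'
#' @param events Event table from [detect()].
#' @param path CSV path.
#' @return `path` / the event table.
#' @export
write_events <- function(events, path) {
  cols <- c("id", "channel", "window", "t_start", "t_stop", "t_peak",
            "minF", "maxF", "peakF", "peak_power", "duration", "n_cycles",
            "Fspan", "band", "filter_match", "n_peaks", "n_troughs",
            "erp_score", "flag_erp", "flag_broadband")
  utils::write.csv(as.data.frame(events)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(ev, class = c("oe_events", "data.frame"))
}

#' @export
print.oe_events <- function(x, ...) {
  cat(sprintf("Oscillation events: %d event(s)", nrow(x)))
  if (nrow(x)) {
    excl <- sum(x$flag_erp | x$flag_broadband)
    cat(sprintf(" (%d flagged for exclusion)", excl))
    cat("\n")
    tab <- table(factor(x$band, levels = band_scheme()$band))
    cat("  by band:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  } else cat("\n")
  invisible(x)
}
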