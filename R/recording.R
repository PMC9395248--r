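#' Construct a recording
#'
#' A recording is a channels x time matrix of samples with a sampling rate,
#' channel labels, signal units, and a time offset for the first sample.
#'
#' @param samples Numeric matrix, channels x time (a vector is treated as one
#'   channel).
#' @param fs Sampling rate, Hz (> 0).
#' @param channel_labels Character vector, one label per channel.
#' @param units Signal units, e.g. `"mV/mm2"` for CSD or `"V"` for iEEG.
#' @param t0 Time of the first sample, seconds.
#' @return Object of class `oe_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(2000), nrow = 2), fs = 1000)
#' rec_duration(rec)
#' @export
recording <- function(samples, fs, channel_labels = NULL, units = "a.u.",
                      t0 = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), is.numeric(samples), fs > 0)
  if (!all(is.finite(samples))) stop("recording samples must all be finite")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  if (length(channel_labels) != nrow(samples))
    stop("channel count must equal label count")
  structure(list(samples = samples, fs = fs,
                 channel_labels = as.character(channel_labels),
                 units = units, t0 = t0),
            class = "oe_recording")
}

#' @rdname recording
#' @param rec An `oe_recording`.
#' @export
rec_duration <- function(rec) ncol(rec$samples) / rec$fs

#' @export
print.oe_recording <- function(x, ...) {
  cat(sprintf("Recording: %d channel(s), %.3f s at %g Hz [%s]\n",
              nrow(x$samples), rec_duration(x), x$fs, x$units))
  invisible(x)
}

#' Laminar electrode geometry
#'
#' @param spacing Inter-contact spacing in micrometers (> 0); contacts are
#'   assumed ordered superficial to deep.
#' @return Object of class `oe_geometry`.
#' @export
laminar_geometry <- function(spacing) {
  stopifnot(is.numeric(spacing), length(spacing) == 1, spacing > 0)
  structure(list(spacing_um = spacing), class = "oe_geometry")
}

#' Read a recording from disk
#'
#' Supported formats: `"csv"` (one column per channel with a header row of
#' labels), `"binary"` (raw little-endian float32/float64, channel-major,
#' with a JSON sidecar `<path>.json` holding `fs`, `n_channels`, `dtype`,
#' and optionally `labels`, `units`, `t0`), and `"edf"` (standard 16-bit
#' European Data Format; all signals must share one sampling rate).  For
#' headerless formats (`csv`, `binary` without sidecar) the sampling rate
#' must be supplied.
#'
#' @param path File path.
#' @param format One of `"csv"`, `"binary"`, `"edf"`; default guesses from
#'   the file extension.
#' @param fs Sampling rate, Hz; required for csv and for binary without a
#'   sidecar, ignored for EDF (taken from the header).
#' @param units Signal units (overrides any stored value when given).
#' @return An [recording()] object.
#' @export
read_recording <- function(path, format = NULL, fs = NULL, units = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (file.size(path) == 0) stop("file is empty: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", edf = "edf", bin = "binary", dat = "binary",
                     stop("cannot guess format from extension: ", path))
  }
  format <- match.arg(format, c("csv", "binary", "edf"))
  rec <- switch(format,
    csv = {
      if (is.null(fs)) stop("fs must be given for CSV recordings")
      d <- utils::read.csv(path, check.names = FALSE)
      recording(t(as.matrix(d)), fs = fs, channel_labels = names(d),
                units = if (is.null(units)) "a.u." else units)
    },
    binary = read_recording_binary(path, fs, units),
    edf = read_edf(path))
  if (!is.null(units)) rec$units <- units
  rec
}

read_recording_binary <- function(path, fs, units) {
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  if (is.null(fs)) fs <- meta$fs
  if (is.null(fs)) stop("fs must be given for raw binary without sidecar")
  nch <- meta$n_channels
  if (is.null(nch)) stop("raw binary requires n_channels in sidecar metadata")
  dtype <- if (is.null(meta$dtype)) "float64" else meta$dtype
  bytes <- if (dtype == "float32") 4L else 8L
  n <- file.size(path) / bytes
  con <- file(path, "rb"); on.exit(close(con))
  x <- readBin(con, "double", n = n, size = bytes, endian = "little")
  if (length(x) %% nch != 0) stop("binary length not a multiple of n_channels")
  m <- matrix(x, nrow = nch, byrow = TRUE)  # channel-major: ch1 block, ch2 block
  recording(m, fs = fs,
            channel_labels = meta$labels,
            units = if (!is.null(units)) units
                    else if (!is.null(meta$units)) meta$units else "a.u.",
            t0 = if (is.null(meta$t0)) 0 else meta$t0)
}

#' Write a recording to disk
#'
#' @inheritParams read_recording
#' @param rec An [recording()] object.
#' @param format `"csv"`, `"binary"` (float64 + JSON sidecar) or `"edf"`
#'   (16-bit; quantizes to the per-channel physical range).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv", "binary", "edf")) {
  format <- match.arg(format)
  switch(format,
    csv = {
      d <- as.data.frame(t(rec$samples))
      names(d) <- rec$channel_labels
      utils::write.csv(d, path, row.names = FALSE)
    },
    binary = {
      con <- file(path, "wb")
      writeBin(as.vector(t(rec$samples)), con, size = 8, endian = "little")
      close(con)
      jsonlite::write_json(
        list(fs = rec$fs, n_channels = nrow(rec$samples), dtype = "float64",
             labels = rec$channel_labels, units = rec$units, t0 = rec$t0),
        paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    },
    edf = write_edf(rec, path))
  invisible(path)
}

#' Current-source density from laminar recordings
#'
#' Estimates CSD as the negative second spatial difference of the laminar
#' potential profile, `-(V[i-1] - 2 V[i] + V[i+1]) / dz^2`, so that current
#' sinks (depolarizing transmembrane current) are positive.  Edge contacts
#' are dropped: the result has `n - 2` channels, labelled after the interior
#' contacts.
#'
#' @param rec Laminar [recording()] with >= 3 channels ordered
#'   superficial to deep.
#' @param geom [laminar_geometry()]; the contact spacing (um) is converted to
#'   mm, so a potential in mV yields CSD in mV/mm^2.
#' @return An [recording()] of the interior-contact CSD.
#' @export
compute_csd <- function(rec, geom) {
  stopifnot(inherits(rec, "oe_recording"), inherits(geom, "oe_geometry"))
  v <- rec$samples
  if (nrow(v) < 3) stop("CSD requires at least 3 channels")
  dz <- geom$spacing_um / 1000  # mm
  i <- 2:(nrow(v) - 1)
  csd <- -(v[i - 1, , drop = FALSE] - 2 * v[i, , drop = FALSE] +
             v[i + 1, , drop = FALSE]) / dz^2
  recording(csd, fs = rec$fs, channel_labels = rec$channel_labels[i],
            units = paste0(rec$units, "/mm2"), t0 = rec$t0)
}

#' Decimate a recording to an analysis rate
#'
#' Applies a zero-phase 4th-order Butterworth low-pass at 0.4x the target
#' rate and resamples by linear interpolation.  Used to bring acquisition
#' rates (e.g. 44 kHz) down to the analysis rate before wavelet transforms;
#' the target must of course stay above twice the highest analysis frequency.
#'
#' @param rec An [recording()].
#' @param fs_target Target sampling rate, Hz (< `rec$fs`).
#' @return The resampled [recording()].
#' @export
resample_recording <- function(rec, fs_target) {
  stopifnot(fs_target > 0)
  if (fs_target >= rec$fs) return(rec)
  bf <- signal::butter(4, 0.8 * fs_target / rec$fs)  # 0.4*fs_target in Hz
  n_old <- ncol(rec$samples)
  t_old <- (seq_len(n_old) - 1) / rec$fs
  n_new <- floor(n_old * fs_target / rec$fs)
  t_new <- (seq_len(n_new) - 1) / fs_target
  out <- matrix(0, nrow(rec$samples), n_new)
  for (ch in seq_len(nrow(rec$samples))) {
    y <- signal::filtfilt(bf, rec$samples[ch, ])
    out[ch, ] <- stats::approx(t_old, y, xout = t_new, rule = 2)$y
  }
  recording(out, fs = fs_target, channel_labels = rec$channel_labels,
            units = rec$units, t0 = rec$t0)
}
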