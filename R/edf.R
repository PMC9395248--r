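# Minimal reader/writer for standard 16-bit EDF (European Data Format).
# Covers the plain continuous layout: 256-byte fixed header, 256 bytes of
# header per signal, then data records of little-endian int16 samples scaled
# linearly from digital to physical range.  EDF+ annotations are not parsed.

edf_field <- function(raw, at, len) {
  trimws(rawToChar(raw[at:(at + len - 1)]))
}

read_edf <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", n = 256)
  n_rec <- as.integer(edf_field(hdr, 237, 8))
  rec_dur <- as.numeric(edf_field(hdr, 245, 8))
  ns <- as.integer(edf_field(hdr, 253, 4))
  if (is.na(ns) || ns < 1) stop("not a valid EDF file: ", path)
  sig <- readBin(con, "raw", n = 256 * ns)
  fld <- function(off, len)  # per-signal header arrays are field-major
    vapply(seq_len(ns), function(i)
      edf_field(sig, off * ns + (i - 1) * len + 1, len), "")
  labels <- fld(0, 16)
  phys_dim <- fld(96, 8)
  phys_min <- as.numeric(fld(104, 8)); phys_max <- as.numeric(fld(112, 8))
  dig_min <- as.numeric(fld(120, 8));  dig_max <- as.numeric(fld(128, 8))
  spr <- as.integer(fld(216, 8))  # samples per record
  if (length(unique(spr)) != 1)
    stop("EDF signals with differing sampling rates are not supported")
  if (n_rec < 0)  # unknown record count: infer from file size
    n_rec <- (sz - 256 * (ns + 1)) %/% (2 * sum(spr))
  fs <- spr[1] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  x <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
               signed = TRUE, endian = "little")
  out <- matrix(0, ns, n_rec * spr[1])
  dim(x) <- c(spr[1], ns, n_rec)
  for (i in seq_len(ns))
    out[i, ] <- as.vector(x[, i, ]) * gain[i] + phys_min[i] - dig_min[i] * gain[i]
  units <- unique(phys_dim)
  recording(out, fs = fs, channel_labels = labels,
            units = if (length(units) == 1 && nzchar(units)) units else "a.u.")
}

pad_field <- function(x, len) {
  s <- substr(format(x), 1, len)
  formatC(s, width = len, flag = "-")
}

write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate")
  ns <- nrow(rec$samples)
  spr <- as.integer(round(fs))          # one-second records
  n_rec <- ncol(rec$samples) %/% spr
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)")
  x <- rec$samples[, seq_len(n_rec * spr), drop = FALSE]
  phys_min <- apply(x, 1, min); phys_max <- apply(x, 1, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  con <- file(path, "wb"); on.exit(close(con))
  w <- function(s, len) writeChar(pad_field(s, len), con, nchars = len,
                                  eos = NULL)
  w("0", 8); w("X", 80); w("X", 80)
  w("01.01.00", 8); w("00.00.00", 8)
  w(as.character(256 * (ns + 1)), 8); w("", 44)
  w(as.character(n_rec), 8); w("1", 8); w(as.character(ns), 4)
  for (s in rec$channel_labels) w(s, 16)
  for (i in seq_len(ns)) w("", 80)
  for (i in seq_len(ns)) w(rec$units, 8)
  for (v in phys_min) w(sprintf("%.6g", v), 8)
  for (v in phys_max) w(sprintf("%.6g", v), 8)
  for (i in seq_len(ns)) w(as.character(dig_min), 8)
  for (i in seq_len(ns)) w(as.character(dig_max), 8)
  for (i in seq_len(ns)) w("", 80)
  for (i in seq_len(ns)) w(as.character(spr), 8)
  for (i in seq_len(ns)) w("", 32)
  dig <- matrix(0L, ns, n_rec * spr)
  for (i in seq_len(ns))
    dig[i, ] <- as.integer(round((x[i, ] - phys_min[i]) / gain[i]) + dig_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns))
      writeBin(dig[i, idx], con, size = 2, endian = "little")
  }
  invisible(path)
}
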