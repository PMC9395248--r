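# Shared fixtures: all built in code at test time.

# a pure-sinusoid recording
sine_rec <- function(f = 10, dur = 10, fs = 500, amp = 1, phase = 0) {
  t <- (0:(dur * fs - 1)) / fs
  recording(amp * sin(2 * pi * f * t + phase), fs = fs)
}

# small detection parameter sets keep the transforms fast
alpha_params <- function(...) {
  detection_params(freq_min = 1, freq_max = 40, freq_step = 0.25, ...)
}

# wrap a plain power matrix as a normalized single-window spectrogram, so
# the peak/box operations can be exercised on hand-built matrices
toy_spec <- function(m, fs = 1, freqs = seq_len(nrow(m)), normalized = TRUE) {
  structure(list(power = m, freqs = freqs,
                 times = (seq_len(ncol(m)) - 1) / fs,
                 window_index = rep(1L, ncol(m)),
                 fs = fs, normalized = normalized,
                 norm_medians = if (normalized) rep(1, nrow(m)) else NULL,
                 params = NULL, channel = 1L),
            class = "oe_spectrogram")
}

# bare event rows for the statistics module
toy_events <- function(t_start, t_stop, band = "alpha",
                       t_peak = (t_start + t_stop) / 2,
                       peakF = 10, minF = peakF - 1, maxF = peakF + 1,
                       flag_erp = FALSE, flag_broadband = FALSE) {
  data.frame(t_start = t_start, t_stop = t_stop, t_peak = t_peak,
             band = band, peakF = peakF, minF = minF, maxF = maxF,
             peak_power = 10, duration = t_stop - t_start,
             flag_erp = flag_erp, flag_broadband = flag_broadband)
}
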