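Package: oscevents
Title: Detection and Characterization of Neuronal Oscillation Events
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects moderate-to-high-power oscillation events in
    electrophysiological time series (LFP, CSD, iEEG, MUA) from Morlet
    wavelet spectrograms normalized by per-frequency median power.
    Events are found as local spectral maxima above a median-relative
    threshold, bounded by time-frequency boxes, merged when overlapping,
    and characterized by peak frequency, cycle count, frequency span,
    filter-match and waveform extrema.  Includes exclusion of
    event-related-potential-like and broadband transients, event-train
    statistics (rates, active-time ratio, interevent-interval CV2 and
    Fano factor, co-occurrence, band-limited fractions), phase-amplitude
    coupling, current-source density from laminar recordings, and a
    synthetic-data harness that embeds ground-truth sinusoidal bursts in
    1/f background to validate detection accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
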