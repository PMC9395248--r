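test_that("1/f background has the requested spectral slope and RMS", {
  rec <- gen_background(60, 500, exponent = 1.5, scale = 2, seed = 1)
  x <- rec$samples[1, ]
  expect_equal(sqrt(mean(x^2)), 2, tolerance = 1e-9)
  expect_lt(abs(mean(x)), 1e-9)
  # log-log periodogram slope within +-0.2 of -exponent
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  f <- (1:(n / 2)) * 500 / n
  keep <- f >= 1 & f <= 100
  fit <- stats::coef(lm(log(sp[2:(n / 2 + 1)][keep]) ~ log(f[keep])))[2]
  expect_equal(unname(fit), -1.5, tolerance = 0.2)
})

test_that("background generation is seed-reproducible; scale 0 is silence", {
  a <- gen_background(5, 200, seed = 7)
  b <- gen_background(5, 200, seed = 7)
  c3 <- gen_background(5, 200, seed = 8)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c3$samples))
  expect_true(all(gen_background(5, 200, scale = 0, seed = 7)$samples == 0))
})

test_that("burst embedding adds exactly the stated sinusoid", {
  rec <- gen_background(10, 500, seed = 2)
  same <- embed_burst(rec, 10, 0, 1.5, t_start = 3)
  expect_identical(same$recording$samples, rec$samples)
  emb <- embed_burst(rec, 10, 11, 1.5, t_start = 3)
  expect_equal(emb$truth$t_stop - emb$truth$t_start, 1.1)
  # embedding the negated burst restores the original
  sub <- embed_burst(emb$recording, 10, 11, -1.5, t_start = 3)$recording
  expect_equal(sub$samples, rec$samples, tolerance = 1e-12)
  expect_error(embed_burst(rec, 10, 11, 1.5, t_start = 9.5), "fit")
})

test_that("embedded ERP transients are recovered by the ERP score", {
  fs <- 500
  tt <- (0:(0.2 * fs - 1)) / fs
  tpl <- erp_template(exp(-((tt - 0.05) / 0.015)^2), fs = fs, label = "supra")
  rec <- gen_background(10, fs, scale = 0.05, seed = 3)
  emb <- embed_erp(rec, tpl, t = 4, gain = 2)
  seg <- emb$samples[1, (4 * fs + 1):(4.2 * fs)]
  expect_gt(erp_score(seg, tpl, fs), 0.95)
  expect_identical(embed_erp(rec, tpl, t = 4, gain = 0)$samples, rec$samples)
  # a shifted embedding is found at the right lag by sliding correlation
  long <- emb$samples[1, (3.8 * fs + 1):(4.4 * fs)]
  lags <- vapply(0:(length(long) - length(tpl$waveform)), function(l) {
    seg <- long[(l + 1):(l + length(tpl$waveform))]
    stats::cor(seg, tpl$waveform)
  }, 0)
  expect_equal(which.max(lags) - 1, 0.2 * fs, tolerance = 2)
})

test_that("ERP-like events are flagged and excluded from statistics", {
  fs <- 500
  tt <- (0:(0.15 * fs - 1)) / fs
  # ~50-ms sharp transient, as a stereotyped evoked response
  tpl <- erp_template(exp(-((tt - 0.05) / 0.012)^2), fs = fs, label = "supra")
  rec <- gen_background(20, fs, scale = 0.4, seed = 13)
  for (t0 in c(3, 8, 14)) rec <- embed_erp(rec, tpl, t = t0, gain = 4)
  ev <- detect(rec, params = alpha_params(), erp_templates = tpl,
               analysis_fs = fs)
  # transients score high against the template they were built from ...
  near <- ev[ev$t_start < 14.2 & ev$t_stop > 13.9, ]
  expect_gt(max(near$erp_score, na.rm = TRUE), 0.8)
  # ... and every embedding site is flagged for exclusion, by the ERP rule
  # or (for these rapid-onset transients, whose boxes span many bands) by
  # the broadband Fspan rule
  flagged <- ev[ev$flag_erp | ev$flag_broadband, ]
  hit <- vapply(c(3, 8, 14), function(t0)
    any(flagged$t_start < t0 + 0.2 & flagged$t_stop > t0), TRUE)
  expect_true(all(hit))
  # flagged events do not count toward rates
  expect_lt(event_rate(ev, total_duration = 20),
            nrow(ev) / 20)
})

test_that("noise-free bursts of >= 4 cycles are always recalled", {
  fs <- 500
  for (f in c(6, 10, 21)) {
    rec <- recording(rep(0, 10 * fs), fs = fs)
    emb <- embed_burst(rec, f, 6, 1.5, t_start = 4)
    p <- validation_params(f, fs)
    ev <- detect(emb$recording, params = p, analysis_fs = fs)
    ov <- pmin(ev$t_stop, emb$truth$t_stop) -
      pmax(ev$t_start, emb$truth$t_start)
    near <- abs(ev$peakF - f) < f / 2
    expect_true(any(ov > 0 & near), label = paste("recall at", f, "Hz"))
  }
})

test_that("validation recovers burst cycle counts at the default background", {
  sc <- sim_scenario("alpha", cycles = c(6, 11), reps = 5, seed = 21)
  res <- run_validation(sc)
  expect_equal(res$by_band$recall, 1)
  # detected cycles track the truth within a couple of cycles on average
  expect_equal(res$by_cycles$mean_cycles, res$by_cycles$n_cycles,
               tolerance = 0.35)
  # peak frequency lands near the simulated 10 Hz
  expect_equal(res$by_band$mean_peakF, 10, tolerance = 0.15)
})

test_that("parameter sweep reduces to plain detection for one combination", {
  rec <- gen_background(30, 500, seed = 22)
  p <- alpha_params()
  tab <- parameter_sweep(rec, widths = 7, thresholds = 4, overlaps = 0.5,
                         params = p)
  ev <- detect(rec, params = p, analysis_fs = 500,
               waveform_features = FALSE)
  for (b in unique(ev$band)) {
    expect_equal(tab$mean_cycles[tab$band == b],
                 mean(ev$n_cycles[ev$band == b]))
    expect_equal(tab$n_events[tab$band == b], sum(ev$band == b))
  }
  # identical seeds give identical sweep tables
  tab2 <- parameter_sweep(gen_background(30, 500, seed = 22), widths = 7,
                          thresholds = 4, overlaps = 0.5, params = p)
  expect_identical(tab, tab2)
})
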