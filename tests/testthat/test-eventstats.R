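test_that("event rate counts unflagged events per second", {
  ev <- toy_events(t_start = seq(0, 18, by = 2), t_stop = seq(1, 19, by = 2))
  expect_equal(event_rate(ev, "alpha", total_duration = 20), 0.5)
  expect_equal(event_rate(ev, "beta", total_duration = 20), 0)
  ev2 <- toy_events(t_start = 0:6, t_stop = 0:6 + 0.5,
                    flag_broadband = c(rep(FALSE, 4), rep(TRUE, 3)))
  expect_equal(event_rate(ev2, "alpha", total_duration = 10), 0.4)
})

test_that("active-time ratio is the union measure of event spans", {
  one <- toy_events(0, 5)
  expect_equal(active_time_ratio(one, total_duration = 10), 0.5)
  dup <- toy_events(c(0, 0), c(5, 5))
  expect_equal(active_time_ratio(dup, total_duration = 10), 0.5)
  pair <- toy_events(c(0, 1), c(2, 3))
  expect_equal(active_time_ratio(pair, total_duration = 10), 0.3)
  expect_equal(active_time_ratio(pair[0, ], total_duration = 10), 0)
})

test_that("any-band ATR bounds every per-band ATR", {
  set.seed(2)
  st <- runif(40, 0, 50)
  ev <- toy_events(st, st + runif(40, 0.2, 4),
                   band = sample(c("delta", "alpha", "gamma"), 40, TRUE))
  atr_all <- active_time_ratio(ev, total_duration = 60)
  per <- vapply(c("delta", "alpha", "gamma"), function(b)
    active_time_ratio(ev, b, total_duration = 60), 0)
  expect_true(all(per <= atr_all + 1e-12))
  expect_true(all(per >= 0 & per <= 1))
})

test_that("interevent intervals in peak and edge modes", {
  ev <- toy_events(c(0.8, 1.9, 3.8), c(1.2, 2.1, 4.2),
                   t_peak = c(1, 2, 4))
  expect_equal(interevent_intervals(ev, mode = "peak"), c(1, 2))
  abut <- toy_events(c(0, 1), c(1, 2))
  expect_equal(interevent_intervals(abut, mode = "edge"), 0)
  # mixed hand case: gaps 0.7 and overlap (clamped to 0)
  mix <- toy_events(c(0, 1.7, 2.5), c(1.0, 2.7, 3.0))
  expect_equal(interevent_intervals(mix, mode = "edge"), c(0.7, 0))
  expect_error(interevent_intervals(mix[1, ], mode = "peak"), "2 events")
})

test_that("CV2 uses population moments and is scale invariant", {
  expect_equal(cv2(c(2, 2, 2, 2)), 0)
  expect_equal(cv2(c(1, 2, 3)), (2 / 3) / 4)    # 1/6
  set.seed(3)
  iv <- rexp(300) + 0.1
  expect_equal(cv2(iv), cv2(iv * 37.5))
  expect_error(cv2(c(-1, 1)), "mean")
})

test_that("CV2 of periodic trains falls to zero as jitter shrinks", {
  set.seed(4)
  vals <- vapply(c(0.2, 0.1, 0.05, 0.01, 0), function(s) {
    times <- seq(1, 500, by = 1) + rnorm(500, sd = s)
    cv2(diff(times))
  }, 0)
  expect_true(all(diff(vals) < 1e-6))
  expect_equal(vals[5], 0)
})

test_that("Fano factor: periodic, hand counts, Poisson reference", {
  times <- seq(0.25, 100, by = 0.5)           # 20 events per 10-s window
  expect_equal(fano_factor(times, 10, 100), 0)
  # counts [2, 4]: var 1, mean 3
  expect_equal(fano_factor(c(0.5, 1, 10.2, 10.4, 10.6, 10.8), 10, 20), 1 / 3)
  expect_error(fano_factor(numeric(0), 10, 100), "no events")
})

test_that("Poisson calibration: CV2 and FF near 1 at large n", {
  set.seed(5)
  expect_equal(cv2(rexp(50000)), 1, tolerance = 0.05)
  tt <- cumsum(rexp(20000, rate = 1.6))
  tt <- tt[tt < 10000]
  expect_equal(fano_factor(tt, 10, 10000), 1, tolerance = 0.05)
})

test_that("rhythmicity test against the Poisson reference", {
  expect_lt(rhythmicity_test(rep(0.2, 10)), 0.05)
  p_null <- rhythmicity_test(c(0.6, 0.8, 0.9, 1.1, 1.2, 1.4))
  expect_gt(p_null, 0.2)
  expect_lt(p_null, 0.8)
  expect_error(rhythmicity_test(0.5), "length")
  expect_error(rhythmicity_test(rep(1, 6)), "Poisson")
})

test_that("co-occurrence counts overlapping events symmetrically", {
  nested <- rbind(toy_events(c(1, 11), c(2, 12), band = "alpha", peakF = 10),
                  toy_events(c(0.5, 10.5), c(3, 13), band = "delta", peakF = 2))
  co <- cooccurrence(nested)
  expect_equal(co["delta", "alpha"], 1)
  apart <- rbind(toy_events(1, 2, peakF = 10),
                 toy_events(5, 6, peakF = 2))
  expect_equal(cooccurrence(apart)["delta", "alpha"], 0)
  # 2 a-events (1 overlapping), 2 b-events (1 overlapping): 2/4
  half <- rbind(toy_events(c(1, 10), c(2, 11), peakF = 10),
                toy_events(c(1.5, 20), c(2.5, 21), peakF = 2))
  expect_equal(cooccurrence(half)["delta", "alpha"], 0.5)
})

test_that("band-limited and spread fractions on a hand table", {
  ev <- rbind(
    toy_events(0, 1, peakF = 10, minF = 9.5, maxF = 14),    # limited
    toy_events(2, 3, peakF = 10, minF = 7, maxF = 14),      # spread lower
    toy_events(4, 5, peakF = 10, minF = 10, maxF = 17),     # spread higher
    toy_events(6, 7, peakF = 10, minF = 8, maxF = 16))      # both
  bl <- band_limited_fraction(ev)
  a <- bl[bl$band == "alpha", ]
  expect_equal(a$n, 4)
  expect_equal(a$limited, 0.25)
  expect_equal(a$spread_lower, 0.5)
  expect_equal(a$spread_higher, 0.5)
})

test_that("per-band rhythmicity detects a strongly periodic train", {
  st <- seq(0.5, 239, by = 2.4) + rnorm(100, sd = 0.05)  # jittered periodic
  ev <- toy_events(st, st + 0.4)
  rh <- band_rhythmicity(ev, "alpha", total_duration = 240)
  expect_lt(rh$cv2_mean, 0.3)
  expect_lt(rh$fano, 0.5)
  expect_lt(rh$p_cv2, 0.05)
})
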