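test_that("find_peaks: no suprathreshold bins means no peaks", {
  spec <- toy_spec(matrix(1, 5, 9))
  expect_equal(nrow(find_peaks(spec, 4)), 0)
})

test_that("find_peaks: isolated bin and plateau tie rule", {
  m <- matrix(1, 5, 9); m[3, 4] <- 5
  pk <- find_peaks(toy_spec(m), 4)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$f_index, 3)
  expect_equal(pk$t_index, 4)
  expect_equal(pk$peak_power, 5)
  # two equal adjacent bins: one peak, at the earliest time
  m2 <- matrix(1, 5, 9); m2[3, 4] <- 5; m2[3, 5] <- 5
  pk2 <- find_peaks(toy_spec(m2), 4)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$t_index, 4)
  # equal bins in one column: one peak, at the lowest frequency
  m3 <- matrix(1, 5, 9); m3[2, 4] <- 5; m3[3, 4] <- 5
  pk3 <- find_peaks(toy_spec(m3), 4)
  expect_equal(nrow(pk3), 1)
  expect_equal(pk3$f_index, 2)
})

test_that("find_peaks respects matrix borders", {
  m <- matrix(1, 4, 6); m[1, 1] <- 6; m[4, 6] <- 7
  pk <- find_peaks(toy_spec(m), 4)
  expect_equal(nrow(pk), 2)   # corner bins beat their available neighbors
})

test_that("grow_box walks the peak row/column to the bound", {
  # ridge [1,3,5,10,5,3,1], threshold 4: bound = min(10/2, 4) = 4
  m <- matrix(0.1, 3, 7)
  m[2, ] <- c(1, 3, 5, 10, 5, 3, 1)
  box <- grow_box(toy_spec(m), list(f_index = 2, t_index = 4,
                                    peak_power = 10), 4)
  expect_equal(unname(box[c("t_lo", "t_hi")]), c(3, 5))   # bins [5,10,5]
  # ridge [1,2,4,6,4,2,1]: bound = min(3, 4) = 3 -> bins [4,6,4]
  m[2, ] <- c(1, 2, 4, 6, 4, 2, 1)
  box2 <- grow_box(toy_spec(m), list(f_index = 2, t_index = 4,
                                     peak_power = 6), 4)
  expect_equal(unname(box2[c("t_lo", "t_hi")]), c(3, 5))
  # isolated hot bin in zeros: 1-bin box
  z <- matrix(0, 5, 7); z[3, 4] <- 9
  box3 <- grow_box(toy_spec(z), list(f_index = 3, t_index = 4,
                                     peak_power = 9), 4)
  expect_equal(unname(box3), c(3, 3, 4, 4))
})

test_that("merging follows the strict min-area overlap rule", {
  mk <- function(t1, t2, f1, f2)
    data.frame(t_start = t1, t_stop = t2, minF = f1, maxF = f2,
               t_peak = (t1 + t2) / 2, peakF = (f1 + f2) / 2,
               peak_power = 10)
  # disjoint boxes unchanged
  ev <- rbind(mk(0, 1, 5, 6), mk(2, 3, 5, 6))
  expect_equal(nrow(merge_events(ev, 0.5)), 2)
  # identical duplicates collapse (overlap = 100% of min area)
  ev2 <- rbind(mk(0, 4, 5, 7), mk(0, 4, 5, 7))
  expect_equal(nrow(merge_events(ev2, 0.5)), 1)
  # overlap exactly = 50% of min area: NOT merged (strict inequality)
  ev3 <- rbind(mk(0, 4, 0, 2), mk(2, 6, 0, 2))   # intersection 2x2 = 8/2... areas 8, overlap 4
  expect_equal(nrow(merge_events(ev3, 0.5)), 2)
  # slightly more than 50%: merged, union box, higher-power peak kept
  ev4 <- rbind(mk(0, 4, 0, 2), mk(1.9, 5.9, 0, 2))
  ev4$peak_power <- c(12, 10); ev4$peakF <- c(1.0, 1.5)
  out <- merge_events(ev4, 0.5)
  expect_equal(nrow(out), 1)
  expect_equal(out$t_start, 0)
  expect_equal(out$t_stop, 5.9)
  expect_equal(out$peakF, 1.0)       # from the higher-power constituent
  expect_equal(out$peak_power, 12)
})

test_that("merging is idempotent and reaches a fixed point", {
  set.seed(8)
  t1 <- runif(30, 0, 20)
  ev <- data.frame(t_start = t1, t_stop = t1 + runif(30, 0.5, 3),
                   minF = 8, maxF = 12, t_peak = t1, peakF = 10,
                   peak_power = runif(30, 4, 20))
  m1 <- merge_events(ev, 0.5)
  m2 <- merge_events(m1, 0.5)
  expect_equal(m1, m2, ignore_attr = TRUE)
})

test_that("a strong sinusoid burst yields one alpha event containing its peak", {
  set.seed(9)
  rec <- gen_background(10, 500, scale = 0.3, seed = 9)
  emb <- embed_burst(rec, 10, 40, 3, t_start = 2)   # 4-s strong burst
  ev <- detect(emb$recording, params = alpha_params(), analysis_fs = 500)
  hits <- ev[ev$band == "alpha" & ev$t_start < 6 & ev$t_stop > 2, ]
  expect_equal(nrow(hits), 1)
  expect_equal(hits$peakF, 10, tolerance = 0.06)
  # the box contains its generating peak; peak_power is the box maximum
  expect_true(hits$t_start <= hits$t_peak && hits$t_peak <= hits$t_stop)
  expect_true(hits$minF <= hits$peakF && hits$peakF <= hits$maxF)
})

test_that("flood-fill boxes cover at least the axis-walk box", {
  rec <- gen_background(10, 500, scale = 0.3, seed = 14)
  emb <- embed_burst(rec, 10, 20, 3, t_start = 3)
  spec <- normalize_by_median(morlet_power(emb$recording,
                                           params = alpha_params()))
  pk <- find_peaks(spec, 4)
  pk <- pk[which.max(pk$peak_power), ]
  ax <- grow_box(spec, pk, 4)
  fl <- oscevents:::grow_box_flood(spec, pk, 4)
  expect_lte(fl["f_lo"], ax["f_lo"])
  expect_gte(fl["f_hi"], ax["f_hi"])
  expect_lte(fl["t_lo"], ax["t_lo"])
  expect_gte(fl["t_hi"], ax["t_hi"])
})

test_that("all-zero signals produce an empty event table", {
  rec <- recording(rep(0, 5000), fs = 500)
  ev <- detect(rec, params = alpha_params(), analysis_fs = 500)
  expect_equal(nrow(ev), 0)
})

test_that("event identities hold for every detected event", {
  rec <- gen_background(20, 500, seed = 10)
  ev <- detect(rec, params = alpha_params(), analysis_fs = 500)
  expect_gt(nrow(ev), 0)
  expect_equal(ev$duration, ev$t_stop - ev$t_start)
  expect_equal(ev$n_cycles, ev$duration * ev$peakF)
  expect_equal(ev$Fspan, log(ev$maxF / ev$minF))
  expect_true(all(ev$t_start <= ev$t_peak & ev$t_peak <= ev$t_stop))
  expect_true(all(ev$minF <= ev$peakF & ev$peakF <= ev$maxF))
  expect_true(all(ev$peak_power > 4))
  expect_true(all(ev$filter_match >= -1 & ev$filter_match <= 1, na.rm = TRUE))
})

test_that("raising the threshold never increases the event count", {
  rec <- gen_background(20, 500, seed = 11)
  spec <- normalize_by_median(morlet_power(rec, params = alpha_params()))
  n <- vapply(c(4, 6, 8), function(th) nrow(find_peaks(spec, th)), 0)
  expect_true(all(diff(n) <= 0))
})

test_that("event tables round-trip through CSV with the fixed column set", {
  rec <- gen_background(10, 500, seed = 12)
  emb <- embed_burst(rec, 10, 8, 1.5, t_start = 3)
  ev <- detect(emb$recording, params = alpha_params(), analysis_fs = 500)
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  hdr <- names(utils::read.csv(path, nrows = 1))
  expect_equal(hdr, c("id", "channel", "window", "t_start", "t_stop",
                      "t_peak", "minF", "maxF", "peakF", "peak_power",
                      "duration", "n_cycles", "Fspan", "band",
                      "filter_match", "n_peaks", "n_troughs", "erp_score",
                      "flag_erp", "flag_broadband"))
  back <- read_events(path)
  expect_equal(back$n_cycles, ev$n_cycles)
})
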