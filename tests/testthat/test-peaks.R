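test_that("worked peak examples match the brute-force definition", {
  tr <- as_trace_1hz(c(0, 50, 0))
  pk <- find_peaks(tr, 40, 20)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$height, 50)
  expect_equal(pk$prominence, 50)

  expect_equal(nrow(find_peaks(as_trace_1hz(c(0, 30, 0)), 40, 20)), 0)

  # the 45 mmHg peak has prominence 10 (saddle at 35) and is rejected
  tr3 <- as_trace_1hz(c(0, 45, 35, 50, 0))
  pk3 <- find_peaks(tr3, 40, 20)
  expect_equal(pk3$height, 50)
  expect_equal(pk3$prominence, 50)
  # lowering the prominence threshold recovers it with prominence 10
  pk3b <- find_peaks(tr3, 40, 5)
  expect_equal(pk3b$height, c(45, 50))
  expect_equal(pk3b$prominence, c(10, 50))
})

test_that("plateaus collapse to a single midpoint peak", {
  tr <- as_trace_1hz(c(0, 50, 50, 50, 0, 60, 60, 0))
  pk <- find_peaks(tr, 40, 20)
  expect_equal(pk$time_s, c(2, 5))       # floor midpoint of runs 2:4 and 6:7
  expect_equal(pk$height, c(50, 60))
})

test_that("edge samples are never peaks and short traces error", {
  expect_equal(nrow(find_peaks(as_trace_1hz(c(80, 0, 0, 0, 90)), 40, 20)), 0)
  expect_error(find_peaks(as_trace_1hz(c(0, 50)), 40, 20), "3 samples")
  tr10 <- pressure_trace("a", "g", seq(0, 2, by = 0.1), rep(1, 21), 10)
  expect_error(find_peaks(tr10, 40, 20), "1 Hz")
})

test_that("detector matches the O(n^2) oracle on random traces", {
  set.seed(101)
  for (rep in 1:300) {
    n <- sample(10:500, 1)
    x <- random_trace(n, quantize = rep %% 2 == 0)
    mh <- sample(c(30, 40, 50), 1)
    mp <- sample(c(5, 10, 20), 1)
    got <- find_peaks(as_trace_1hz(x), mh, mp)
    want <- oracle_peaks(x, mh, mp)
    expect_equal(got$time_s, want$index - 1)
    expect_equal(got$height, want$height)
    expect_equal(got$prominence, want$prominence)
  }
})

test_that("raising either threshold never adds peaks", {
  set.seed(55)
  for (rep in 1:40) {
    x <- random_trace(sample(50:300, 1), quantize = rep %% 3 == 0)
    tr <- as_trace_1hz(x)
    base <- find_peaks(tr, 35, 10)
    higher_h <- find_peaks(tr, 45, 10)
    higher_p <- find_peaks(tr, 35, 25)
    expect_true(all(higher_h$time_s %in% base$time_s))
    expect_true(all(higher_p$time_s %in% base$time_s))
    expect_lte(nrow(higher_h), nrow(base))
    expect_lte(nrow(higher_p), nrow(base))
  }
})

test_that("peaks in interpolated dropout spans are suppressed", {
  x <- c(rep(5, 10), 0, 50, 0, rep(5, 10))
  tr <- pressure_trace("a", "g", seq_along(x) - 1, x, 1,
                       interpolated = seq_along(x) == 12)
  expect_equal(nrow(find_peaks(tr, 40, 20)), 0)
  tr2 <- pressure_trace("a", "g", seq_along(x) - 1, x, 1)
  expect_equal(nrow(find_peaks(tr2, 40, 20)), 1)
})

test_that("onset-referenced windows partition detected peaks", {
  rec <- delivery_record("m1", "ctrl", c(120, 130, 150))  # onset 120 min
  onset_s <- 120 * 60
  peaks <- data.frame(time_s = c(onset_s - 3000, onset_s + 1800,
                                 onset_s + 7200, onset_s + 9000),
                      height = c(55, 60, 70, 80),
                      prominence = c(50, 55, 65, 75))
  pre <- window_peaks(peaks, rec, "pre_labor", recording_start = 0)
  post <- window_peaks(peaks, rec, "post_onset_2h")
  late <- window_peaks(peaks, rec, "beyond_2h", recording_end = Inf)
  expect_equal(pre$peaks$time_s, onset_s - 3000)
  expect_equal(post$peaks$time_s, onset_s + 1800)     # +150 min is outside
  # a peak exactly at onset + 2 h belongs to the later window (half-open)
  expect_equal(late$peaks$time_s, c(onset_s + 7200, onset_s + 9000))

  # partition property on random peak lists
  set.seed(7)
  for (i in 1:25) {
    pk <- data.frame(time_s = sort(stats::runif(40, 0, 6e4)),
                     height = stats::runif(40, 40, 100),
                     prominence = stats::runif(40, 20, 80))
    parts <- lapply(c("pre_labor", "post_onset_2h", "beyond_2h"),
                    function(w) window_peaks(pk, rec, w, recording_start = 0,
                                             recording_end = Inf)$peaks$time_s)
    expect_equal(sort(unlist(parts)), sort(pk$time_s))
    expect_true(all(parts[[1]] < onset_s))
    expect_true(all(parts[[2]] >= onset_s & parts[[2]] < onset_s + 7200))
  }
})

test_that("empty windows are empty peak sets, not errors", {
  rec <- delivery_record("m1", "ctrl", 120)
  pk <- data.frame(time_s = numeric(0), height = numeric(0),
                   prominence = numeric(0))
  ps <- window_peaks(pk, rec, "post_onset_2h")
  expect_s3_class(ps, "peak_set")
  expect_equal(nrow(ps$peaks), 0)
  # onset-referenced window without deliveries errors
  rec0 <- delivery_record("m2", "ko", numeric(0))
  expect_error(window_peaks(pk, rec0, "post_onset_2h"), "no deliveries")
})

test_that("animal summaries compute the windowed means and onset flag", {
  rec <- delivery_record("m1", "ctrl", c(120, 130, 150))
  pk <- data.frame(time_s = 120 * 60 + c(600, 1200), height = c(60, 80),
                   prominence = c(55, 75))
  ps <- window_peaks(pk, rec, "post_onset_2h")
  s <- summarize_animal(ps, rec, d_drg = 0, d_uterus = 1)
  expect_equal(s$mean_peak_pressure, 70)
  expect_equal(s$n_peaks, 2)
  expect_equal(s$mean_interpup_interval, 15)   # gaps 10 and 20 min
  expect_equal(s$onset_zt, 2)
  expect_false(s$onset_after_zt3)

  # single pup: interval undefined, onset still defined
  rec1 <- delivery_record("m2", "ko", 200)
  ps1 <- window_peaks(pk, rec1, "post_onset_2h")
  s1 <- summarize_animal(ps1, rec1)
  expect_true(is.na(s1$mean_interpup_interval))
  expect_equal(s1$onset_zt, 200 / 60)
  expect_true(s1$onset_after_zt3)

  # no peaks in window: mean pressure missing, not an error
  ps2 <- window_peaks(pk[0, ], rec, "post_onset_2h")
  expect_true(is.na(summarize_animal(ps2, rec)$mean_peak_pressure))
})

test_that("well-separated synthetic transients are all recovered", {
  # every interior ground-truth transient (at least 5 widths from the trace
  # edges, so its geometry is untruncated) must be detected, with no
  # spurious detections; edge-clipped transients may legitimately fall below
  # the prominence criterion
  hits <- vapply(1:100, function(s) {
    cfg <- cohort_config(n_per_group = 1, duration = 3, raw_sample_rate = 1,
                         group_defs = data.frame(label = "g", d_drg = 0L,
                                                 d_uterus = 0L),
                         peak_amp_mean = 100, peak_amp_sd = 5,
                         baseline_noise_sd = 1,
                         prelabor_event_rate = 6, postonset_event_rate = 6,
                         onset_zt_mean = 1.5, onset_zt_sd = 0.2, seed = s)
    raw <- generate_pressure_trace(cfg, 1)
    tr <- resample_1hz(raw)
    truth <- attr(raw, "ground_truth")$time_s
    margin <- 5 * cfg$peak_width_sd
    interior <- truth[truth > margin & truth < 3 * 3600 - margin]
    det <- find_peaks(tr, 40, 20)$time_s
    all_found <- all(vapply(interior, function(t0)
      any(abs(det - t0) <= 6), logical(1)))
    none_spurious <- all(vapply(det, function(t0)
      any(abs(truth - t0) <= 6), logical(1)))
    all_found && none_spurious
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
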