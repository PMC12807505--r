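test_that("config validation rejects malformed cohorts", {
  expect_error(cohort_config(peak_width_sd = -1), "positive")
  expect_error(cohort_config(raw_sample_rate = 0.5), "1 Hz")
  expect_error(cohort_config(n_pups_range = c(3, 1)), "ascending")
  expect_error(cohort_config(postonset_event_rate = c(NA, 1, 1, 1)), "finite")
  bad_defs <- data.frame(label = "g", d_drg = 2L, d_uterus = 0L)
  expect_error(cohort_config(group_defs = bad_defs), "0 or 1")
})

test_that("a forced noise-free transient reproduces its amplitude exactly", {
  cfg <- cohort_config(n_per_group = 1, baseline_pressure = 0,
                       baseline_noise_sd = 0, duration = 4, seed = 5)
  tr <- generate_pressure_trace(cfg, 1, event_times = 3600, event_amps = 80)
  expect_equal(max(tr$pressure), 80)
  expect_equal(min(tr$pressure), 0)
  apex <- which.max(tr$pressure)
  expect_equal(tr$timestamps[apex], 3600)
})

test_that("trace and schedule generation are deterministic under a seed", {
  cfg <- cohort_config(n_per_group = c(2, 2, 2, 2), duration = 3, seed = 42)
  t1 <- generate_pressure_trace(cfg, 3)
  t2 <- generate_pressure_trace(cfg, 3)
  expect_identical(t1$pressure, t2$pressure)
  expect_identical(attr(t1, "ground_truth"), attr(t2, "ground_truth"))
  d1 <- generate_delivery_events(cfg, 3)
  d2 <- generate_delivery_events(cfg, 3)
  expect_identical(d1$delivery_times, d2$delivery_times)
  # event generation does not depend on whether the trace was drawn first
  cfg2 <- cohort_config(n_per_group = c(2, 2, 2, 2), duration = 3, seed = 42)
  d3 <- generate_delivery_events(cfg2, 3)
  expect_identical(d1$delivery_times, d3$delivery_times)
})

test_that("cohort files are byte-identical for identical config and seed", {
  cfg <- cohort_config(n_per_group = c(2, 2), duration = 2, seed = 9,
                       group_defs = data.frame(
                         label = c("control", "combined_ko"),
                         d_drg = c(0L, 1L), d_uterus = c(0L, 1L)))
  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  generate_cohort(cfg, d1)
  generate_cohort(cfg, d2)
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("simulated transient amplitudes obey the configured law", {
  # law-of-large-numbers check on the generator's amplitude stream
  cfg <- cohort_config(n_per_group = 60, duration = 4, raw_sample_rate = 1,
                       baseline_noise_sd = 0,
                       group_defs = data.frame(label = "g", d_drg = 0L,
                                               d_uterus = 0L),
                       peak_amp_mean = 60, peak_amp_sd = 10,
                       postonset_event_rate = 60, prelabor_event_rate = 60,
                       onset_zt_mean = 1, onset_zt_sd = 0, seed = 31)
  amps <- unlist(lapply(1:60, function(i)
    attr(generate_pressure_trace(cfg, i), "ground_truth")$amplitude))
  amps <- amps[seq_len(min(10000, length(amps)))]
  expect_gt(length(amps), 5000)
  se <- 10 / sqrt(length(amps))
  expect_lt(abs(mean(amps) - 60), 3 * se)
})

test_that("per-animal amplitude variance grows with the configured spread", {
  base <- function(s, seed) cohort_config(
    n_per_group = 16, duration = 4, raw_sample_rate = 1,
    group_defs = data.frame(label = "g", d_drg = 0L, d_uterus = 0L),
    peak_amp_mean = 100, peak_amp_sd = s, onset_zt_mean = 1,
    onset_zt_sd = 0.2, seed = seed)
  vars <- vapply(c(2, 10, 30), function(s) {
    cfg <- base(s, 77)
    means <- vapply(1:16, function(i)
      mean(attr(generate_pressure_trace(cfg, i), "ground_truth")$amplitude),
      numeric(1))
    stats::var(means)
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})

test_that("delivery schedules honour degenerate interval settings", {
  cfg <- cohort_config(n_per_group = 1, duration = 8,
                       group_defs = data.frame(label = "g", d_drg = 0L,
                                               d_uterus = 0L),
                       interpup_interval_mean = 10, interpup_interval_sd = 0,
                       n_pups_range = c(5, 5), onset_zt_mean = 2,
                       onset_zt_sd = 0, seed = 3)
  rec <- generate_delivery_events(cfg, 1)
  expect_length(rec$delivery_times, 5)
  expect_equal(diff(rec$delivery_times), rep(10, 4))
  expect_equal(rec$first_pup_time, 120)

  cfg1 <- cohort_config(n_per_group = 1, duration = 8,
                        group_defs = data.frame(label = "g", d_drg = 0L,
                                                d_uterus = 0L),
                        n_pups_range = c(1, 1), seed = 3)
  rec1 <- generate_delivery_events(cfg1, 1)
  expect_length(rec1$delivery_times, 1)
})

test_that("onset times concentrate on the configured distribution", {
  cfg <- cohort_config(n_per_group = 1000, duration = 8,
                       group_defs = data.frame(label = "g", d_drg = 0L,
                                               d_uterus = 0L),
                       onset_zt_mean = 2, onset_zt_sd = 0.5, seed = 19)
  onsets <- vapply(1:1000, function(i)
    generate_delivery_events(cfg, i)$first_pup_time / 60, numeric(1))
  se <- 0.5 / sqrt(1000)
  expect_lt(abs(mean(onsets) - 2), 3 * se)
})

test_that("animal_index outside the cohort is rejected", {
  cfg <- cohort_config(n_per_group = c(2, 2, 2, 2), duration = 2, seed = 1)
  expect_error(generate_pressure_trace(cfg, 9), "exceeds cohort size")
  expect_error(generate_delivery_events(cfg, 0), "positive")
})

test_that("non-responsive sweeps stay within Gaussian noise bounds", {
  sc <- sweep_config(baseline_current_sd = 1, seed = 8)
  sw <- generate_sweep(sc, depth = 5, responsive = FALSE)
  expect_gt(length(sw$current), 4000)
  expect_true(all(abs(sw$current - sc$baseline_current) <= 6))
})

test_that("responsive sweeps carry the configured inward deflection", {
  sc <- sweep_config(baseline_current_sd = 1, depths = c(2, 5),
                     response_amplitude = c(50, 200), seed = 21)
  sw <- generate_sweep(sc, depth = 5, responsive = TRUE)
  hold <- sw$time >= sc$stimulus_onset + 5 &
    sw$time <= sc$stimulus_onset + 5 + sc$hold_duration
  expect_lt(abs(min(sw$current[hold]) - (sc$baseline_current - 200)), 5)
  # determinism
  sw2 <- generate_sweep(sc, depth = 5, responsive = TRUE)
  expect_identical(sw$current, sw2$current)
})

test_that("sweep config invariants are enforced", {
  expect_error(sweep_config(depths = c(3, 1)), "ascending")
  expect_error(sweep_config(stimulus_onset = 20), "35 ms")
  sc <- sweep_config()
  expect_error(generate_sweep(sc, depth = 99), "one of config")
})
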