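# Synthetic cohort generator: intrauterine-pressure traces, delivery events,
# and patch-clamp sweeps with the statistical structure the downstream
# analysis assumes. Fully seeded; identical config + seed reproduces output
# byte for byte.

#' Cohort configuration for the synthetic-data generator
#'
#' Describes a four-group telemetry cohort (control, uterus-specific knockout,
#' DRG-specific knockout, combined knockout by default). Per-group vectors are
#' recycled to the number of groups. Contraction transients are Gaussian bumps
#' whose centres follow an inhomogeneous Poisson process: a sparse pre-labor
#' rate switching to a group-dependent post-onset rate at the animal's labor
#' onset. Transient amplitudes are Normal per group, truncated below at zero.
#'
#' @param n_per_group integer vector, animals per group.
#' @param group_defs data.frame with columns `label`, `d_drg`, `d_uterus`
#'   (0/1 indicators). Default mirrors the four-arm knockout design.
#' @param baseline_pressure resting intrauterine pressure, mmHg.
#' @param baseline_noise_sd Gaussian sensor noise SD, mmHg.
#' @param prelabor_event_rate contraction events per hour before labor onset.
#' @param postonset_event_rate events per hour after onset, per group.
#' @param peak_amp_mean mean transient amplitude per group, mmHg (above
#'   baseline).
#' @param peak_amp_sd per-transient amplitude SD per group, mmHg.
#' @param peak_width_sd Gaussian transient width parameter, seconds.
#' @param n_pups_range integer length-2 vector, inclusive range of litter size.
#' @param interpup_interval_mean mean gap between successive pups, minutes,
#'   per group.
#' @param interpup_interval_sd SD of the inter-pup gap, minutes, per group.
#'   Gaps are Gamma-distributed with this mean/SD (degenerate at the mean when
#'   the SD is zero), so they are strictly positive.
#' @param onset_zt_mean,onset_zt_sd labor-onset time distribution, hours ZT,
#'   per group. Draws are clamped to keep the pre-labor and 2-h post-onset
#'   windows inside the recording.
#' @param raw_sample_rate telemetry sampling rate, Hz (>= 1).
#' @param duration recording length, hours.
#' @param seed integer master seed; every animal derives private substreams.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(8L, 7L, 6L, 8L),
                          group_defs = data.frame(
                            label = c("control", "uterus_ko", "drg_ko",
                                      "combined_ko"),
                            d_drg = c(0L, 0L, 1L, 1L),
                            d_uterus = c(0L, 1L, 0L, 1L)),
                          baseline_pressure = 5,
                          baseline_noise_sd = 1.5,
                          prelabor_event_rate = 3,
                          postonset_event_rate = c(30, 26, 22, 18),
                          peak_amp_mean = c(150, 133.99, 102.89, 86.88),
                          peak_amp_sd = c(8, 10, 12, 14),
                          peak_width_sd = 15,
                          n_pups_range = c(5L, 9L),
                          interpup_interval_mean = c(10, 13, 11, 25),
                          interpup_interval_sd = c(4, 5, 4, 10),
                          onset_zt_mean = c(1.5, 2.0, 3.0, 3.2),
                          onset_zt_sd = c(0.6, 0.8, 1.0, 1.2),
                          raw_sample_rate = 2,
                          duration = 8,
                          seed = 1L) {
  k <- nrow(group_defs)
  if (k < 1L) stop("group_defs must define at least one group")
  if (!all(c("label", "d_drg", "d_uterus") %in% names(group_defs)))
    stop("group_defs needs columns label, d_drg, d_uterus")
  if (!all(unlist(group_defs[c("d_drg", "d_uterus")]) %in% c(0, 1)))
    stop("knockout indicators must be 0 or 1")
  rec <- function(x, nm) {
    if (!is.numeric(x) || !all(is.finite(x)))
      stop(sprintf("'%s' must be finite numeric", nm), call. = FALSE)
    rep_len(x, k)
  }
  cfg <- list(
    n_per_group = as.integer(rep_len(n_per_group, k)),
    group_defs = group_defs,
    baseline_pressure = stopifnot_scalar(baseline_pressure,
                                         "baseline_pressure"),
    baseline_noise_sd = stopifnot_scalar(baseline_noise_sd,
                                         "baseline_noise_sd"),
    prelabor_event_rate = stopifnot_scalar(prelabor_event_rate,
                                           "prelabor_event_rate",
                                           positive = TRUE),
    postonset_event_rate = rec(postonset_event_rate, "postonset_event_rate"),
    peak_amp_mean = rec(peak_amp_mean, "peak_amp_mean"),
    peak_amp_sd = rec(peak_amp_sd, "peak_amp_sd"),
    peak_width_sd = stopifnot_scalar(peak_width_sd, "peak_width_sd",
                                     positive = TRUE),
    n_pups_range = as.integer(n_pups_range),
    interpup_interval_mean = rec(interpup_interval_mean,
                                 "interpup_interval_mean"),
    interpup_interval_sd = rec(interpup_interval_sd, "interpup_interval_sd"),
    onset_zt_mean = rec(onset_zt_mean, "onset_zt_mean"),
    onset_zt_sd = rec(onset_zt_sd, "onset_zt_sd"),
    raw_sample_rate = stopifnot_scalar(raw_sample_rate, "raw_sample_rate",
                                       positive = TRUE),
    duration = stopifnot_scalar(duration, "duration", positive = TRUE),
    seed = as.integer(stopifnot_scalar(seed, "seed", integerish = TRUE))
  )
  if (any(cfg$n_per_group < 1L)) stop("n_per_group must be >= 1")
  if (any(cfg$postonset_event_rate <= 0) || any(cfg$peak_amp_sd < 0) ||
      any(cfg$interpup_interval_mean <= 0) || any(cfg$interpup_interval_sd < 0) ||
      any(cfg$onset_zt_sd < 0))
    stop("rates and dispersion parameters must be positive (SDs >= 0)")
  if (length(cfg$n_pups_range) != 2L || cfg$n_pups_range[1] < 1L ||
      diff(cfg$n_pups_range) < 0)
    stop("n_pups_range must be an ascending integer pair >= 1")
  if (cfg$raw_sample_rate < 1) stop("raw_sample_rate must be >= 1 Hz")
  structure(cfg, class = "cohort_config")
}

# group index and ids for each animal in the cohort
cohort_roster <- function(config) {
  g <- rep(seq_len(nrow(config$group_defs)), config$n_per_group)
  within_grp <- sequence(config$n_per_group)
  data.frame(
    animal_index = seq_along(g),
    animal_id = sprintf("%s_%02d", config$group_defs$label[g], within_grp),
    group = config$group_defs$label[g],
    group_index = g,
    d_drg = config$group_defs$d_drg[g],
    d_uterus = config$group_defs$d_uterus[g],
    stringsAsFactors = FALSE
  )
}

check_animal_index <- function(config, animal_index) {
  n_total <- sum(config$n_per_group)
  stopifnot_scalar(animal_index, "animal_index", positive = TRUE,
                   integerish = TRUE)
  if (animal_index > n_total)
    stop(sprintf("animal_index %d exceeds cohort size %d", animal_index,
                 n_total), call. = FALSE)
  invisible(animal_index)
}

# The labor schedule (onset ZT, litter size, inter-pup gaps) has its own
# substream so that trace and event generation agree on the onset no matter
# which is called first. Onset is clamped so the recording always contains a
# pre-labor stretch and the full 2-hour post-onset window.
draw_labor_schedule <- function(config, animal_index) {
  roster <- cohort_roster(config)
  g <- roster$group_index[animal_index]
  with_seed(mix_seed(config$seed, animal_index, 1L), {
    onset_zt <- stats::rnorm(1, config$onset_zt_mean[g], config$onset_zt_sd[g])
    onset_zt <- min(max(onset_zt, 0.5), max(config$duration - 3, 0.5))
    n_pups <- if (diff(config$n_pups_range) == 0L) config$n_pups_range[1]
      else sample(config$n_pups_range[1]:config$n_pups_range[2], 1)
    m <- config$interpup_interval_mean[g]
    s <- config$interpup_interval_sd[g]
    gaps <- if (n_pups < 2L) numeric(0)
      else if (s == 0) rep(m, n_pups - 1L)
      else stats::rgamma(n_pups - 1L, shape = (m / s)^2, rate = m / s^2)
    list(group_index = g, onset_zt = onset_zt, n_pups = n_pups, gaps = gaps)
  })
}

#' Generate one animal's synthetic intrauterine-pressure trace
#'
#' Baseline + Gaussian noise + a sum of Gaussian contraction transients.
#' Transient centres follow an inhomogeneous Poisson process whose rate
#' switches from `prelabor_event_rate` to the group's `postonset_event_rate`
#' at the animal's labor onset; centres closer than `3 * peak_width_sd` to the
#' previous kept centre are thinned so ground-truth peaks stay resolvable at
#' 1 Hz. Amplitudes are Normal per group, truncated below at zero.
#'
#' @param config a [cohort_config()].
#' @param animal_index 1-based index into the cohort roster.
#' @param event_times optional numeric vector (seconds) overriding the Poisson
#'   draw, for controlled constructions.
#' @param event_amps optional amplitudes (mmHg) paired with `event_times`.
#' @return A [pressure_trace()] with attributes `ground_truth` (data.frame of
#'   transient times and amplitudes) and `onset_zt` (hours).
#' @export
generate_pressure_trace <- function(config, animal_index,
                                    event_times = NULL, event_amps = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  check_animal_index(config, animal_index)
  roster <- cohort_roster(config)
  sched <- draw_labor_schedule(config, animal_index)
  g <- sched$group_index
  dur_s <- config$duration * 3600
  onset_s <- sched$onset_zt * 3600
  w <- config$peak_width_sd
  min_gap <- 3 * w

  with_seed(mix_seed(config$seed, animal_index, 2L), {
    if (is.null(event_times)) {
      draw_pp <- function(rate_per_h, t0, t1) {
        if (t1 <= t0) return(numeric(0))
        lam <- rate_per_h / 3600
        n <- stats::rpois(1, lam * (t1 - t0))
        sort(stats::runif(n, t0, t1))
      }
      ev <- c(draw_pp(config$prelabor_event_rate, 0, onset_s),
              draw_pp(config$postonset_event_rate[g], onset_s, dur_s))
      # dead-time thinning: keep an event only if >= 3*width from last kept
      if (length(ev) > 1L) {
        keep <- logical(length(ev)); last <- -Inf
        for (i in seq_along(ev)) {
          if (ev[i] - last >= min_gap) { keep[i] <- TRUE; last <- ev[i] }
        }
        ev <- ev[keep]
      }
      amps <- pmax(stats::rnorm(length(ev), config$peak_amp_mean[g],
                                config$peak_amp_sd[g]), 0)
    } else {
      ev <- as.numeric(event_times)
      amps <- if (is.null(event_amps))
        pmax(stats::rnorm(length(ev), config$peak_amp_mean[g],
                          config$peak_amp_sd[g]), 0)
      else rep_len(as.numeric(event_amps), length(ev))
    }

    ts <- seq(0, dur_s, by = 1 / config$raw_sample_rate)
    pr <- rep(config$baseline_pressure, length(ts))
    if (config$baseline_noise_sd > 0)
      pr <- pr + stats::rnorm(length(ts), 0, config$baseline_noise_sd)
    for (i in seq_along(ev)) {
      lo <- max(1L, ceiling((ev[i] - 5 * w) * config$raw_sample_rate) + 1L)
      hi <- min(length(ts), floor((ev[i] + 5 * w) * config$raw_sample_rate) + 1L)
      if (hi >= lo) {
        idx <- lo:hi
        pr[idx] <- pr[idx] + amps[i] * exp(-(ts[idx] - ev[i])^2 / (2 * w^2))
      }
    }
    tr <- pressure_trace(roster$animal_id[animal_index],
                         roster$group[animal_index],
                         ts, pr, config$raw_sample_rate)
    attr(tr, "ground_truth") <- data.frame(time_s = ev, amplitude = amps)
    attr(tr, "onset_zt") <- sched$onset_zt
    tr
  })
}

#' Generate one animal's synthetic delivery-event record
#'
#' Labor onset is drawn from the group's onset distribution and successive
#' inter-pup gaps from the group's Gamma interval distribution; timestamps are
#' rounded to whole minutes, matching the 1-minute annotation accuracy of
#' video-scored deliveries.
#'
#' @inheritParams generate_pressure_trace
#' @return a [delivery_record()].
#' @export
generate_delivery_events <- function(config, animal_index) {
  stopifnot(inherits(config, "cohort_config"))
  check_animal_index(config, animal_index)
  roster <- cohort_roster(config)
  sched <- draw_labor_schedule(config, animal_index)
  times_min <- round(sched$onset_zt * 60 + cumsum(c(0, sched$gaps)))
  delivery_record(roster$animal_id[animal_index], roster$group[animal_index],
                  delivery_times = times_min,
                  completed_by_gd20 = times_min[length(times_min)] <=
                    config$duration * 60)
}

#' Sweep configuration for synthetic patch-clamp recordings
#'
#' Mechanical indentation protocol: probe advanced at `ramp_speed` and held at
#' the target depth for `hold_duration` (125 ms by default, the standard
#' whole-cell poking protocol).
#'
#' @param sample_rate acquisition rate, Hz.
#' @param stimulus_onset probe-movement start, ms (>= 35 ms so the baseline
#'   window fits).
#' @param hold_duration hold at target depth, ms.
#' @param ramp_speed probe speed, micrometres per ms.
#' @param baseline_current_sd Gaussian current-noise SD, pA.
#' @param baseline_current holding current level, pA.
#' @param depths ascending non-negative indentation depths, micrometres.
#' @param response_amplitude evoked inward-current magnitude (pA, positive
#'   number) per depth.
#' @param tail_duration recording time after the hold ends, ms.
#' @param seed integer seed.
#' @return object of class `sweep_config`.
#' @export
sweep_config <- function(sample_rate = 20000,
                         stimulus_onset = 50,
                         hold_duration = 125,
                         ramp_speed = 1,
                         baseline_current_sd = 5,
                         baseline_current = -20,
                         depths = c(1, 2, 3, 4, 5, 6),
                         response_amplitude = c(0, 15, 60, 150, 300, 480),
                         tail_duration = 50,
                         seed = 1L) {
  stopifnot_scalar(sample_rate, "sample_rate", positive = TRUE)
  stopifnot_scalar(stimulus_onset, "stimulus_onset", positive = TRUE)
  stopifnot_scalar(hold_duration, "hold_duration", positive = TRUE)
  stopifnot_scalar(ramp_speed, "ramp_speed", positive = TRUE)
  stopifnot_scalar(baseline_current_sd, "baseline_current_sd")
  if (baseline_current_sd < 0) stop("baseline_current_sd must be >= 0")
  if (stimulus_onset < 35)
    stop("stimulus_onset must be >= 35 ms so the baseline window fits")
  depths <- as.numeric(depths)
  if (any(depths < 0) || is.unsorted(depths, strictly = TRUE))
    stop("depths must be non-negative and strictly ascending")
  structure(list(
    sample_rate = sample_rate, stimulus_onset = stimulus_onset,
    hold_duration = hold_duration, ramp_speed = ramp_speed,
    baseline_current_sd = baseline_current_sd,
    baseline_current = baseline_current,
    depths = depths,
    response_amplitude = rep_len(as.numeric(response_amplitude),
                                 length(depths)),
    tail_duration = stopifnot_scalar(tail_duration, "tail_duration",
                                     positive = TRUE),
    seed = as.integer(stopifnot_scalar(seed, "seed", integerish = TRUE))
  ), class = "sweep_config")
}

#' Generate a synthetic patch-clamp sweep
#'
#' Gaussian current noise throughout; when `responsive`, an inward (negative)
#' deflection of the depth's configured amplitude rises linearly during the
#' probe ramp, persists through the hold window, and relaxes exponentially
#' (5 ms time constant) after the hold ends.
#'
#' @param config a [sweep_config()].
#' @param depth one of `config$depths`, micrometres.
#' @param responsive logical; inject the evoked current?
#' @param sweep_index integer; decouples the noise stream of repeated sweeps.
#' @return a [sweep_record()].
#' @export
generate_sweep <- function(config, depth, responsive = TRUE,
                           sweep_index = 1L) {
  stopifnot(inherits(config, "sweep_config"))
  di <- match(depth, config$depths)
  if (is.na(di)) stop("depth must be one of config$depths")
  ramp_t <- depth / config$ramp_speed
  dur <- config$stimulus_onset + ramp_t + config$hold_duration +
    config$tail_duration
  dt <- 1000 / config$sample_rate                     # ms per sample
  tm <- seq(0, dur, by = dt)
  with_seed(mix_seed(config$seed, sweep_index, 3L + di), {
    cur <- rep(config$baseline_current, length(tm))
    if (config$baseline_current_sd > 0)
      cur <- cur + stats::rnorm(length(tm), 0, config$baseline_current_sd)
    if (isTRUE(responsive) && config$response_amplitude[di] > 0) {
      amp <- config$response_amplitude[di]
      t0 <- config$stimulus_onset
      t1 <- t0 + ramp_t
      t2 <- t1 + config$hold_duration
      shape <- numeric(length(tm))
      shape[tm >= t0 & tm < t1] <- (tm[tm >= t0 & tm < t1] - t0) /
        max(ramp_t, dt)
      shape[tm >= t1 & tm <= t2] <- 1
      post <- tm > t2
      shape[post] <- exp(-(tm[post] - t2) / 5)
      cur <- cur - amp * shape
    }
    sweep_record(time = tm, current = cur,
                 stimulus_onset = config$stimulus_onset,
                 hold_duration = config$hold_duration, depth = depth,
                 sample_rate = config$sample_rate)
  })
}

#' Write a full synthetic cohort to disk
#'
#' Emits one telemetry file and one shared events file per the delimited
#' dialects documented in [read_trace()]/[read_events()], plus a cohort
#' manifest (`manifest.csv`) listing animals, groups, indicators, and file
#' paths. Deterministic: the same config (including seed) yields
#' byte-identical files.
#'
#' @param config a [cohort_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
generate_cohort <- function(config, outdir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  roster <- cohort_roster(config)
  ev_rows <- vector("list", nrow(roster))
  trace_files <- character(nrow(roster))
  for (i in roster$animal_index) {
    tr <- generate_pressure_trace(config, i)
    trace_files[i] <- file.path(outdir, paste0(roster$animal_id[i],
                                               "_trace.csv"))
    write_trace(tr, trace_files[i])
    rec <- generate_delivery_events(config, i)
    ev_rows[[i]] <- data.frame(animal_id = rec$animal_id, group = rec$group,
                               event_type = "pup_delivery",
                               timestamp_min = rec$delivery_times,
                               stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev_rows)
  events_file <- file.path(outdir, "events.csv")
  utils::write.csv(events, events_file, row.names = FALSE, quote = FALSE)
  manifest <- data.frame(roster[c("animal_id", "group", "d_drg", "d_uterus")],
                         trace_file = basename(trace_files),
                         events_file = basename(events_file),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
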