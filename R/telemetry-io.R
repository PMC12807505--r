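# Telemetry I/O: delimited-text readers/writers, zeitgeber-time alignment,
# and 1 Hz bin-average resampling.
#
# Telemetry dialect (one file per animal):
#   header `timestamp_s,pressure_mmHg`, one sample per row, timestamps in
#   seconds since the recording's lights-on reference (ZT0).
# Events dialect (one file per cohort):
#   header `animal_id,group,event_type,timestamp_min`, timestamps in whole
#   minutes since ZT0.

#' Pressure-trace container
#'
#' One animal's intrauterine-pressure time series. Timestamps are seconds
#' since lights-on (ZT0); pressure is mmHg.
#'
#' @param animal_id identifier.
#' @param group treatment-group label.
#' @param timestamps strictly increasing numeric vector, seconds.
#' @param pressure numeric vector, mmHg, same length.
#' @param sample_rate nominal sampling rate, Hz.
#' @param interpolated optional logical vector flagging samples filled in over
#'   telemetry dropouts; such spans are excluded from peak statistics.
#' @return object of class `pressure_trace`.
#' @export
pressure_trace <- function(animal_id, group, timestamps, pressure,
                           sample_rate, interpolated = NULL) {
  timestamps <- as.numeric(timestamps)
  pressure <- as.numeric(pressure)
  if (length(timestamps) != length(pressure))
    stop("timestamps and pressure must have equal length")
  if (length(timestamps) == 0L) stop("empty trace")
  if (!all(is.finite(pressure)) || !all(is.finite(timestamps)))
    stop("trace values must be finite")
  bad <- which(diff(timestamps) <= 0)
  if (length(bad))
    stop(sprintf("timestamps not strictly increasing at row %d", bad[1] + 1L))
  if (is.null(interpolated)) interpolated <- rep(FALSE, length(timestamps))
  structure(list(animal_id = animal_id, group = group,
                 timestamps = timestamps, pressure = pressure,
                 sample_rate = sample_rate,
                 interpolated = as.logical(interpolated)),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf(
    "<pressure_trace> %s (%s): %d samples @ %g Hz, %.2f-%.2f h ZT\n",
    x$animal_id, x$group, length(x$pressure), x$sample_rate,
    x$timestamps[1] / 3600, x$timestamps[length(x$timestamps)] / 3600))
  invisible(x)
}

#' Delivery-event container
#'
#' Per-animal pup-delivery timestamps at whole-minute resolution, with the
#' derived labor-onset time (appearance of the first pup).
#'
#' @param animal_id identifier.
#' @param group treatment-group label.
#' @param delivery_times whole minutes since ZT0, ascending.
#' @param completed_by_gd20 logical flag.
#' @return object of class `delivery_record`.
#' @export
delivery_record <- function(animal_id, group, delivery_times,
                            completed_by_gd20 = TRUE) {
  delivery_times <- as.numeric(delivery_times)
  if (any(delivery_times != round(delivery_times)))
    stop("delivery_times must be whole minutes")
  delivery_times <- sort(delivery_times)
  structure(list(animal_id = animal_id, group = group,
                 delivery_times = delivery_times,
                 first_pup_time = if (length(delivery_times))
                   min(delivery_times) else NA_real_,
                 completed_by_gd20 = isTRUE(completed_by_gd20)),
            class = "delivery_record")
}

#' Read a telemetry trace from delimited text
#'
#' @param path file in the telemetry dialect (`timestamp_s,pressure_mmHg`).
#' @param animal_id identifier to attach.
#' @param group optional group label.
#' @param sample_rate optional nominal rate; inferred from the median
#'   timestamp step when omitted.
#' @return a [pressure_trace()].
#' @export
read_trace <- function(path, animal_id, group = NA_character_,
                       sample_rate = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_s", "pressure_mmHg")
  if (!all(need %in% names(df)))
    stop(sprintf("format error in %s: need columns %s", path,
                 paste(need, collapse = ", ")))
  bad <- which(!is.finite(df$timestamp_s) | !is.finite(df$pressure_mmHg))
  if (length(bad))
    stop(sprintf("unparseable rows in %s at data line(s): %s", path,
                 paste(utils::head(bad, 5), collapse = ", ")))
  nonmono <- which(diff(df$timestamp_s) <= 0)
  if (length(nonmono))
    stop(sprintf("data error in %s: timestamps not increasing at data line %d",
                 path, nonmono[1] + 1L))
  if (is.null(sample_rate)) {
    dt <- stats::median(diff(df$timestamp_s))
    sample_rate <- 1 / dt
  }
  pressure_trace(animal_id, group, df$timestamp_s, df$pressure_mmHg,
                 sample_rate)
}

#' Write a telemetry trace as delimited text
#'
#' Fixed-precision formatting (ms timestamps, 1e-6 mmHg) so that identical
#' traces serialize byte-identically and round-trip losslessly at the printed
#' precision.
#'
#' @param trace a [pressure_trace()].
#' @param path output file.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pressure_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("timestamp_s,pressure_mmHg", con)
  writeLines(sprintf("%.3f,%.6f", trace$timestamps, trace$pressure), con)
  invisible(path)
}

#' Read a cohort events file into delivery records
#'
#' @param path events file (`animal_id,group,event_type,timestamp_min`).
#' @return named list of [delivery_record()], one per animal present.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "event_type", "timestamp_min")
  if (!all(need %in% names(df)))
    stop(sprintf("format error in %s: need columns %s", path,
                 paste(need, collapse = ", ")))
  df <- df[df$event_type == "pup_delivery", , drop = FALSE]
  recs <- lapply(split(df, df$animal_id), function(d)
    delivery_record(d$animal_id[1], d$group[1], d$timestamp_min))
  recs[order(names(recs))]
}

#' Resample a pressure trace to exactly 1 Hz
#'
#' Each output sample is the mean of the input samples in the half-open bin
#' `[t, t + 1 s)` anchored at the first timestamp, so every input sample is
#' counted exactly once and a constant signal is preserved exactly. Bins with
#' no samples (telemetry dropouts) are linearly interpolated from the nearest
#' non-empty bins and flagged in `$interpolated`; flagged spans are excluded
#' from peak statistics downstream.
#'
#' @param trace a [pressure_trace()] with `sample_rate >= 1` Hz.
#' @return a [pressure_trace()] at exactly 1 Hz.
#' @export
resample_1hz <- function(trace) {
  stopifnot(inherits(trace, "pressure_trace"))
  if (trace$sample_rate < 1)
    stop("resample_1hz requires an input rate of at least 1 Hz")
  t0 <- trace$timestamps[1]
  bin <- floor(trace$timestamps - t0)            # [t0 + k, t0 + k + 1)
  nbins <- max(bin) + 1L
  sums <- tapply(trace$pressure, bin, sum)
  cnts <- tapply(trace$pressure, bin, length)
  out <- rep(NA_real_, nbins)
  out[as.integer(names(sums)) + 1L] <- sums / cnts
  filled <- is.na(out)
  if (any(filled)) {
    if (all(filled)) stop("no samples to resample")
    out <- stats::approx(which(!filled), out[!filled], xout = seq_len(nbins),
                         rule = 2)$y
  }
  pressure_trace(trace$animal_id, trace$group,
                 timestamps = t0 + seq_len(nbins) - 1,
                 pressure = out, sample_rate = 1,
                 interpolated = filled)
}

#' Convert wall-clock time to zeitgeber time
#'
#' ZT0 is lights-on; values wrap across midnight into `[0, 24)` hours.
#'
#' @param clock_time time of day, either decimal hours or a "HH:MM"/"HH:MM:SS"
#'   string (vectorized).
#' @param lights_on lights-on time of day, same formats (default "06:00").
#' @return hours ZT in `[0, 24)`.
#' @export
to_zt <- function(clock_time, lights_on = "06:00") {
  as_hours <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    parts <- strsplit(as.character(x), ":", fixed = TRUE)
    vapply(parts, function(p) {
      p <- suppressWarnings(as.numeric(p))
      if (any(is.na(p))) stop("unparseable time of day")
      sum(p * c(1, 1 / 60, 1 / 3600)[seq_along(p)])
    }, numeric(1))
  }
  (as_hours(clock_time) - as_hours(lights_on)) %% 24
}
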