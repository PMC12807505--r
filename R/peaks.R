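# Contraction-peak detection on 1 Hz pressure traces: strict local maxima
# filtered by absolute height and topographic prominence, then windowed
# relative to labor onset.

#' Detect contraction peaks by height and prominence
#'
#' A peak is a strict local maximum (plateaus of equal samples collapse to a
#' single peak at the plateau midpoint, floor division) whose sample value is
#' at least `min_height` and whose topographic prominence is at least
#' `min_prominence`. The prominence of a peak is its height minus the higher
#' of its two bases, where each base is the minimum sample value between the
#' peak and the nearest strictly higher sample on that side (or the trace
#' edge when no higher sample exists). Height is the absolute sample value in
#' mmHg, not baseline-subtracted. Edge samples cannot be peaks. Peaks whose
#' apex falls in a flagged dropout span (see [resample_1hz()]) are dropped.
#'
#' @param trace a [pressure_trace()] at 1 Hz.
#' @param min_height minimum absolute peak height, mmHg (default 40).
#' @param min_prominence minimum topographic prominence, mmHg (default 20).
#' @return data.frame with columns `time_s`, `height`, `prominence`, sorted
#'   by time.
#' @export
find_peaks <- function(trace, min_height = 40, min_prominence = 20) {
  stopifnot(inherits(trace, "pressure_trace"))
  x <- trace$pressure
  n <- length(x)
  if (n < 3L) stop("trace shorter than 3 samples")
  if (abs(trace$sample_rate - 1) > 1e-9)
    stop("find_peaks expects a 1 Hz trace; run resample_1hz() first")

  # plateau-aware local maxima
  apex <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) apex <- c(apex, (i + j) %/% 2L)
      i <- j + 1L
    } else i <- i + 1L
  }
  apex <- apex[x[apex] >= min_height]

  prom <- vapply(apex, function(p) {
    h <- x[p]
    higher <- which(x > h)
    l <- higher[higher < p]
    left_base <- if (length(l)) min(x[(max(l) + 1L):p]) else min(x[1:p])
    r <- higher[higher > p]
    right_base <- if (length(r)) min(x[p:(min(r) - 1L)]) else min(x[p:n])
    h - max(left_base, right_base)
  }, numeric(1))

  keep <- prom >= min_prominence & !trace$interpolated[apex]
  data.frame(time_s = trace$timestamps[apex[keep]],
             height = x[apex[keep]],
             prominence = prom[keep])
}

#' Construct a labor-referenced peak set
#'
#' Windows are half-open on the right, so the three onset-referenced windows
#' partition the recording: `pre_labor` = [recording start, onset),
#' `post_onset_2h` = [onset, onset + 2 h), `beyond_2h` = [onset + 2 h, end).
#'
#' @param peaks data.frame from [find_peaks()].
#' @param record a [delivery_record()] supplying the labor onset (minutes).
#' @param window_label one of `"pre_labor"`, `"post_onset_2h"`, `"beyond_2h"`,
#'   `"custom"`.
#' @param recording_start,recording_end bounds of the recording, seconds.
#' @param custom_bounds length-2 numeric (seconds) when `window_label` is
#'   `"custom"`.
#' @return object of class `peak_set` with elements `animal_id`,
#'   `window_label`, `peaks` (data.frame), `window_bounds` (seconds).
#' @export
window_peaks <- function(peaks, record,
                         window_label = c("post_onset_2h", "pre_labor",
                                          "beyond_2h", "custom"),
                         recording_start = 0, recording_end = Inf,
                         custom_bounds = NULL) {
  window_label <- match.arg(window_label)
  if (window_label == "custom") {
    if (is.null(custom_bounds) || length(custom_bounds) != 2L)
      stop("custom window needs custom_bounds = c(lo, hi) in seconds")
    bounds <- as.numeric(custom_bounds)
  } else {
    stopifnot(inherits(record, "delivery_record"))
    if (is.na(record$first_pup_time))
      stop(sprintf("animal %s has no deliveries; onset-referenced window '%s' undefined",
                   record$animal_id, window_label))
    onset_s <- record$first_pup_time * 60
    bounds <- switch(window_label,
      pre_labor = c(recording_start, onset_s),
      post_onset_2h = c(onset_s, onset_s + 7200),
      beyond_2h = c(onset_s + 7200, recording_end))
  }
  inside <- peaks$time_s >= bounds[1] & peaks$time_s < bounds[2]
  sel <- peaks[inside, , drop = FALSE]
  sel <- sel[order(sel$time_s), , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(animal_id = record$animal_id, window_label = window_label,
                 peaks = sel, window_bounds = bounds),
            class = "peak_set")
}

#' Summarize one animal's labor phenotype
#'
#' `mean_peak_pressure` is the arithmetic mean of peak heights in the 2-hour
#' post-onset window (the per-animal outcome fed to the GLS contrast model);
#' `mean_interpup_interval` is the mean gap between successive deliveries.
#' Statistics that are undefined (no peaks; fewer than two pups) are carried
#' as `NA` rather than errors.
#'
#' @param peakset a `peak_set` for the `post_onset_2h` window.
#' @param record the animal's [delivery_record()].
#' @param d_drg,d_uterus 0/1 knockout indicators for the animal's group.
#' @param zt_boundary onset-classification boundary, hours ZT (default 3);
#'   onset exactly at the boundary counts as "before" (strict `>`).
#' @return one-row data.frame (an AnimalSummary row).
#' @export
summarize_animal <- function(peakset, record, d_drg = 0L, d_uterus = 0L,
                             zt_boundary = 3) {
  stopifnot(inherits(peakset, "peak_set"), inherits(record, "delivery_record"))
  if (peakset$window_label != "post_onset_2h")
    stop("summarize_animal expects the post_onset_2h peak set")
  h <- peakset$peaks$height
  gaps <- diff(record$delivery_times)
  onset_zt <- if (is.na(record$first_pup_time)) NA_real_
    else record$first_pup_time / 60
  data.frame(
    animal_id = record$animal_id,
    group = record$group,
    d_drg = as.integer(d_drg),
    d_uterus = as.integer(d_uterus),
    mean_peak_pressure = if (length(h)) mean(h) else NA_real_,
    n_peaks = length(h),
    mean_interpup_interval = if (length(gaps)) mean(gaps) else NA_real_,
    onset_zt = onset_zt,
    onset_after_zt3 = classify_onset(onset_zt, zt_boundary),
    stringsAsFactors = FALSE
  )
}
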