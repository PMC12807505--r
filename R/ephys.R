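# Mechanically activated current classification for patch-clamp sweeps:
# 8-pole Bessel low-pass (-3 dB at the requested cutoff), baseline statistics
# from the 35-to-5 ms pre-stimulus window, and the 5x-SD response rule.

#' Patch-clamp sweep container
#'
#' @param time uniform ascending time grid, ms.
#' @param current pA (inward currents negative).
#' @param stimulus_onset probe-movement start, ms.
#' @param hold_duration hold at target depth, ms.
#' @param depth indentation depth, micrometres.
#' @param sample_rate Hz.
#' @param ramp_speed probe speed, micrometres per ms (default 1).
#' @return object of class `sweep_record`.
#' @export
sweep_record <- function(time, current, stimulus_onset, hold_duration, depth,
                         sample_rate, ramp_speed = 1) {
  time <- as.numeric(time); current <- as.numeric(current)
  if (length(time) != length(current)) stop("time/current length mismatch")
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
    stop("time must be a uniform ascending grid")
  stim_end <- stimulus_onset + depth / ramp_speed + hold_duration
  if (stimulus_onset < time[1] || stim_end > time[length(time)])
    stop("stimulus window must lie inside the record")
  structure(list(time = time, current = current,
                 stimulus_onset = stimulus_onset,
                 hold_duration = hold_duration, depth = depth,
                 sample_rate = sample_rate, ramp_speed = ramp_speed),
            class = "sweep_record")
}

# ascending coefficients of the degree-n reverse Bessel polynomial
# theta_n(s): a_k = (2n - k)! / (2^(n-k) k! (n-k)!)
reverse_bessel_coefs <- function(n) {
  k <- 0:n
  exp(lgamma(2 * n - k + 1) - (n - k) * log(2) - lgamma(k + 1) -
        lgamma(n - k + 1))
}

# monic polynomial coefficients (descending) from roots
poly_from_roots <- function(r) {
  co <- 1
  for (ri in r) co <- c(co, 0) - c(0, co * ri)
  co
}

# Design an n-pole digital Bessel low-pass as second-order sections.
# The delay-normalized analog prototype (roots of theta_n) is rescaled so its
# -3 dB point sits at the bilinear pre-warped cutoff, guaranteeing that the
# digital magnitude response crosses 1/sqrt(2) exactly at `cutoff` Hz; DC
# gain is normalized to 1 per section.
design_bessel_sos <- function(poles, cutoff, fs) {
  co <- reverse_bessel_coefs(poles)
  proto <- polyroot(co)
  hmag <- function(w) co[1] / abs(apply(outer(1i * w, proto, "-"), 1, prod))
  w3 <- stats::uniroot(function(w) hmag(w) - 1 / sqrt(2),
                       c(1e-3, 10 * poles), tol = 1e-13)$root
  wc <- 2 * fs * tan(pi * cutoff / fs)           # pre-warped analog cutoff
  p <- proto * (wc / w3)
  used <- rep(FALSE, poles); sections <- list()
  for (i in seq_len(poles)) {
    if (used[i]) next
    used[i] <- TRUE
    if (abs(Im(p[i])) < 1e-9 * abs(p[i])) pp <- p[i]
    else {
      j <- which(!used & abs(p - Conj(p[i])) < 1e-6 * abs(p[i]))[1]
      used[j] <- TRUE
      pp <- c(p[i], p[j])
    }
    zp <- (1 + pp / (2 * fs)) / (1 - pp / (2 * fs))   # bilinear transform
    a <- Re(poly_from_roots(zp))
    b <- Re(poly_from_roots(rep(-1 + 0i, length(pp)))) # zeros at Nyquist
    sections[[length(sections) + 1L]] <- list(b = b * sum(a) / sum(b), a = a)
  }
  sections
}

#' Low-pass filter a sweep with a digital Bessel filter
#'
#' Digital realization of the analog Bessel prototype via bilinear transform
#' with cutoff pre-warping, normalized so the -3 dB point lands at `cutoff`
#' exactly; applied causally as a cascade of second-order sections. The
#' filter state is initialized at the DC steady state of the first sample, so
#' a constant input passes unchanged.
#'
#' @param sweep a [sweep_record()].
#' @param cutoff -3 dB cutoff, Hz (default 500).
#' @param poles filter order (default 8).
#' @return the filtered [sweep_record()].
#' @export
bessel_lowpass <- function(sweep, cutoff = 500, poles = 8L) {
  stopifnot(inherits(sweep, "sweep_record"))
  if (cutoff >= sweep$sample_rate / 2)
    stop("cutoff must be below the Nyquist frequency")
  sos <- design_bessel_sos(poles, cutoff, sweep$sample_rate)
  x0 <- sweep$current[1]
  y <- sweep$current - x0          # DC offset removal avoids startup transient
  for (s in sos) y <- as.numeric(signal::filter(s$b, s$a, y))
  out <- sweep
  out$current <- y + x0
  out
}

#' Baseline statistics from the pre-stimulus window
#'
#' Mean and sample standard deviation of the current in the closed-open
#' window from 35 ms to 5 ms before stimulus onset.
#'
#' @param sweep a [sweep_record()].
#' @return list with `mean` (pA), `sd` (pA), `n` (samples used).
#' @export
baseline_stats <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_record"))
  lo <- sweep$stimulus_onset - 35
  hi <- sweep$stimulus_onset - 5
  if (lo < sweep$time[1])
    stop("baseline window [onset - 35 ms, onset - 5 ms) truncated by record start")
  idx <- sweep$time >= lo & sweep$time < hi
  x <- sweep$current[idx]
  list(mean = mean(x), sd = sd0(x), n = length(x))
}

#' Classify a sweep as a mechanoresponse
#'
#' The sweep is low-pass filtered (500 Hz, 8-pole Bessel by default), the
#' baseline is measured in the 35-to-5 ms pre-stimulus window, and the peak
#' amplitude is the largest absolute baseline-subtracted excursion within the
#' stimulation window (probe ramp plus hold). The sweep is a mechanoresponse
#' only when that amplitude strictly exceeds `5 x baseline SD`.
#'
#' @param sweep a [sweep_record()].
#' @param cutoff,poles filter settings passed to [bessel_lowpass()].
#' @param filter logical; set `FALSE` to classify the raw trace.
#' @return object of class `mech_response`: `baseline_mean`, `baseline_sd`,
#'   `peak_amplitude` (pA, non-negative magnitude), `peak_sign` (-1 inward,
#'   +1 outward), `threshold` (pA), `is_response`, `depth`.
#' @export
classify_response <- function(sweep, cutoff = 500, poles = 8L,
                              filter = TRUE) {
  stopifnot(inherits(sweep, "sweep_record"))
  sw <- if (filter) bessel_lowpass(sweep, cutoff, poles) else sweep
  bl <- baseline_stats(sw)
  stim_end <- sw$stimulus_onset + sw$depth / sw$ramp_speed + sw$hold_duration
  idx <- sw$time >= sw$stimulus_onset & sw$time <= stim_end
  dev <- sw$current[idx] - bl$mean
  k <- which.max(abs(dev))
  peak <- abs(dev[k])
  threshold <- 5 * bl$sd
  structure(list(baseline_mean = bl$mean, baseline_sd = bl$sd,
                 peak_amplitude = peak,
                 peak_sign = if (peak == 0) 0 else sign(dev[k]),
                 threshold = threshold,
                 is_response = peak > threshold,
                 depth = sw$depth),
            class = "mech_response")
}

#' @export
print.mech_response <- function(x, ...) {
  cat(sprintf(
    "<mech_response> depth %g um: peak %.1f pA (%s), threshold %.1f pA -> %s\n",
    x$depth, x$peak_amplitude,
    if (x$peak_sign < 0) "inward" else "outward", x$threshold,
    if (x$is_response) "response" else "no response"))
  invisible(x)
}

#' Peak amplitude by indentation depth for a cell
#'
#' Runs [classify_response()] over a list of sweeps and tabulates the
#' baseline-subtracted peak amplitude per depth (the quantity plotted in
#' pressure-response summaries).
#'
#' @param sweeps list of [sweep_record()].
#' @param ... passed to [classify_response()].
#' @return data.frame with `depth`, `peak_amplitude`, `is_response`,
#'   `baseline_sd`.
#' @export
amplitude_by_depth <- function(sweeps, ...) {
  rows <- lapply(sweeps, function(sw) {
    r <- classify_response(sw, ...)
    data.frame(depth = r$depth, peak_amplitude = r$peak_amplitude,
               is_response = r$is_response, baseline_sd = r$baseline_sd)
  })
  out <- do.call(rbind, rows)
  out[order(out$depth), , drop = FALSE]
}
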