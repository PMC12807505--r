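# Independent brute-force oracles used to validate the fast implementations.

# Peak oracle: enumerate plateau-collapsed local maxima via run-length
# encoding, then compute each peak's prominence by a literal left/right scan
# of the definition (minimum sample between the peak and the nearest strictly
# higher sample, or the trace edge).
oracle_peaks <- function(x, min_height, min_prominence) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (q in seq_along(r$values)) {
    if (q == 1L || q == length(r$values)) next
    if (!(r$values[q] > r$values[q - 1L] && r$values[q] > r$values[q + 1L]))
      next
    p <- (starts[q] + ends[q]) %/% 2L
    h <- x[p]
    if (h < min_height) next
    lmin <- h; k <- p - 1L
    while (k >= 1L && x[k] <= h) { lmin <- min(lmin, x[k]); k <- k - 1L }
    rmin <- h; k <- p + 1L
    while (k <= length(x) && x[k] <= h) { rmin <- min(rmin, x[k]); k <- k + 1L }
    prom <- h - max(lmin, rmin)
    if (prom >= min_prominence)
      rows[[length(rows) + 1L]] <- c(p, h, prom)
  }
  if (!length(rows))
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  m <- do.call(rbind, rows)
  data.frame(index = m[, 1], height = m[, 2], prominence = m[, 3])
}

# random 1 Hz test traces: smoothed random walks rescaled so that some peaks
# clear the height threshold; half are quantized to force ties and plateaus
random_trace <- function(n, quantize = FALSE) {
  x <- cumsum(stats::rnorm(n))
  x <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
  x[is.na(x)] <- 0
  x <- (x - min(x)) / max(diff(range(x)), 1e-9) * 80
  if (quantize) x <- round(x / 4) * 4
  x
}

as_trace_1hz <- function(x, id = "t") {
  pressure_trace(id, "g", seq_along(x) - 1, x, 1)
}

# Mann-Whitney oracle: full enumeration over all choose(n1 + n2, n1)
# assignments of the pooled values to the first sample
oracle_mw <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); N <- length(pooled)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(N, n1), 2, u_of)
  pl <- mean(us <= u_obs)
  pu <- mean(us >= u_obs)
  min(1, 2 * min(pl, pu))
}

# Fisher oracle: explicit hypergeometric enumeration from binomial
# coefficients (no dhyper)
oracle_fisher <- function(a, b, cc, d) {
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; N <- a + b + cc + d
  pr <- function(aa) choose(r1, aa) * choose(r2, c1 - aa) / choose(N, c1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, pr, numeric(1))
  sum(probs[probs <= pr(a) * (1 + 1e-12)])
}

# direct dense GLS solve for a fixed, known covariance diagonal
oracle_gls_beta <- function(X, P, omega) {
  Oi <- diag(1 / omega)
  solve(t(X) %*% Oi %*% X) %*% t(X) %*% Oi %*% P
}

# animal-summary table for simulated outcomes under the knockout design
simulate_summaries <- function(ns, beta, sds,
                               labels = c("control", "uterus_ko", "drg_ko",
                                          "combined_ko")) {
  d_drg <- rep(c(0, 0, 1, 1), ns)
  d_ut <- rep(c(0, 1, 0, 1), ns)
  grp <- rep(labels, ns)
  mu <- beta[1] + beta[2] * d_drg + beta[3] * d_ut
  data.frame(animal_id = sprintf("a%02d", seq_along(grp)), group = grp,
             d_drg = d_drg, d_uterus = d_ut,
             mean_peak_pressure = mu + stats::rnorm(length(grp), 0,
                                                    rep(sds, ns)),
             stringsAsFactors = FALSE)
}
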