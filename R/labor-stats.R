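# Group-level tests on animal summaries, implemented from first principles
# for small-sample exactness: Fisher's exact 2x2 by full hypergeometric
# enumeration, Mann-Whitney with an exact rank-sum distribution for small
# samples, and Kruskal-Wallis with tie correction.

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Enumerates every table sharing the observed margins and sums the
#' hypergeometric probabilities of all tables whose probability does not
#' exceed that of the observed table (the probability-mass rule, within
#' relative tolerance 1e-12). Rows are groups, columns outcome classes.
#'
#' @param table 2x2 matrix of non-negative counts, or length-4 vector
#'   `c(a, b, c, d)` read row-wise.
#' @return list with `p_value`, `odds_ratio` (sample OR, may be `Inf`), and
#'   `note` (non-`NULL` for degenerate margins, where p = 1).
#' @export
fisher_exact_2x2 <- function(table) {
  tb <- if (is.matrix(table)) {
    if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
    matrix(as.numeric(table), 2, 2)
  } else {
    if (length(table) != 4L) stop("table must be 2x2 or length-4 c(a,b,c,d)")
    matrix(as.numeric(table), 2, 2, byrow = TRUE)
  }
  if (any(tb < 0) || any(tb != round(tb)) || sum(tb) == 0)
    stop("table must hold non-negative integer counts with a positive total")
  a <- tb[1, 1]; b <- tb[1, 2]; cc <- tb[2, 1]; d <- tb[2, 2]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  orat <- (a * d) / (b * cc)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(p_value = 1, odds_ratio = orat,
                note = "degenerate margins: an all-zero row or column"))
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  list(p_value = min(p, 1), odds_ratio = orat, note = NULL)
}

#' Mann-Whitney U test (two-sided)
#'
#' For combined sample size at most 20 and no ties, the p-value is exact:
#' the full permutation distribution of U is built by dynamic programming
#' over rank assignments. Otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `U` (number of (x, y) pairs with x > y, ties counting
#'   one half), `p_value`, and `method` ("exact" or "normal_approx").
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  if (length(unique(pooled)) == 1L)
    return(list(U = U, p_value = 1, method = "degenerate"))
  if (!ties && N <= 20L) {
    cnt <- exact_u_counts(n1, n2)
    tot <- sum(cnt)
    pl <- sum(cnt[seq_len(U + 1L)]) / tot            # P(U <= u)
    pu <- sum(cnt[(U + 1L):length(cnt)]) / tot       # P(U >= u)
    p <- min(1, 2 * min(pl, pu))
    return(list(U = U, p_value = p, method = "exact"))
  }
  tab <- table(pooled)
  tiesum <- sum(tab^3 - tab)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tiesum / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "degenerate"))
  z <- (U - n1 * n2 / 2 - sign(U - n1 * n2 / 2) * 0.5) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal_approx")
}

# Exact null distribution of U without ties: counts[u + 1] = number of the
# choose(n1 + n2, n1) rank interleavings with U = u, via the recurrence
# N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1)
# (the largest value is an x, contributing n to U, or a y, contributing 0).
exact_u_counts <- function(n1, n2) {
  maxu <- n1 * n2
  prev <- lapply(0:n2, function(n) c(1, numeric(maxu)))   # m = 0: U is 0
  for (m in seq_len(n1)) {
    cur <- vector("list", n2 + 1L)
    cur[[1L]] <- c(1, numeric(maxu))                      # n = 0: U is 0
    for (n in seq_len(n2)) {
      shifted <- c(numeric(n), prev[[n + 1L]][seq_len(maxu + 1L - n)])
      cur[[n + 1L]] <- shifted + cur[[n]]
    }
    prev <- cur
  }
  prev[[n2 + 1L]]
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with tie correction, referred to a chi-square distribution
#' with k - 1 degrees of freedom.
#'
#' @param groups list of two or more non-empty numeric samples.
#' @return list with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("kruskal_wallis needs at least 2 groups")
  if (any(!lengths(groups))) stop("all groups must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  grp <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, grp, mean)
  ni <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  tab <- table(pooled)
  C <- 1 - sum(tab^3 - tab) / (N^3 - N)
  H <- if (C > 0) H / C else 0
  df <- length(groups) - 1L
  list(H = H, df = df,
       p_value = if (H == 0) 1 else stats::pchisq(H, df, lower.tail = FALSE))
}

#' Classify labor onset relative to a zeitgeber-time boundary
#'
#' Returns `TRUE` when onset is strictly after the boundary (default ZT3);
#' onset exactly at the boundary counts as "before". Missing onsets stay
#' missing.
#'
#' @param onset_zt onset time(s), hours ZT.
#' @param zt_boundary boundary, hours ZT (default 3).
#' @return logical vector.
#' @export
classify_onset <- function(onset_zt, zt_boundary = 3) {
  as.logical(onset_zt > zt_boundary)
}
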