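# Heteroscedastic generalized least squares for per-animal mean peak
# pressure. Model: P_i = b0 + b_DRG * D_DRG_i + b_Uterus * D_Uterus_i + e_i,
# e_i ~ N(0, sigma^2_{g_i}) with one variance per treatment group (viral
# knockouts are inherently more variable than germline Cre lines). Feasible
# GLS iterates between the weighted normal equations and the per-group
# variance estimates; knockout effects are tested one-sided (H1: beta < 0)
# against a t reference with n - p degrees of freedom.

#' Build the knockout design matrix from animal summaries
#'
#' Columns are intercept, `d_drg`, `d_uterus`; rows are ordered by
#' `animal_id`. Animals without a defined mean peak pressure are rejected,
#' and every group must contribute at least two animals so its variance is
#' estimable.
#'
#' @param summaries data.frame of AnimalSummary rows (see
#'   [summarize_animal()]): columns `animal_id`, `group`, `d_drg`,
#'   `d_uterus`, `mean_peak_pressure`.
#' @return list of class `design_matrix` with `X` (n x 3), `P` (outcomes,
#'   mmHg), `group` (labels), `group_index` (integer per row).
#' @export
build_design <- function(summaries) {
  need <- c("animal_id", "group", "d_drg", "d_uterus", "mean_peak_pressure")
  if (!all(need %in% names(summaries)))
    stop(sprintf("summaries must have columns %s", paste(need, collapse = ", ")))
  if (any(is.na(summaries$mean_peak_pressure)))
    stop("every animal must have a defined mean_peak_pressure")
  if (!all(c(summaries$d_drg, summaries$d_uterus) %in% c(0, 1)))
    stop("indicators must be 0/1")
  summaries <- summaries[order(summaries$animal_id), , drop = FALSE]
  grp <- factor(summaries$group, levels = unique(summaries$group))
  sizes <- table(grp)
  if (length(sizes) < 2L)
    stop("need at least two treatment groups")
  if (any(sizes < 2L))
    stop(sprintf("group(s) with fewer than 2 animals: %s",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  X <- cbind(intercept = 1, d_drg = summaries$d_drg,
             d_uterus = summaries$d_uterus)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient; check group composition")
  structure(list(X = X, P = summaries$mean_peak_pressure,
                 group = as.character(grp),
                 group_index = as.integer(grp),
                 animal_id = summaries$animal_id),
            class = "design_matrix")
}

#' Fit the heteroscedastic GLS model by iterative feasible estimation
#'
#' Starts from ordinary least squares, then alternates (a) per-group error
#' variances from the current residuals and (b) the weighted estimator
#' `(X' O^-1 X)^-1 X' O^-1 P` with `O = diag(sigma^2_{g_i})`, until the
#' maximum relative change in the coefficients drops below `tol`. Standard
#' errors come from `diag((X' O^-1 X)^-1)` at the final variances; one-sided
#' p-values are the lower tail of a t distribution with `n - p` degrees of
#' freedom, `p` counting only the 3 mean-model coefficients.
#'
#' Group variances use the leverage-corrected denominator
#' `sum(1 - h_ii)` over the group's observations (the GLS hat diagonal), a
#' near-unbiased small-sample correction; `var_correction = "none"` gives the
#' plain mean squared residual. `one_step = TRUE` stops after the first
#' variance update (non-iterated feasible GLS).
#'
#' @param design a [build_design()] result, or a summaries data.frame.
#' @param tol relative convergence tolerance on coefficients.
#' @param max_iter iteration cap.
#' @param one_step logical; single variance update instead of iterating.
#' @param var_correction `"leverage"` (default) or `"none"`.
#' @param omega optional fixed per-observation variance vector; when given, no
#'   variance estimation happens and the closed-form GLS estimate is returned.
#' @return object of class `gls_fit`: `beta`, `se`, `t_stats`, `p_one_sided`,
#'   `sigma2_by_group`, `omega_diag`, `df`, `converged`, `n_iter`.
#' @export
fit_gls <- function(design, tol = 1e-8, max_iter = 100L, one_step = FALSE,
                    var_correction = c("leverage", "none"), omega = NULL) {
  if (is.data.frame(design)) design <- build_design(design)
  stopifnot(inherits(design, "design_matrix"))
  var_correction <- match.arg(var_correction)
  X <- design$X; P <- design$P; g <- design$group_index
  n <- nrow(X); p <- ncol(X); df <- n - p
  ngroups <- max(g)

  gls_solve <- function(w) {
    XtW <- t(X * w)
    A <- XtW %*% X
    if (rcond(A) < 1e-14) stop("singular weighted normal equations")
    V <- solve(A)
    list(beta = as.numeric(V %*% (XtW %*% P)), V = V)
  }

  if (!is.null(omega)) {                     # known covariance: closed form
    w <- 1 / rep_len(as.numeric(omega), n)
    sol <- gls_solve(w)
    beta <- sol$beta
    se <- sqrt(diag(sol$V))
    s2g <- tapply(rep_len(as.numeric(omega), n), g, mean)
    t_stats <- beta / se
    return(new_gls_fit(beta, se, t_stats, stats::pt(t_stats, df),
                       s2g, rep_len(as.numeric(omega), n), df,
                       TRUE, 0L, design))
  }

  beta <- qr.coef(qr(X), P)                  # OLS start
  w <- rep(1, n)
  V <- solve(crossprod(X))                   # so leverage applies from OLS on
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    r <- as.numeric(P - X %*% beta)
    if (var_correction == "leverage") {
      h <- rowSums((X %*% V) * (X * w))      # diag of X (X'WX)^-1 X'W
      denom <- tapply(1 - h, g, sum)
    } else {
      denom <- tapply(rep(1, n), g, sum)
    }
    s2g <- tapply(r^2, g, sum) / denom
    if (any(s2g <= 0)) stop("a group variance collapsed to zero")
    w <- as.numeric(1 / s2g[g])
    sol <- gls_solve(w)
    delta <- max(abs(sol$beta - beta) / pmax(abs(beta), 1e-10))
    beta <- sol$beta
    V <- sol$V
    if (one_step) { converged <- TRUE; break }
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  se <- sqrt(diag(V))
  t_stats <- beta / se
  new_gls_fit(beta, se, t_stats, stats::pt(t_stats, df), s2g,
              as.numeric(s2g[g]), df, converged, iter, design)
}

new_gls_fit <- function(beta, se, t_stats, p_one_sided, s2g, omega_diag, df,
                        converged, n_iter, design) {
  names(beta) <- names(se) <- names(t_stats) <- names(p_one_sided) <-
    colnames(design$X)
  structure(list(beta = beta, se = se, t_stats = t_stats,
                 p_one_sided = p_one_sided,
                 sigma2_by_group = s2g, omega_diag = omega_diag, df = df,
                 converged = converged, n_iter = n_iter,
                 group = design$group, n = nrow(design$X)),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("Heteroscedastic GLS fit (n = %d, df = %d, %s in %d iteration%s)\n",
              x$n, x$df,
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, if (x$n_iter == 1) "" else "s"))
  tab <- data.frame(estimate = x$beta, se = x$se, t = x$t_stats,
                    p_one_sided = x$p_one_sided)
  print(format(tab, digits = 4))
  cat("group variances (mmHg^2):\n")
  print(round(x$sigma2_by_group, 2))
  invisible(x)
}

#' One-sided test of a knockout coefficient
#'
#' Tests H0: beta >= 0 against H1: beta < 0; the p-value is the lower-tail
#' probability of a t distribution with `n - p` degrees of freedom at
#' `t = beta / se`, reported as the lower tail even when the estimate is
#' positive. Set `two_sided = TRUE` for the symmetric alternative.
#'
#' @param fit a [fit_gls()] result.
#' @param coefficient `"d_drg"` or `"d_uterus"`.
#' @param two_sided logical.
#' @return list with `t`, `df`, `p_value`.
#' @export
one_sided_test <- function(fit, coefficient = c("d_drg", "d_uterus"),
                           two_sided = FALSE) {
  stopifnot(inherits(fit, "gls_fit"))
  coefficient <- match.arg(coefficient)
  t <- unname(fit$t_stats[coefficient])
  p <- if (two_sided) 2 * stats::pt(-abs(t), fit$df)
       else stats::pt(t, fit$df)
  list(t = t, df = fit$df, p_value = p)
}
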