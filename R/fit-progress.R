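# Nonlinear fitting of individual slow-binding progress curves.

# Unvalidated model evaluation used inside optimisation loops.
#' @noRd
.sb_model <- function(t, v0, vs, kobs) {
  vs * t + (v0 - vs) * (1 - exp(-kobs * t)) / kobs
}

#' Fit the slow-binding model to one progress curve
#'
#' Estimates (v0, vs, kobs) by nonlinear least squares with a deterministic
#' multistart: kobs is started at \{0.5, 1, 2, 5, 10\}/T_end, v0 at the
#' secant slope over the first decile of the trace and vs at the secant
#' slope over the last quintile; the start with the smallest residual sum of
#' squares wins, ties going to the smaller kobs. Standard errors come from
#' the Jacobian at the optimum.
#'
#' A curve without a detectable slow phase is not forced through the
#' three-parameter model: the slow-binding fit is compared with a straight
#' line through the origin by an F-test, and when the curvature is not
#' significant (p > `alpha_linear`) a sentinel fit is returned with
#' `slow_binding = FALSE`, `v0 = vs =` the linear slope and `kobs = NA`.
#'
#' @param curve a [progress_curve()].
#' @param alpha_linear significance level of the curvature F-test.
#' @param maxiter,ftol,ptol optimiser controls passed to
#'   [minpack.lm::nls.lm.control()].
#' @return object of class `slow_binding_fit`: estimates, standard errors,
#'   `sse`, `converged`, `slow_binding`, `p_linear`, and the curve's
#'   (S, I, curve_id).
#' @export
fit_progress_curve <- function(curve, alpha_linear = 0.05,
                               maxiter = 500, ftol = 1e-10, ptol = 1e-8) {
  stopifnot(inherits(curve, "progress_curve"))
  t <- curve$times
  y <- curve$signal
  n <- length(t)
  if (n < 6) stop_input("need at least 6 time points, got %d", n)
  if (all(y == y[1])) stop_input("signal is constant; nothing to fit")

  # Straight line through the origin (the model's linear limit).
  lin_slope <- sum(t * y) / sum(t * t)
  sse_lin <- sum((y - lin_slope * t)^2)

  sentinel <- function(p_linear) {
    structure(
      list(v0 = lin_slope, vs = lin_slope, kobs = NA_real_,
           se = c(v0 = NA_real_, vs = NA_real_, kobs = NA_real_),
           sse = sse_lin, converged = TRUE, slow_binding = FALSE,
           p_linear = p_linear, n = n,
           S = curve$S, I = curve$I, curve_id = curve$curve_id),
      class = "slow_binding_fit")
  }

  # Numerically exact straight line: curvature unidentifiable.
  if (sse_lin <= n * (1e-10 * max(abs(y)))^2) return(sentinel(1))

  t_end <- max(t)
  i10 <- max(2L, ceiling(n / 10))
  v0_start <- (y[i10] - y[1]) / (t[i10] - t[1])
  i80 <- min(n - 1L, floor(0.8 * n))
  vs_start <- (y[n] - y[i80]) / (t[n] - t[i80])
  v0_start <- max(v0_start, .Machine$double.eps)
  vs_start <- min(max(vs_start, 0), v0_start)

  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol, ptol = ptol)
  scale0 <- max(abs(y))
  best <- NULL
  for (k_start in c(0.5, 1, 2, 5, 10) / t_end) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ vs * t + (v0 - vs) * (1 - exp(-kobs * t)) / kobs,
        data = data.frame(t = t, y = y),
        start = list(v0 = v0_start, vs = vs_start, kobs = k_start),
        lower = c(v0 = 0, vs = 0, kobs = 1e-3 / t_end),
        control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    kb <- stats::coef(fit)[["kobs"]]
    if (is.null(best) || sse < best$sse * (1 - 1e-12) ||
        (abs(sse - best$sse) <= 1e-12 * max(sse, best$sse) && kb < best$kobs)) {
      best <- list(fit = fit, sse = sse, kobs = kb)
    }
  }

  if (is.null(best)) {
    return(structure(
      list(v0 = NA_real_, vs = NA_real_, kobs = NA_real_,
           se = c(v0 = NA_real_, vs = NA_real_, kobs = NA_real_),
           sse = NA_real_, converged = FALSE, slow_binding = NA,
           p_linear = NA_real_, n = n,
           S = curve$S, I = curve$I, curve_id = curve$curve_id),
      class = "slow_binding_fit"))
  }

  sse_sb <- best$sse
  # F-test: does the slow phase improve on the straight line?
  df2 <- n - 3
  f_stat <- ((sse_lin - sse_sb) / 2) / (sse_sb / df2)
  p_linear <- if (sse_sb == 0) {
    0  # exact curved fit: the slow phase is certainly there
  } else if (is.finite(f_stat) && f_stat > 0) {
    stats::pf(f_stat, 2, df2, lower.tail = FALSE)
  } else {
    1
  }
  if (p_linear > alpha_linear) return(sentinel(p_linear))

  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) c(v0 = NA, vs = NA, kobs = NA))
  structure(
    list(v0 = cf[["v0"]], vs = cf[["vs"]], kobs = cf[["kobs"]],
         se = c(v0 = se[["v0"]], vs = se[["vs"]], kobs = se[["kobs"]]),
         sse = sse_sb, converged = TRUE, slow_binding = TRUE,
         p_linear = p_linear, n = n,
         S = curve$S, I = curve$I, curve_id = curve$curve_id),
    class = "slow_binding_fit")
}

#' @export
print.slow_binding_fit <- function(x, ...) {
  if (isTRUE(x$slow_binding)) {
    cat(sprintf("<slow_binding_fit> %s: v0 = %.4g, vs = %.4g, kobs = %.4g s^-1 (sse %.3g)\n",
                x$curve_id, x$v0, x$vs, x$kobs, x$sse))
  } else if (isFALSE(x$slow_binding)) {
    cat(sprintf("<slow_binding_fit> %s: linear (no slow phase), slope = %.4g (p = %.3g)\n",
                x$curve_id, x$v0, x$p_linear))
  } else {
    cat(sprintf("<slow_binding_fit> %s: did not converge\n", x$curve_id))
  }
  invisible(x)
}

#' Tidy a list of progress-curve fits
#'
#' @param fits list of `slow_binding_fit` objects.
#' @return data frame with one row per curve.
#' @export
tidy_progress_fits <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(curve_id = f$curve_id, S = f$S, I = f$I,
               v0 = f$v0, vs = f$vs, kobs = f$kobs,
               se_v0 = f$se[["v0"]], se_vs = f$se[["vs"]], se_kobs = f$se[["kobs"]],
               sse = f$sse, converged = f$converged,
               slow_binding = f$slow_binding, p_linear = f$p_linear)
  }))
}
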