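# Fast-binding analysis: global Michaelis-Menten inhibition fits with AICc
# model selection, double-reciprocal diagnostics, and apparent-parameter
# trends.

#' @noRd
.mm_formulas <- list(
  competitive    = v ~ Vmax * S / (Km * (1 + I / Ki) + S),
  noncompetitive = v ~ Vmax * S / ((Km + S) * (1 + I / Ki)),
  uncompetitive  = v ~ Vmax * S / (Km + S * (1 + I / Ki)),
  mixed          = v ~ Vmax * S / (Km * (1 + I / Kic) + S * (1 + I / Kiu))
)

#' @noRd
.mm_npar <- c(competitive = 3, noncompetitive = 3, uncompetitive = 3, mixed = 4)

#' Globally fit the Michaelis-Menten inhibition model family
#'
#' Fits the competitive, noncompetitive, uncompetitive and mixed inhibition
#' rate laws to an initial-rate grid by nonlinear least squares on the
#' untransformed rates, and selects the modality by small-sample corrected
#' AICc. Rows with I = 0 participate in every fit (they pin down Km and
#' Vmax). The default weighting (1/v^2) matches a constant-CV error model;
#' set `weighting = "none"` for homoscedastic errors.
#'
#' Model selection: weighted residual sums of squares are floored at
#' numerical-noise level so that models reproducing the data exactly tie;
#' among models within 2 AICc units of the best, the one with fewest
#' parameters wins (the 4-parameter mixed law nests the three 3-parameter
#' laws, so an exact tie means its extra constant is unidentifiable). A tie
#' between non-nested 3-parameter models is reported as "undetermined" with
#' both candidates.
#'
#' @param table a [rate_table()] (or data frame with columns S, I, v),
#'   concentrations in molar.
#' @param weighting `"proportional"` (weights 1/v^2, default) or `"none"`.
#' @return object of class `steady_state_fit`: `modality`, `params` (named
#'   estimates), `se`, `aicc` (per-model table), `apparent` (per-inhibitor
#'   Km_app/Vmax_app), `fits` (the nls objects), `candidates` (modalities
#'   within the tie band).
#' @export
fit_inhibition_models <- function(table, weighting = c("proportional", "none")) {
  weighting <- match.arg(weighting)
  df <- as.data.frame(table)[, c("S", "I", "v")]
  if (length(unique(df$S)) < 3 || length(unique(df$I)) < 2) {
    stop_input("insufficient design: need >= 3 substrate and >= 2 inhibitor levels")
  }
  if (any(df$v <= 0)) {
    bad <- sum(df$v <= 0)
    warning(sprintf("dropping %d rows with non-positive rates", bad), call. = FALSE)
    df <- df[df$v > 0, ]
  }
  n <- nrow(df)
  w <- if (weighting == "proportional") 1 / df$v^2 else rep(1, n)

  # Starting values from the uninhibited rows (or the lowest-I rows).
  base <- df[df$I == min(df$I), ]
  Vmax0 <- max(df$v) * 1.2
  Km0 <- base$S[which.min(abs(base$v - Vmax0 / 2))]
  if (length(Km0) == 0 || Km0 <= 0) Km0 <- stats::median(df$S)
  Ki0 <- stats::median(df$I[df$I > 0])
  if (!is.finite(Ki0) || Ki0 <= 0) Ki0 <- Km0

  lo3 <- c(Vmax = Vmax0 * 1e-6, Km = min(df$S) * 1e-4, Ki = Ki0 * 1e-6)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12, ptol = 1e-10)

  fits <- list()
  rss <- se <- list()
  scale_w <- sqrt(mean(w * df$v^2))
  rss_floor <- n * (1e-9 * scale_w)^2
  for (m in names(.mm_formulas)) {
    start <- if (m == "mixed") {
      list(Vmax = Vmax0, Km = Km0, Kic = Ki0, Kiu = Ki0 * 2)
    } else {
      list(Vmax = Vmax0, Km = Km0, Ki = Ki0)
    }
    lower <- if (m == "mixed") {
      c(lo3[c("Vmax", "Km")], Kic = unname(lo3[["Ki"]]), Kiu = unname(lo3[["Ki"]]))
    } else {
      lo3
    }
    fml <- .mm_formulas[[m]]
    environment(fml) <- environment()  # so nls sees the local weights
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = df, start = start,
                        lower = lower, weights = w, control = ctrl),
      error = function(e) NULL)
    fits[[m]] <- fit
    if (!is.null(fit)) {
      # weighted RSS (residuals() on nls objects is unweighted)
      rss[[m]] <- max(sum(w * (df$v - stats::fitted(fit))^2), rss_floor)
      se[[m]] <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                          error = function(e) NULL)
    }
  }
  ok <- names(fits)[!vapply(fits, is.null, logical(1))]
  if (length(ok) == 0) stop_input("no inhibition model converged")

  aicc <- data.frame(
    modality = ok,
    n_par = .mm_npar[ok],
    rss = unlist(rss[ok]),
    exact = unlist(rss[ok]) <= rss_floor * (1 + 1e-8),
    aicc = vapply(ok, function(m) aicc_from_rss(rss[[m]], n, .mm_npar[[m]]),
                  numeric(1)),
    row.names = NULL)
  aicc <- aicc[order(aicc$aicc), ]
  band <- aicc[aicc$aicc - min(aicc$aicc) < 2, ]
  simplest <- band[band$n_par == min(band$n_par), ]
  if (nrow(simplest) > 1) {
    modality <- "undetermined"
    chosen <- simplest$modality[1]  # report parameters of the AICc-best
  } else {
    modality <- simplest$modality
    chosen <- modality
  }

  apparent <- apparent_parameters(df, weighting = weighting)

  structure(
    list(modality = modality, candidates = band$modality,
         params = stats::coef(fits[[chosen]]), se = se[[chosen]],
         aicc = aicc, apparent = apparent, fits = fits,
         weighting = weighting, n = n, data = df),
    class = "steady_state_fit")
}

# Per-inhibitor-level Michaelis-Menten fits: apparent Km and Vmax at each I.
#' @noRd
apparent_parameters <- function(df, weighting = "proportional") {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  out <- lapply(sort(unique(df$I)), function(i) {
    sub <- df[df$I == i, ]
    if (length(unique(sub$S)) < 3) return(NULL)
    w <- if (weighting == "proportional") 1 / sub$v^2 else rep(1, nrow(sub))
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ Vm * S / (Kma + S), data = sub,
                        start = list(Vm = max(sub$v) * 1.2,
                                     Kma = stats::median(sub$S)),
                        lower = c(Vm = 0, Kma = 0), weights = w, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    cf <- stats::coef(fit)
    data.frame(I = i, Km_app = cf[["Kma"]], Vmax_app = cf[["Vm"]])
  })
  do.call(rbind, out)
}

#' @export
print.steady_state_fit <- function(x, ...) {
  cat(sprintf("<steady_state_fit> modality: %s (n = %d, %s weighting)\n",
              x$modality, x$n, x$weighting))
  p <- x$params
  cat("  ", paste(sprintf("%s = %.4g", names(p), p), collapse = ", "), "\n")
  print(x$aicc, row.names = FALSE)
  invisible(x)
}

#' Double-reciprocal (Lineweaver-Burk) diagnostics
#'
#' Fits a straight line to 1/v versus 1/S at each inhibitor level and
#' classifies the convergence pattern: lines sharing their 1/v-axis
#' intercept (1/Vmax) indicate competitive inhibition, lines crossing on the
#' 1/S axis at -1/Km indicate noncompetitive, and parallel lines indicate
#' uncompetitive inhibition. The transform amplifies noise at low rates, so
#' this is a diagnostic view; parameter estimates of record come from
#' [fit_inhibition_models()].
#'
#' @param table a [rate_table()] or data frame with columns S, I, v.
#' @param se_mult on noisy data, intercepts within `se_mult` pooled standard
#'   errors are treated as common.
#' @return object of class `reciprocal_diagnostics`: per-level `lines`
#'   (slope/intercept with SEs), relative spreads of the three convergence
#'   statistics, and the `pattern` classification.
#' @export
reciprocal_diagnostics <- function(table, se_mult = 2) {
  df <- as.data.frame(table)[, c("S", "I", "v")]
  dropped <- sum(df$v <= 0)
  if (dropped > 0) {
    warning(sprintf("dropped %d rows with non-positive rates", dropped),
            call. = FALSE)
    df <- df[df$v > 0, ]
  }
  lines <- do.call(rbind, lapply(sort(unique(df$I)), function(i) {
    sub <- df[df$I == i, ]
    if (length(unique(sub$S)) < 2) return(NULL)
    fit <- stats::lm(I(1 / v) ~ I(1 / S), data = sub)
    cf <- suppressWarnings(summary(fit))$coefficients
    se_col <- if (nrow(sub) > 2) cf[, "Std. Error"] else c(NA_real_, NA_real_)
    data.frame(I = i, slope = cf[2, "Estimate"], intercept = cf[1, "Estimate"],
               se_slope = se_col[2], se_intercept = se_col[1])
  }))
  if (is.null(lines) || nrow(lines) < 2) {
    stop_input("need >= 2 inhibitor levels with >= 2 substrate points each")
  }
  rel_spread <- function(x) stats::sd(x) / mean(abs(x))
  spreads <- c(
    v_intercept = rel_spread(lines$intercept),            # competitive
    s_intercept = rel_spread(-lines$intercept / lines$slope),  # noncompetitive
    slope = rel_spread(lines$slope)                       # uncompetitive
  )
  pattern <- c("competitive", "noncompetitive", "uncompetitive")[which.min(spreads)]

  # Statistical support: are the 1/v intercepts common within se_mult SEs?
  pooled_se <- sqrt(mean(lines$se_intercept^2))
  common_v_intercept <- if (is.finite(pooled_se) && pooled_se > 0) {
    diff(range(lines$intercept)) <= se_mult * pooled_se
  } else {
    NA
  }
  structure(
    list(lines = lines, spreads = spreads, pattern = pattern,
         common_v_intercept = common_v_intercept, dropped = dropped),
    class = "reciprocal_diagnostics")
}

#' @export
print.reciprocal_diagnostics <- function(x, ...) {
  cat(sprintf("<reciprocal_diagnostics> %d lines, pattern: %s\n",
              nrow(x$lines), x$pattern))
  print(x$lines, row.names = FALSE)
  invisible(x)
}

#' Trend of apparent Km and Vmax with inhibitor concentration
#'
#' For a competitive inhibitor the apparent Michaelis constant grows
#' linearly, Km_app = Km (1 + I/Ki), while Vmax is untouched; the regression
#' of Km_app on I therefore yields an independent Ki estimate
#' (intercept/slope). Vmax invariance is assessed by a slope t-test plus a
#' relative-range check.
#'
#' @param fit a `steady_state_fit` (its `apparent` table is used), or a data
#'   frame with columns I, Km_app, Vmax_app.
#' @param alpha significance level for the Vmax trend test.
#' @param vmax_band practical-equivalence band for Vmax invariance.
#' @return object of class `apparent_trend`: `Ki_est`, `km_line`,
#'   `vmax_line`, `vmax_invariant`.
#' @export
apparent_parameter_trend <- function(fit, alpha = 0.05, vmax_band = 0.1) {
  app <- if (inherits(fit, "steady_state_fit")) fit$apparent else as.data.frame(fit)
  if (is.null(app) || nrow(app) < 2) {
    stop_input("need apparent parameters at >= 2 inhibitor levels")
  }
  km_fit <- stats::lm(Km_app ~ I, data = app)
  km_cf <- stats::coef(km_fit)
  Ki_est <- if (km_cf[["I"]] > 0) km_cf[["(Intercept)"]] / km_cf[["I"]] else NA_real_

  vm_fit <- stats::lm(Vmax_app ~ I, data = app)
  vm_sm <- suppressWarnings(summary(vm_fit))$coefficients
  p_vm <- if (nrow(app) > 2) vm_sm["I", "Pr(>|t|)"] else NA_real_
  vm_span <- abs(vm_sm["I", "Estimate"]) * diff(range(app$I)) / mean(app$Vmax_app)
  vmax_invariant <- (is.na(p_vm) || p_vm >= alpha) && vm_span < vmax_band

  structure(
    list(Ki_est = Ki_est,
         km_line = c(intercept = km_cf[["(Intercept)"]], slope = km_cf[["I"]]),
         vmax_line = c(intercept = vm_sm["(Intercept)", "Estimate"],
                       slope = vm_sm["I", "Estimate"]),
         p_vmax = p_vm, vmax_span = vm_span, vmax_invariant = vmax_invariant,
         apparent = app),
    class = "apparent_trend")
}

#' @export
print.apparent_trend <- function(x, ...) {
  cat(sprintf("<apparent_trend> Ki (from Km_app ~ I) = %.4g; Vmax invariant: %s\n",
              x$Ki_est, x$vmax_invariant))
  invisible(x)
}
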