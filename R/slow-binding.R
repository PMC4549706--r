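# The kobs-based inference chain for slow-binding inhibition:
# kobs ~ [I] regression per substrate level, modality diagnosis from the
# substrate dependence of the apparent constants A and B, and microscopic
# rate constants with Ki = k-0 / k+0.

#' Regress kobs on inhibitor concentration
#'
#' Ordinary least-squares line kobs = B + A * I. The slope A is the apparent
#' association constant and the intercept B the apparent dissociation
#' constant at the substrate level of the underlying curves. Units follow
#' the inhibitor vector supplied: with I in molar, A is in s^-1 M^-1.
#'
#' @param kobs observed rate constants, s^-1.
#' @param I inhibitor concentrations (>= 3 distinct levels).
#' @param se optional standard errors of `kobs`; when supplied and
#'   `weighted = TRUE` an inverse-variance weighted fit is used.
#' @param weighted logical; default unweighted OLS.
#' @param S optional substrate concentration annotation carried in the result.
#' @return object of class `kobs_regression`: `A`, `B`, `se_A`, `se_B`,
#'   `r_squared`, `n`, `S`.
#' @export
regress_kobs_vs_inhibitor <- function(kobs, I, se = NULL, weighted = FALSE,
                                      S = NA_real_) {
  if (length(kobs) != length(I)) stop_input("'kobs' and 'I' must have equal length")
  keep <- is.finite(kobs) & is.finite(I)
  kobs <- kobs[keep]; I <- I[keep]
  if (!is.null(se)) se <- se[keep]
  if (length(unique(I)) < 3) {
    stop_input("insufficient design: need >= 3 distinct inhibitor levels, got %d",
               length(unique(I)))
  }
  w <- if (weighted && !is.null(se) && all(is.finite(se)) && all(se > 0)) {
    1 / se^2
  } else {
    NULL
  }
  fit <- stats::lm(kobs ~ I, weights = w)
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  structure(
    list(A = cf["I", "Estimate"], B = cf["(Intercept)", "Estimate"],
         se_A = cf["I", "Std. Error"], se_B = cf["(Intercept)", "Std. Error"],
         r_squared = sm$r.squared, n = length(kobs), S = S,
         weighted = !is.null(w)),
    class = "kobs_regression")
}

#' @export
print.kobs_regression <- function(x, ...) {
  cat(sprintf("<kobs_regression> A = %.4g +/- %.2g, B = %.4g +/- %.2g (r^2 = %.4f, n = %d)\n",
              x$A, x$se_A, x$B, x$se_B, x$r_squared, x$n))
  invisible(x)
}

#' Tidy a list of kobs regressions into an A/B table
#'
#' @param regressions list of `kobs_regression` objects carrying `S`.
#' @return data frame with columns S, A, B, se_A, se_B, r_squared.
#' @export
ab_table <- function(regressions) {
  do.call(rbind, lapply(regressions, function(r) {
    data.frame(S = r$S, A = r$A, B = r$B, se_A = r$se_A, se_B = r$se_B,
               r_squared = r$r_squared)
  }))
}

#' Diagnose slow-binding modality from the substrate dependence of A and B
#'
#' For a competitive slow-binding inhibitor the apparent association constant
#' A = k+0 / (1 + S/Km) falls with substrate while the apparent dissociation
#' constant B = k-0 stays flat, so 1/A is linear and increasing in S. For a
#' noncompetitive inhibitor neither A nor B depends on S.
#'
#' The verdict is "competitive" when the slope of 1/A versus S is
#' significantly positive (t-test, `alpha`) while B passes both an
#' invariance t-test and a practical-equivalence band (fitted change across
#' the S range below `b_equiv_band` of the mean); "noncompetitive" when
#' neither A nor B shows a significant S trend; otherwise "undetermined",
#' always with the full evidence table.
#'
#' @param ab data frame with columns S, A, B (and optionally se_A, se_B), one
#'   row per substrate level; >= 3 levels required for a verdict.
#' @param alpha significance level for the trend t-tests.
#' @param b_equiv_band practical-equivalence band for B invariance, as a
#'   fraction of mean(B).
#' @return object of class `modality_evidence`: `modality` plus an
#'   `evidence` data frame of tests, statistics and p-values.
#' @export
classify_slow_binding_modality <- function(ab, alpha = 0.05,
                                           b_equiv_band = 0.2) {
  if (nrow(ab) < 3) {
    return(structure(
      list(modality = "undetermined",
           evidence = data.frame(test = "design", statistic = NA_real_,
                                 p_value = NA_real_,
                                 conclusion = "fewer than 3 substrate levels")),
      class = "modality_evidence"))
  }
  if (any(ab$A <= 0)) stop_input("apparent association constants must be positive")

  inv_a <- stats::lm(I(1 / A) ~ S, data = ab)
  cia <- suppressWarnings(summary(inv_a))$coefficients
  p_inv_a <- cia["S", "Pr(>|t|)"]
  a_decreasing <- cia["S", "Estimate"] > 0 && p_inv_a < alpha

  b_fit <- stats::lm(B ~ S, data = ab)
  cb <- suppressWarnings(summary(b_fit))$coefficients
  p_b <- cb["S", "Pr(>|t|)"]
  b_span <- abs(cb["S", "Estimate"]) * diff(range(ab$S)) / mean(ab$B)
  b_invariant <- p_b >= alpha && b_span < b_equiv_band

  modality <- if (a_decreasing && b_invariant) {
    "competitive"
  } else if (!a_decreasing && p_inv_a >= alpha && p_b >= alpha) {
    "noncompetitive"
  } else {
    "undetermined"
  }
  structure(
    list(modality = modality,
         evidence = data.frame(
           test = c("slope(1/A ~ S) > 0", "slope(B ~ S) == 0",
                    "B practical equivalence"),
           statistic = c(cia["S", "Estimate"], cb["S", "Estimate"], b_span),
           p_value = c(p_inv_a, p_b, NA_real_),
           conclusion = c(
             if (a_decreasing) "A decreases with S" else "no significant A trend",
             if (p_b < alpha) "B depends on S" else "no significant B trend",
             if (b_span < b_equiv_band) "B within equivalence band" else "B varies too much"))),
    class = "modality_evidence")
}

#' @export
print.modality_evidence <- function(x, ...) {
  cat(sprintf("<modality_evidence> %s\n", x$modality))
  print(x$evidence, row.names = FALSE)
  invisible(x)
}

#' Test horizontality of kobs across substrate levels
#'
#' At a fixed inhibitor concentration, kobs that does not change with the
#' substrate concentration indicates noncompetitive slow binding with
#' respect to that substrate; a significant negative trend points to
#' competition.
#'
#' @param kobs observed rate constants at a fixed inhibitor level.
#' @param S substrate concentrations (>= 3 levels).
#' @param alpha significance level.
#' @return list with `modality` ("noncompetitive", "competitive" or
#'   "undetermined"), `slope` and `p_value`.
#' @export
test_kobs_horizontality <- function(kobs, S, alpha = 0.05) {
  if (length(unique(S)) < 3) stop_input("need >= 3 substrate levels")
  fit <- stats::lm(kobs ~ S)
  cf <- suppressWarnings(summary(fit))$coefficients
  p <- cf["S", "Pr(>|t|)"]
  slope <- cf["S", "Estimate"]
  modality <- if (p >= alpha) {
    "noncompetitive"
  } else if (slope < 0) {
    "competitive"
  } else {
    "undetermined"
  }
  list(modality = modality, slope = slope, p_value = p)
}

#' Microscopic rate constants from kobs regressions
#'
#' Converts apparent association/dissociation constants (A, B) into the true
#' microscopic constants of one-step slow binding and the inhibition
#' constant Ki = k-0 / k+0.
#'
#' For a noncompetitive inhibitor, k+0 and k-0 equal A and B (pooled across
#' substrate levels by inverse-variance weighting when several regressions
#' are supplied). For a competitive inhibitor, A = k+0 / (1 + S/Km): with
#' `Km` supplied, 1/A is regressed through the origin on (1 + S/Km) so the
#' coefficient is 1/k+0; with `Km = NULL`, the line 1/A = 1/k+0 + S/(k+0 Km)
#' co-estimates Km from its intercept and slope. k-0 is always the
#' inverse-variance weighted mean of B.
#'
#' Units follow the inhibitor units used in the regressions: with I in
#' molar, k+0 is in s^-1 M^-1.
#'
#' @param ab data frame with columns S, A, B (optionally se_A, se_B), as from
#'   [ab_table()]; a single row suffices for noncompetitive.
#' @param modality `"competitive"` or `"noncompetitive"`.
#' @param Km Michaelis constant of the competing substrate (same units as
#'   the S column), or NULL to co-estimate it (competitive, >= 2 levels).
#' @return object of class `microscopic_constants`: `k_plus0`, `k_minus0`,
#'   `Ki`, `modality`, `Km` (supplied or co-estimated).
#' @export
derive_microscopic_constants <- function(ab, modality, Km = NULL) {
  check_modality(modality, allowed = c("competitive", "noncompetitive"))
  if (any(ab$A <= 0)) stop_input("inconsistent data: non-positive A")
  se_A <- if ("se_A" %in% names(ab)) ab$se_A else NULL
  se_B <- if ("se_B" %in% names(ab)) ab$se_B else NULL

  if (modality == "noncompetitive") {
    k_plus0 <- ivw_mean(ab$A, se_A)
    km_out <- Km
  } else {
    if (!is.null(Km)) {
      x <- 1 + ab$S / Km
      k_plus0 <- sum(x * x) / sum(x / ab$A)  # 1/A = x / k+0, origin regression
      km_out <- Km
    } else {
      if (nrow(ab) < 2) {
        stop_input("competitive derivation without Km needs >= 2 substrate levels")
      }
      line <- stats::lm(I(1 / A) ~ S, data = ab)
      cf <- stats::coef(line)
      if (cf[["(Intercept)"]] <= 0 || cf[["S"]] <= 0) {
        stop_input("inconsistent data: 1/A line has non-positive intercept or slope")
      }
      k_plus0 <- 1 / cf[["(Intercept)"]]
      km_out <- cf[["(Intercept)"]] / cf[["S"]]
    }
  }
  k_minus0 <- ivw_mean(ab$B, se_B)
  if (!is.finite(k_plus0) || k_plus0 <= 0 || !is.finite(k_minus0) || k_minus0 <= 0) {
    stop_input("inconsistent data: derived rate constants are not positive")
  }
  structure(
    list(k_plus0 = k_plus0, k_minus0 = k_minus0, Ki = k_minus0 / k_plus0,
         modality = modality, Km = km_out, n_levels = nrow(ab)),
    class = "microscopic_constants")
}

#' @export
print.microscopic_constants <- function(x, ...) {
  cat(sprintf("<microscopic_constants> %s: k+0 = %.4g, k-0 = %.4g, Ki = %.4g (I units)\n",
              x$modality, x$k_plus0, x$k_minus0, x$Ki))
  invisible(x)
}

#' Full slow-binding inference chain for one study
#'
#' Runs the whole pipeline on a set of progress curves: per-curve
#' (v0, vs, kobs) fits, a kobs-versus-[I] regression at every substrate
#' level with at least three positive inhibitor levels, modality diagnosis
#' from the A/B substrate dependence (when three or more substrate levels
#' are available), and microscopic constants.
#'
#' With a single substrate level the A/B diagnosis is impossible; the
#' noncompetitive reduction k+0 = A, k-0 = B is then applied when
#' `modality = "auto"`, which is only exact if independent evidence (e.g. a
#' kobs horizontality test against this substrate) supports noncompetitive
#' binding.
#'
#' @param curves list of [progress_curve()] objects covering an (S, I) grid.
#' @param Km Michaelis constant (molar) of the varied substrate, used in the
#'   competitive derivation; NULL co-estimates it.
#' @param modality `"auto"` (default), `"competitive"` or `"noncompetitive"`.
#' @param alpha significance level for the modality tests.
#' @return object of class `slow_binding_study`: `fits` (tidy data frame),
#'   `regressions` (list of `kobs_regression`), `ab` (A/B table),
#'   `diagnosis` (`modality_evidence` or NULL), `constants`
#'   (`microscopic_constants`).
#' @export
analyze_slow_binding <- function(curves, Km = NULL, modality = "auto",
                                 alpha = 0.05) {
  stopifnot(length(curves) > 0)
  fits <- lapply(curves, fit_progress_curve)
  tidy <- tidy_progress_fits(fits)

  usable <- tidy[tidy$I > 0 & tidy$converged & tidy$slow_binding %in% TRUE, ]
  regressions <- list()
  for (s in sort(unique(usable$S))) {
    sub <- usable[usable$S == s, ]
    if (length(unique(sub$I)) >= 3) {
      regressions[[length(regressions) + 1]] <-
        regress_kobs_vs_inhibitor(sub$kobs, sub$I, se = sub$se_kobs, S = s)
    }
  }
  if (length(regressions) == 0) {
    stop_input("no substrate level has >= 3 inhibitor levels with converged slow-binding fits")
  }
  ab <- ab_table(regressions)

  diagnosis <- NULL
  if (modality == "auto") {
    if (nrow(ab) >= 3) {
      diagnosis <- classify_slow_binding_modality(ab, alpha = alpha)
      modality <- diagnosis$modality
    } else {
      modality <- "noncompetitive"
    }
  }
  constants <- NULL
  constants_error <- NULL
  if (modality %in% c("competitive", "noncompetitive")) {
    constants <- tryCatch(
      derive_microscopic_constants(ab, modality = modality, Km = Km),
      error = function(e) {
        constants_error <<- conditionMessage(e)
        NULL
      })
  }
  structure(
    list(fits = tidy, regressions = regressions, ab = ab,
         diagnosis = diagnosis, constants = constants,
         constants_error = constants_error, modality = modality),
    class = "slow_binding_study")
}

#' @export
print.slow_binding_study <- function(x, ...) {
  cat(sprintf("<slow_binding_study> %d curves, %d kobs regressions, modality: %s\n",
              nrow(x$fits), length(x$regressions), x$modality))
  if (!is.null(x$constants)) print(x$constants)
  invisible(x)
}
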