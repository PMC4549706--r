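# Lightweight S3 containers for assay data. All constructors validate and
# store concentrations in molar and times in seconds.

#' Assay design
#'
#' Describes one kinetic assay layout: which substrate is varied, the
#' substrate and inhibitor concentration grids, and the sampling of each
#' progress trace.
#'
#' @param assay_id short label for the enzyme system, e.g. `"SCR-cytc"`
#'   (succinate-cytochrome c reductase, cytochrome c varied) or
#'   `"DBH2-cytc"` (decylubiquinol-cytochrome c reductase, DBH2 varied).
#' @param varied_substrate name of the varied substrate.
#' @param substrate_concs substrate levels, molar.
#' @param inhibitor_concs inhibitor levels, molar. Either one vector applied
#'   at every substrate level, or a list with one vector per substrate level.
#' @param duration trace duration, s (used by the progress-curve generator).
#' @param n_timepoints samples per trace (>= 4).
#' @return object of class `assay_design`.
#' @export
assay_design <- function(assay_id, varied_substrate, substrate_concs,
                         inhibitor_concs, duration = 300, n_timepoints = 60) {
  check_nonnegative(substrate_concs, "substrate_concs")
  if (is.list(inhibitor_concs)) {
    if (length(inhibitor_concs) != length(substrate_concs)) {
      stop_input("per-substrate 'inhibitor_concs' must have one vector per substrate level")
    }
    lapply(inhibitor_concs, check_nonnegative, name = "inhibitor_concs")
  } else {
    check_nonnegative(inhibitor_concs, "inhibitor_concs")
  }
  check_positive(duration, "duration")
  if (n_timepoints < 4) stop_input("'n_timepoints' must be >= 4")
  structure(
    list(assay_id = assay_id, varied_substrate = varied_substrate,
         substrate_concs = substrate_concs, inhibitor_concs = inhibitor_concs,
         duration = duration, n_timepoints = as.integer(n_timepoints)),
    class = "assay_design"
  )
}

#' @export
print.assay_design <- function(x, ...) {
  ni <- if (is.list(x$inhibitor_concs)) {
    paste(lengths(x$inhibitor_concs), collapse = "/")
  } else {
    length(x$inhibitor_concs)
  }
  cat(sprintf("<assay_design> %s: %d %s levels x %s inhibitor levels, %g s, %d points/trace\n",
              x$assay_id, length(x$substrate_concs), x$varied_substrate, ni,
              x$duration, x$n_timepoints))
  invisible(x)
}

# Inhibitor levels applicable at substrate level i of a design.
#' @noRd
design_inhibitors <- function(design, i) {
  if (is.list(design$inhibitor_concs)) design$inhibitor_concs[[i]] else design$inhibitor_concs
}

#' Progress curve
#'
#' One timed product-formation trace at fixed substrate and inhibitor
#' concentration.
#'
#' @param times sampling times, s; strictly increasing, first >= 0.
#' @param signal product signal at `times` (molar equivalents or any
#'   monotone signal unit).
#' @param S substrate concentration, molar.
#' @param I inhibitor concentration, molar.
#' @param assay_id assay label.
#' @param curve_id trace label, unique within a study.
#' @return object of class `progress_curve`.
#' @export
progress_curve <- function(times, signal, S, I,
                           assay_id = "assay", curve_id = "curve") {
  if (length(times) != length(signal)) {
    stop_input("'times' and 'signal' must have equal length")
  }
  if (times[1] < 0 || any(diff(times) <= 0)) {
    stop_input("'times' must be strictly increasing with times[1] >= 0")
  }
  check_nonnegative(S, "S")
  check_nonnegative(I, "I")
  structure(
    list(times = as.numeric(times), signal = as.numeric(signal),
         S = S, I = I, assay_id = assay_id, curve_id = curve_id),
    class = "progress_curve"
  )
}

#' @export
print.progress_curve <- function(x, ...) {
  cat(sprintf("<progress_curve> %s/%s: %d points over %g s, S = %.3g M, I = %.3g M\n",
              x$assay_id, x$curve_id, length(x$times), max(x$times), x$S, x$I))
  invisible(x)
}

#' Initial-rate table
#'
#' A validated data frame of initial rates on a substrate x inhibitor grid,
#' the input to [fit_inhibition_models()].
#'
#' @param S substrate concentrations, molar (> 0).
#' @param I inhibitor concentrations, molar (>= 0).
#' @param v initial rates (>= 0).
#' @param replicate replicate index.
#' @return data frame of class `rate_table` with columns S, I, v, replicate.
#' @export
rate_table <- function(S, I, v, replicate = 1L) {
  check_positive(S, "S")
  check_nonnegative(I, "I")
  check_nonnegative(v, "v")
  df <- data.frame(S = S, I = I, v = v, replicate = replicate)
  if (length(unique(df$S)) < 2) stop_input("need at least 2 distinct substrate levels")
  class(df) <- c("rate_table", "data.frame")
  df
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("<rate_table> %d rows: %d substrate x %d inhibitor levels\n",
              nrow(x), length(unique(x$S)), length(unique(x$I))))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}
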