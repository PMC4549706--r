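# Hit-to-lead decision layer: candidate enumeration, free-energy threshold
# triage, pesticide-likeness filtering, and calculated-vs-experimental
# correlation.

#' @noRd
.substituent_groups <- c(a = "-F", b = "-Cl", c = "-Br", d = "-NO2",
                         e = "-CH3", f = "-CF3", g = "-OCH3", h = "-OH",
                         i = "-NH2", j = "-COOH")

#' Enumerate substitution candidates
#'
#' Builds the full substitution-scanning candidate set: every combination of
#' scaffold series (1 = CH scaffold, 2 = N analogue), aromatic substitution
#' site (4-7) and substituent group (a-j, i.e. -F, -Cl, -Br, -NO2, -CH3,
#' -CF3, -OCH3, -OH, -NH2, -COOH). Compound numbers are assigned
#' series-major, then site, then group, starting at 2 (compound 1 is the
#' unsubstituted parent hit), so the defaults give compounds 2-41 for
#' series 1 and 42-81 for series 2 — 80 candidates in total.
#'
#' @param sites substitution sites (default 4:7); must be unique.
#' @param groups substituent group letters (default a-j); must be unique.
#' @param series scaffold series (default 1:2); must be unique.
#' @return data frame of class `candidate_set` with columns `compound`,
#'   `series`, `site`, `group`, `substituent`, `label`.
#' @examples
#' nrow(enumerate_candidates())  # 80
#' @export
enumerate_candidates <- function(sites = 4:7, groups = letters[1:10],
                                 series = 1:2) {
  if (anyDuplicated(sites)) stop_input("duplicate site labels")
  if (anyDuplicated(groups)) stop_input("duplicate group labels")
  if (anyDuplicated(series)) stop_input("duplicate series labels")
  grid <- expand.grid(group = groups, site = sites, series = series,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("series", "site", "group")]
  grid$compound <- seq_len(nrow(grid)) + 1L
  grid$substituent <- unname(.substituent_groups[grid$group])
  grid$label <- sprintf("%d-%d%s", grid$series, grid$site, grid$group)
  out <- grid[, c("compound", "series", "site", "group", "substituent", "label")]
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Triage candidates by calculated binding free-energy shift
#'
#' Keeps candidates whose calculated free-energy shift is strictly below the
#' threshold. The default threshold, -1.37 kcal/mol, corresponds to a
#' ten-fold improvement in Ki at 300 K (RT ln 10 = 1.37 kcal/mol); a
#' candidate sitting exactly on the threshold is excluded ("lower than").
#'
#' @param candidates data frame with a `ddG_cal` column (kcal/mol).
#' @param threshold triage threshold, kcal/mol.
#' @return the selected rows sorted ascending by `ddG_cal`, with attributes
#'   `n_selected`, `n_missing` (rows without ddG_cal, excluded with a
#'   warning) and `threshold`.
#' @export
triage_by_ddg <- function(candidates, threshold = -1.37) {
  if (!"ddG_cal" %in% names(candidates)) {
    stop_input("candidates must carry a 'ddG_cal' column")
  }
  missing <- !is.finite(candidates$ddG_cal)
  if (any(missing)) {
    warning(sprintf("%d candidates without ddG_cal excluded", sum(missing)),
            call. = FALSE)
  }
  present <- candidates[!missing, , drop = FALSE]
  sel <- present[present$ddG_cal < threshold, , drop = FALSE]
  sel <- sel[order(sel$ddG_cal), , drop = FALSE]
  attr(sel, "n_selected") <- nrow(sel)
  attr(sel, "n_missing") <- sum(missing)
  attr(sel, "threshold") <- threshold
  sel
}

#' @noRd
.likeness_limits <- c(MW = 435, ClogP = 6, HBA = 6, HBD = 2, ROB = 9, ARB = 17)

#' Pesticide-likeness filter
#'
#' Six-rule physicochemical filter for agrochemical candidates: MW <= 435 Da,
#' ClogP <= 6, H-bond acceptors <= 6, H-bond donors <= 2, rotatable bonds
#' <= 9, aromatic bonds <= 17. Boundary values pass. Descriptors are
#' consumed as inputs; the package does not compute them from structures.
#'
#' @param descriptors data frame (or one-row list) with columns MW, ClogP,
#'   HBA, HBD, ROB, ARB.
#' @param limits named vector of rule limits; defaults to the six above.
#' @return data frame with one logical column per rule (`ok_MW`, ...) and a
#'   `pass` column that is TRUE only when every rule holds.
#' @examples
#' pesticide_likeness(data.frame(MW = 435, ClogP = 6, HBA = 6, HBD = 2,
#'                               ROB = 9, ARB = 17))
#' @export
pesticide_likeness <- function(descriptors, limits = NULL) {
  if (is.null(limits)) limits <- .likeness_limits
  d <- as.data.frame(descriptors)
  for (f in names(limits)) {
    if (!f %in% names(d)) stop_input("missing descriptor '%s'", f)
    if (any(!is.finite(d[[f]]))) stop_input("missing descriptor '%s'", f)
  }
  flags <- lapply(names(limits), function(f) d[[f]] <= limits[[f]])
  names(flags) <- paste0("ok_", names(limits))
  out <- as.data.frame(flags)
  out$pass <- Reduce(`&`, flags)
  out
}

#' Correlation between calculated and experimental free-energy shifts
#'
#' @param ddg_cal,ddg_exp paired shifts, kcal/mol (>= 3 pairs, both with
#'   non-zero variance).
#' @return list with `r_squared` (squared Pearson correlation), `slope`,
#'   `intercept`, `n`.
#' @export
ddg_correlation <- function(ddg_cal, ddg_exp) {
  keep <- is.finite(ddg_cal) & is.finite(ddg_exp)
  x <- ddg_cal[keep]; y <- ddg_exp[keep]
  if (length(x) < 3) stop_input("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_input("zero variance on one axis; correlation undefined")
  }
  fit <- stats::lm(y ~ x)
  list(r_squared = stats::cor(x, y)^2,
       slope = stats::coef(fit)[["x"]],
       intercept = stats::coef(fit)[["(Intercept)"]],
       n = length(x))
}

#' Build potency records relative to a reference inhibitor
#'
#' Combines Ki values with the thermodynamic conversions: binding free
#' energy, shift versus the reference, fold change and ligand efficiency.
#'
#' @param ki inhibition constants, molar.
#' @param ki_ref reference inhibition constant, molar.
#' @param n_heavy optional non-hydrogen atom counts for ligand efficiency.
#' @param ctx a [thermo_context()].
#' @return data frame with columns ki, dG, ddG, fold_change and (when
#'   `n_heavy` is given) LE.
#' @export
potency_record <- function(ki, ki_ref, n_heavy = NULL,
                           ctx = thermo_context()) {
  out <- data.frame(
    ki = ki,
    dG = dg_from_ki(ki, ctx),
    ddG = ddg_from_ki(ki, ki_ref, ctx),
    fold_change = fold_improvement(ki_ref, ki))
  if (!is.null(n_heavy)) out$LE <- ligand_efficiency(ki, n_heavy, ctx)
  out
}
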