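#' Thermodynamic context
#'
#' Bundles the gas constant and absolute temperature used to interconvert
#' inhibition constants and binding free energies. The defaults
#' (R = 1.9872e-3 kcal mol^-1 K^-1, T = 300 K) give RT ln(10) = 1.373
#' kcal/mol, so a 10-fold potency gain corresponds to a free-energy shift of
#' -1.37 kcal/mol at two decimals.
#'
#' @param R gas constant, kcal mol^-1 K^-1.
#' @param T absolute temperature, K.
#' @return An object of class `thermo_context` with elements `R` and `T`.
#' @examples
#' ctx <- thermo_context()
#' ctx$R * ctx$T * log(10)
#' @export
thermo_context <- function(R = 1.9872e-3, T = 300.0) {
  check_positive(R, "R")
  check_positive(T, "T")
  structure(list(R = R, T = T), class = "thermo_context")
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("<thermo_context> R = %g kcal/mol/K, T = %g K (RT = %.4f kcal/mol)\n",
              x$R, x$T, x$R * x$T))
  invisible(x)
}

#' Binding free energy from an inhibition constant
#'
#' dG = RT ln(Ki) with Ki in molar; tighter binders have more negative dG.
#'
#' @param ki inhibition constant, molar.
#' @param ctx a [thermo_context()].
#' @return free energy, kcal mol^-1.
#' @export
dg_from_ki <- function(ki, ctx = thermo_context()) {
  check_positive(ki, "ki")
  ctx$R * ctx$T * log(ki)
}

#' Binding free-energy shift between two inhibition constants
#'
#' ddG = dG(new) - dG(ref) = RT ln(Ki_new / Ki_ref). Negative values mean the
#' new compound binds tighter than the reference. The function is
#' antisymmetric in its arguments and additive along chains of references.
#'
#' @param ki_new,ki_ref inhibition constants in the same (positive) units;
#'   only their ratio enters.
#' @param ctx a [thermo_context()].
#' @return free-energy shift, kcal mol^-1.
#' @examples
#' ddg_from_ki(1, 10)          # 10-fold improvement: about -1.37
#' ddg_from_ki(4.1e-9, 297.6e-9)
#' @export
ddg_from_ki <- function(ki_new, ki_ref, ctx = thermo_context()) {
  check_positive(ki_new, "ki_new")
  check_positive(ki_ref, "ki_ref")
  ctx$R * ctx$T * log(ki_new / ki_ref)
}

#' Fold improvement in potency
#'
#' Ratio Ki_ref / Ki_new; values above 1 mean the new compound is more potent.
#'
#' @param ki_ref,ki_new inhibition constants in the same (positive) units.
#' @return dimensionless fold change.
#' @examples
#' fold_improvement(297.6, 4.1)  # ~73-fold
#' @export
fold_improvement <- function(ki_ref, ki_new) {
  check_positive(ki_ref, "ki_ref")
  check_positive(ki_new, "ki_new")
  ki_ref / ki_new
}

#' Ligand efficiency
#'
#' Binding free-energy magnitude per non-hydrogen atom,
#' LE = -RT ln(Ki) / n_heavy with Ki in molar. A Ki of 1 M or weaker gives a
#' non-positive LE; such values are returned but flagged with a warning.
#'
#' @param ki inhibition constant, molar.
#' @param n_heavy non-hydrogen atom count (>= 1).
#' @param ctx a [thermo_context()].
#' @return kcal mol^-1 per non-H atom.
#' @examples
#' ligand_efficiency(297.6e-9, 30)  # ~0.30
#' @export
ligand_efficiency <- function(ki, n_heavy, ctx = thermo_context()) {
  check_positive(ki, "ki")
  if (any(n_heavy < 1) || any(n_heavy != round(n_heavy))) {
    stop_input("'n_heavy' must be an integer >= 1")
  }
  le <- -dg_from_ki(ki, ctx) / n_heavy
  if (any(le <= 0)) {
    warning("Ki >= 1 M gives non-positive ligand efficiency", call. = FALSE)
  }
  le
}
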