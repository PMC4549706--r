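# Forward kinetic models: the Michaelis-Menten inhibition family, the
# one-step slow-binding progress-curve equation, and the kobs law.
#
# Unit convention throughout the package: concentrations in molar, time in
# seconds, rates in (signal units)/s. The I/O layer converts from the
# micromolar/nanomolar columns used in assay sheets.

MODALITIES <- c("competitive", "noncompetitive", "uncompetitive", "mixed")

#' @noRd
check_modality <- function(modality,
                           allowed = MODALITIES) {
  if (!is.character(modality) || length(modality) != 1L ||
      !(modality %in% allowed)) {
    stop_input("unknown modality '%s' (expected one of: %s)",
               paste(modality, collapse = ","), paste(allowed, collapse = ", "))
  }
  modality
}

#' Michaelis-Menten rate under reversible inhibition
#'
#' Evaluates the steady-state rate law for the four classical inhibition
#' modalities:
#' \describe{
#'   \item{competitive}{v = Vmax S / (Km (1 + I/Ki) + S)}
#'   \item{noncompetitive}{v = Vmax S / ((Km + S)(1 + I/Ki))}
#'   \item{uncompetitive}{v = Vmax S / (Km + S (1 + I/Ki))}
#'   \item{mixed}{v = Vmax S / (Km (1 + I/Kic) + S (1 + I/Kiu))}
#' }
#'
#' @param S substrate concentration, molar (vectorised).
#' @param I inhibitor concentration, molar (vectorised).
#' @param Vmax maximal velocity, rate units.
#' @param Km Michaelis constant, molar.
#' @param Ki inhibition constant, molar (used by all modalities except mixed).
#' @param modality one of `"competitive"`, `"noncompetitive"`,
#'   `"uncompetitive"`, `"mixed"`.
#' @param Kic,Kiu competitive/uncompetitive components for the mixed model.
#' @return rate(s), same length as `S`/`I` after recycling.
#' @examples
#' mm_rate(80e-6, 394.7e-9, Vmax = 1, Km = 80e-6, Ki = 394.7e-9,
#'         modality = "competitive")  # Vmax / 3
#' @export
mm_rate <- function(S, I, Vmax, Km, Ki = NULL, modality,
                    Kic = NULL, Kiu = NULL) {
  check_modality(modality)
  check_nonnegative(S, "S")
  check_nonnegative(I, "I")
  check_positive(Vmax, "Vmax")
  check_positive(Km, "Km")
  if (modality == "mixed") {
    check_positive(Kic, "Kic")
    check_positive(Kiu, "Kiu")
  } else {
    check_positive(Ki, "Ki")
  }
  switch(modality,
    competitive    = Vmax * S / (Km * (1 + I / Ki) + S),
    noncompetitive = Vmax * S / ((Km + S) * (1 + I / Ki)),
    uncompetitive  = Vmax * S / (Km + S * (1 + I / Ki)),
    mixed          = Vmax * S / (Km * (1 + I / Kic) + S * (1 + I / Kiu))
  )
}

#' One-step slow-binding progress curve
#'
#' Integrated product-formation equation for an inhibitor that equilibrates
#' slowly with the enzyme:
#' \deqn{P(t) = v_s t + (v_0 - v_s)(1 - e^{-k_{obs} t}) / k_{obs}}
#' The curve starts with slope `v0`, relaxes with first-order constant
#' `kobs`, and approaches the steady-state slope `vs`. `P(0) = 0`.
#'
#' @param t time, s (vectorised).
#' @param v0 initial rate (slope at t = 0).
#' @param vs steady-state rate (slope as t grows large).
#' @param kobs observed first-order rate constant, s^-1. Must be > 0 unless
#'   `v0 == vs` (linear limit), in which case it is unused.
#' @return product signal at `t`.
#' @examples
#' slow_binding_progress(100, v0 = 1, vs = 0.2, kobs = 0.01)  # 70.57
#' @export
slow_binding_progress <- function(t, v0, vs, kobs) {
  check_nonnegative(t, "t")
  if (v0 == vs) {
    return(v0 * t)  # no slow phase; kobs is unidentifiable and ignored
  }
  check_positive(kobs, "kobs")
  vs * t + (v0 - vs) * (1 - exp(-kobs * t)) / kobs
}

#' Observed rate constant as a function of inhibitor and substrate
#'
#' For one-step slow binding, kobs rises linearly with inhibitor
#' concentration from the dissociation constant k-0. Substrate competition
#' attenuates the association term:
#' \describe{
#'   \item{competitive}{kobs = k-0 + k+0 I / (1 + S/Km)}
#'   \item{noncompetitive}{kobs = k-0 + k+0 I (no S dependence)}
#' }
#'
#' @param I inhibitor concentration, molar (vectorised).
#' @param S substrate concentration, molar (vectorised; ignored for
#'   noncompetitive).
#' @param k_plus0 association rate constant, s^-1 M^-1.
#' @param k_minus0 dissociation rate constant, s^-1.
#' @param Km Michaelis constant of the competing substrate, molar (required
#'   for competitive).
#' @param modality `"competitive"` or `"noncompetitive"`.
#' @return kobs, s^-1.
#' @export
kobs_law <- function(I, S, k_plus0, k_minus0, Km = NULL,
                     modality = c("noncompetitive", "competitive")) {
  if (length(modality) > 1) modality <- modality[1]
  check_modality(modality, allowed = c("competitive", "noncompetitive"))
  check_nonnegative(I, "I")
  check_nonnegative(S, "S")
  check_positive(k_plus0, "k_plus0")
  check_positive(k_minus0, "k_minus0")
  if (modality == "competitive") {
    check_positive(Km, "Km")
    k_minus0 + k_plus0 * I / (1 + S / Km)
  } else {
    k_minus0 + k_plus0 * I + 0 * S
  }
}
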