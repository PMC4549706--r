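# Seeded synthetic-assay generator. The presets reproduce the reference
# experimental designs of the bc1-complex inhibition study conditions:
# succinate-cytochrome c reductase (SCR) assays with cytochrome c varied,
# and decylubiquinol (DBH2)-cytochrome c assays with DBH2 varied.

#' Reference assay designs
#'
#' Named list of the assay layouts used throughout the package's simulation
#' studies (concentrations stored in molar):
#' \describe{
#'   \item{az_dbh2}{DBH2-cytochrome c assay, DBH2 20-120 uM (6 levels),
#'     azoxystrobin 0-5000 nM (6 levels); fast competitive.}
#'   \item{hit_cytc}{SCR assay, cytochrome c 1.13-15.6 uM (6 geometric
#'     levels), hit compound 0-60 nM (5 levels); fast noncompetitive.}
#'   \item{hit_dbh2}{DBH2-cytochrome c assay, DBH2 20-120 uM, hit compound
#'     0-500 nM (6 levels); fast competitive.}
#'   \item{lead_cytc_slow}{SCR assay at fixed cytochrome c 60 uM, lead
#'     compound 0/15/20/30/40/50 nM; slow-binding noncompetitive progress
#'     curves, 300 s, 60 points.}
#'   \item{lead_dbh2_slow}{DBH2-cytochrome c assay, DBH2 20-120 uM with a
#'     per-level inhibitor ladder of 5 evenly spaced levels from 0 up to
#'     (60 + DBH2[uM]) nM — 0-80 nM at 20 uM up to 0-180 nM at 120 uM;
#'     slow-binding competitive progress curves, 400 s, 60 points.}
#' }
#'
#' @return named list of [assay_design()] objects.
#' @export
reference_designs <- function() {
  s_dbh2 <- seq(20, 120, by = 20) * 1e-6
  list(
    az_dbh2 = assay_design(
      "DBH2-cytc", "DBH2", s_dbh2,
      c(0, 500, 1000, 2000, 3000, 5000) * 1e-9),
    hit_cytc = assay_design(
      "SCR-cytc", "cytochrome c",
      exp(seq(log(1.13e-6), log(15.6e-6), length.out = 6)),
      c(0, 10, 20, 40, 60) * 1e-9),
    hit_dbh2 = assay_design(
      "DBH2-cytc", "DBH2", s_dbh2,
      c(0, 50, 100, 200, 300, 500) * 1e-9),
    lead_cytc_slow = assay_design(
      "SCR-cytc", "cytochrome c", 60e-6,
      c(0, 15, 20, 30, 40, 50) * 1e-9,
      duration = 300, n_timepoints = 60),
    lead_dbh2_slow = assay_design(
      "DBH2-cytc", "DBH2", s_dbh2,
      lapply(s_dbh2, function(s) seq(0, (60 + s * 1e6) * 1e-9, length.out = 5)),
      duration = 400, n_timepoints = 60)
  )
}

#' Reference kinetic truths
#'
#' True parameter sets paired with [reference_designs()], used as generator
#' defaults in recovery studies. Rate constants in molar-seconds units
#' (k+0 in s^-1 M^-1; 6.6e5 s^-1 M^-1 = 0.00066 s^-1 nM^-1).
#'
#' @return named list of truth lists.
#' @export
reference_truths <- function() {
  list(
    az_dbh2 = list(mechanism = "fast-competitive",
                   Vmax = 1e-7, Km = 80e-6, Ki = 394.7e-9),
    hit_cytc = list(mechanism = "fast-noncompetitive",
                    Vmax = 1e-7, Km = 4.3e-6, Ki = 31.1e-9),
    hit_dbh2 = list(mechanism = "fast-competitive",
                    Vmax = 1e-7, Km = 80e-6, Ki = 96.5e-9),
    lead_cytc_slow = list(mechanism = "slow-binding-noncompetitive",
                          k_plus0 = 6.6e5, k_minus0 = 0.00271,
                          Vmax = 1e-8, Km = NULL),
    lead_dbh2_slow = list(mechanism = "slow-binding-competitive",
                          k_plus0 = 3.8e5, k_minus0 = 0.00509,
                          Vmax = 1e-8, Km = 80e-6)
  )
}

#' @noRd
.fast_mechanisms <- c("fast-competitive", "fast-noncompetitive",
                      "fast-uncompetitive", "fast-mixed")
#' @noRd
.slow_mechanisms <- c("slow-binding-competitive", "slow-binding-noncompetitive")

#' Generate a synthetic initial-rate table
#'
#' Draws rates on the design's (S, I) grid from the selected fast-binding
#' rate law, with seeded Gaussian noise: proportional
#' (v = v_true (1 + eps), the default with sigma = 0.03) or additive
#' (v = v_true + eps, sigma in rate units). Negative draws are clamped at 0.
#'
#' @param design an [assay_design()].
#' @param truth list with `mechanism` (one of the fast mechanisms), `Vmax`,
#'   `Km`, and `Ki` (or `Kic`/`Kiu` for fast-mixed).
#' @param noise list with `model` ("proportional" or "additive") and `sigma`.
#' @param seed integer seed; the same design, truth and seed always yield
#'   the same table.
#' @param replicates replicate draws per grid point.
#' @return a [rate_table()] with the truth attached as attribute `"truth"`.
#' @export
generate_rate_table <- function(design, truth,
                                noise = list(model = "proportional", sigma = 0.03),
                                seed = 1L, replicates = 1L) {
  if (truth$mechanism %in% .slow_mechanisms) {
    stop_input("slow-binding mechanism: use generate_progress_curves()")
  }
  if (!truth$mechanism %in% .fast_mechanisms) {
    stop_input("unknown mechanism '%s'", truth$mechanism)
  }
  modality <- sub("^fast-", "", truth$mechanism)
  grid <- expand.grid(S = design$substrate_concs,
                      I = if (is.list(design$inhibitor_concs)) {
                        unique(unlist(design$inhibitor_concs))
                      } else {
                        design$inhibitor_concs
                      },
                      replicate = seq_len(replicates))
  v_true <- mm_rate(grid$S, grid$I, Vmax = truth$Vmax, Km = truth$Km,
                    Ki = truth$Ki, modality = modality,
                    Kic = truth$Kic, Kiu = truth$Kiu)
  check_nonnegative(noise$sigma, "noise$sigma")
  v <- local_seed(seed, {
    eps <- stats::rnorm(length(v_true), 0, noise$sigma)
    if (identical(noise$model, "additive")) v_true + eps else v_true * (1 + eps)
  })
  out <- rate_table(grid$S, grid$I, pmax(v, 0), grid$replicate)
  attr(out, "truth") <- c(truth, list(noise = noise, seed = seed,
                                      assay_id = design$assay_id))
  out
}

#' Generate synthetic slow-binding progress curves
#'
#' Builds one progress curve per (S, I) point of the design. The
#' uninhibited initial rate follows the substrate saturation curve
#' v0 = Vmax S/(Km + S) (or v0 = Vmax when the truth carries no Km, e.g. a
#' fixed-substrate assay); kobs comes from [kobs_law()] and the steady-state
#' rate from the one-step identity vs = v0 k-0 / kobs, so the generated
#' curves satisfy vs = v0 / (1 + I/Ki_app) by construction. Curves at I = 0
#' are exactly linear before noise. Additive Gaussian noise with standard
#' deviation `sigma_frac` of each curve's final (noiseless) signal is added
#' point-wise.
#'
#' @param design an [assay_design()]; per-substrate inhibitor ladders are
#'   honoured.
#' @param truth list with `mechanism` (slow-binding-competitive or
#'   slow-binding-noncompetitive), `k_plus0` (s^-1 M^-1), `k_minus0` (s^-1),
#'   `Vmax` (rate scale), and `Km` (molar; required for competitive).
#' @param noise list with `sigma_frac` (default 0.02).
#' @param seed integer seed.
#' @return list of [progress_curve()] objects with a per-curve truth
#'   manifest (data frame) attached as attribute `"truth"`.
#' @export
generate_progress_curves <- function(design, truth,
                                     noise = list(sigma_frac = 0.02),
                                     seed = 1L) {
  if (!truth$mechanism %in% .slow_mechanisms) {
    stop_input("fast mechanism: use generate_rate_table()")
  }
  modality <- sub("^slow-binding-", "", truth$mechanism)
  if (modality == "competitive") check_positive(truth$Km, "truth$Km")
  times <- seq(0, design$duration, length.out = design$n_timepoints)

  curves <- list()
  manifest <- list()
  local_seed(seed, {
    for (si in seq_along(design$substrate_concs)) {
      S <- design$substrate_concs[si]
      v0 <- if (is.null(truth$Km)) {
        truth$Vmax
      } else {
        truth$Vmax * S / (truth$Km + S)
      }
      for (I in design_inhibitors(design, si)) {
        if (I == 0) {
          p <- v0 * times
          kobs <- NA_real_
          vs <- v0
        } else {
          kobs <- kobs_law(I, S, truth$k_plus0, truth$k_minus0,
                           Km = truth$Km, modality = modality)
          if (kobs * design$duration < 1) {
            warning(sprintf(
              "kobs * duration = %.2f < 1 at S = %.3g, I = %.3g: steady state not reached within the trace",
              kobs * design$duration, S, I), call. = FALSE)
          }
          vs <- v0 * truth$k_minus0 / kobs
          p <- slow_binding_progress(times, v0, vs, kobs)
        }
        sd_noise <- noise$sigma_frac * max(p)
        y <- p + stats::rnorm(length(p), 0, sd_noise)
        id <- sprintf("S%.3g_I%.3g", S, I)
        curves[[length(curves) + 1L]] <-
          progress_curve(times, y, S, I, assay_id = design$assay_id,
                         curve_id = id)
        manifest[[length(manifest) + 1L]] <-
          data.frame(curve_id = id, S = S, I = I, v0 = v0, vs = vs,
                     kobs = kobs, sigma = sd_noise)
      }
    }
  })
  attr(curves, "truth") <- do.call(rbind, manifest)
  attr(curves, "params") <- c(truth, list(seed = seed, noise = noise))
  curves
}
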