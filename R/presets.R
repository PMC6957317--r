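#' Kinetic parameter set for a simulated nuclear factor
#'
#' Bundles the ground-truth kinetic parameters of one experimental
#' condition: the stationary bound-state occupancy, the free and bound
#' diffusion coefficients, the mean dwell times of the short- and
#' long-lived bound states, and the probability that a binding event is
#' long-lived. Optional `region_modifiers` override `F_bound` and/or
#' `f_long_event` inside heterochromatin vs euchromatin when a chromatin
#' map is supplied to the simulator.
#'
#' @param name label for the condition.
#' @param F_bound stationary probability of being bound, in `[0, 1)`.
#'   `F_bound = 0` denotes a pure-free species (allowed in simulation,
#'   rejected by [derive_rates()]).
#' @param D_free free-state diffusion coefficient (µm²/s).
#' @param D_bound bound-state diffusion coefficient (µm²/s); small but
#'   non-zero by default so bound molecules show realistic localization
#'   jitter.
#' @param tau_short_s,tau_long_s mean dwell times (s) of short- and
#'   long-lived binding events; `tau_long_s >= tau_short_s > 0`.
#' @param f_long_event probability that a binding event is long-lived.
#' @param region_modifiers optional named list with elements
#'   `heterochromatin` and/or `euchromatin`, each a list possibly holding
#'   `F_bound` and `f_long_event` overrides and/or a `D_free_mult`
#'   multiplier on the free diffusion coefficient. Modifiers take effect
#'   only when the simulation carries a chromatin map.
#' @return An object of class `kinetic_preset`.
#' @seealso [preset_catalog()], [derive_rates()], [simulate_cell()]
#' @export
kinetic_preset <- function(name, F_bound, D_free, D_bound = 0.005,
                           tau_short_s = 2, tau_long_s = 7,
                           f_long_event = 0.25, region_modifiers = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(F_bound) || F_bound < 0 || F_bound >= 1)
    stop("F_bound must lie in [0, 1)")
  if (!(D_bound >= 0 && D_bound < D_free))
    stop("need 0 <= D_bound < D_free")
  if (!(tau_short_s > 0 && tau_long_s >= tau_short_s))
    stop("need tau_long_s >= tau_short_s > 0")
  if (f_long_event < 0 || f_long_event > 1)
    stop("f_long_event must lie in [0, 1]")
  structure(list(name = name, F_bound = F_bound, D_free = D_free,
                 D_bound = D_bound, tau_short_s = tau_short_s,
                 tau_long_s = tau_long_s, f_long_event = f_long_event,
                 region_modifiers = region_modifiers),
            class = "kinetic_preset")
}

#' @export
print.kinetic_preset <- function(x, ...) {
  cat(sprintf("<kinetic_preset> %s\n", x$name))
  cat(sprintf("  F_bound %.3g | D_free %.3g | D_bound %.3g um^2/s\n",
              x$F_bound, x$D_free, x$D_bound))
  cat(sprintf("  tau_short %.3g s | tau_long %.3g s | f_long_event %.3g\n",
              x$tau_short_s, x$tau_long_s, x$f_long_event))
  if (!is.null(x$region_modifiers)) cat("  (with region modifiers)\n")
  invisible(x)
}

#' Transition rates implied by a kinetic preset
#'
#' Converts the occupancy/dwell parameterization of a [kinetic_preset()]
#' into the rate constants of the underlying three-state Markov chain.
#' The off-rates are the reciprocal dwell times, and the binding rate is
#' chosen so that the stationary bound occupancy equals `F_bound`:
#' `k_on = F_bound / ((1 - F_bound) * E[tau_b])` with
#' `E[tau_b] = f_long_event * tau_long_s + (1 - f_long_event) * tau_short_s`.
#'
#' @param preset a [kinetic_preset()].
#' @return A list with `k_on`, `k_off_short`, `k_off_long`,
#'   `mean_bound_dwell_s` and the implied `F_bound` (equal to the preset's).
#' @examples
#' derive_rates(kinetic_preset("wt", 0.55, 1.0))
#' @export
derive_rates <- function(preset) {
  stopifnot(inherits(preset, "kinetic_preset"))
  F <- preset$F_bound
  if (F <= 0 || F >= 1)
    stop("degenerate chain: F_bound must lie strictly in (0, 1)")
  e_tau <- preset$f_long_event * preset$tau_long_s +
    (1 - preset$f_long_event) * preset$tau_short_s
  k_on <- F / ((1 - F) * e_tau)
  list(k_on = k_on,
       k_off_short = 1 / preset$tau_short_s,
       k_off_long = 1 / preset$tau_long_s,
       mean_bound_dwell_s = e_tau,
       F_bound = k_on * e_tau / (1 + k_on * e_tau))
}

#' Catalog of ground-truth presets for the studied conditions
#'
#' Returns the named kinetic parameter sets used throughout the package:
#' wild-type MeCP2 in cultured cerebellar granule cells, the
#' DNA-modification mutants (Dnmt3a cKO, Tet1/2/3 cKO), the Rett-syndrome
#' MBD point mutants (R106W, R133C), the minimal MBD+NLS constructs, the
#' reference nuclear factors (histone H2b, free NLS, Sox2, TBP, linker
#' histone H1.0) and the acute-slice granule vs Purkinje-cell conditions.
#' The wild-type granule-cell preset carries heterochromatin/euchromatin
#' modifiers of the long-lived event fraction (0.30 vs 0.20, identical
#' dwell times) for region-stratified simulations.
#'
#' @return Named list of [kinetic_preset()] objects.
#' @export
preset_catalog <- function() {
  het_mod <- list(heterochromatin = list(f_long_event = 0.30),
                  euchromatin = list(f_long_event = 0.20))
  p <- list(
    kinetic_preset("MeCP2_GC_WT", 0.55, 1.0, region_modifiers = het_mod),
    kinetic_preset("MeCP2_Dnmt3a_cKO", 0.45, 1.0),
    kinetic_preset("MeCP2_Tets_cKO", 0.60, 1.0),
    kinetic_preset("MeCP2_R106W", 0.15, 1.4),
    kinetic_preset("MeCP2_R133C", 0.55, 1.2),
    kinetic_preset("MeCP2_minimal", 0.55, 1.5),
    kinetic_preset("MeCP2_minimal_R106W", 0.05, 2.0),
    kinetic_preset("NLS", 0.15, 4.0),
    kinetic_preset("H2b", 0.85, 0.5, tau_long_s = 300, f_long_event = 0.9),
    kinetic_preset("Sox2", 0.30, 2.0, tau_long_s = 10),
    kinetic_preset("TBP", 0.35, 1.5, tau_long_s = 14),
    kinetic_preset("H1.0", 0.50, 1.0, tau_long_s = 10),
    kinetic_preset("MeCP2_GC_slice", 0.70, 1.0),
    kinetic_preset("MeCP2_PC", 0.60, 2.0))
  setNames(p, vapply(p, `[[`, "", "name"))
}
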