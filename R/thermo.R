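#' Physical constants for the thermochemical layer
#'
#' CODATA values of the Boltzmann, Planck and gas constants together with
#' the conventions used to turn computed aqueous free energies into pKa
#' values: the aqueous-phase proton free energy (-265.9 kcal/mol) and the
#' standard-state correction from 1 atm to 1 M (1.89 kcal/mol).
#'
#' @param temperature Absolute temperature in K (default 298.15, i.e.
#'   25 degrees C).
#' @return List with elements `temperature` (K), `boltzmann` (J/K),
#'   `planck` (J s), `gas_constant_kcal` (kcal/(mol K)),
#'   `proton_aqueous_free_energy` (kcal/mol),
#'   `standard_state_correction` (kcal/mol) and `hartree_to_kcal`.
#' @export
thermo_constants <- function(temperature = 298.15) {
  stopifnot(temperature > 0)
  list(
    temperature = temperature,
    boltzmann = 1.380649e-23,
    planck = 6.62607015e-34,
    gas_constant_kcal = 1.987204258640832e-3,
    proton_aqueous_free_energy = -265.9,
    standard_state_correction = 1.89,
    hartree_to_kcal = 627.5095
  )
}

#' Rate constant from an activation free energy (Eyring equation)
#'
#' `k = (k_B T / h) exp(-dG / (R T))` with transmission coefficient 1.
#'
#' @param barrier Activation free energy in kcal/mol.
#' @param temperature Temperature in K.
#' @return Rate constant in 1/s.
#' @seealso [eyring_barrier()] for the inverse.
#' @export
eyring_rate <- function(barrier, temperature = 298.15) {
  cc <- thermo_constants(temperature)
  prefactor <- cc$boltzmann * temperature / cc$planck
  prefactor * exp(-barrier / (cc$gas_constant_kcal * temperature))
}

#' Activation free energy from a rate constant (inverse Eyring)
#'
#' `dG = R T ln(k_B T / (h k))`.
#'
#' @param rate Rate constant in 1/s, > 0.
#' @param temperature Temperature in K.
#' @return Activation free energy in kcal/mol.
#' @export
eyring_barrier <- function(rate, temperature = 298.15) {
  if (any(rate <= 0)) stop("rate must be > 0")
  cc <- thermo_constants(temperature)
  prefactor <- cc$boltzmann * temperature / cc$planck
  cc$gas_constant_kcal * temperature * log(prefactor / rate)
}

#' pKa of a hydroxyl from computed aqueous free energies
#'
#' For the deprotonation `ROH -> RO- + H+` the reaction free energy is
#' `dG = G(anion) + G(H+, aq) - G(neutral) + dG(1 atm -> 1 M)`, with the
#' aqueous proton free energy and the standard-state correction taken
#' from [thermo_constants()]; then `pKa = dG / (ln(10) R T)`.
#'
#' @param g_neutral,g_anion Aqueous free energies of the protonated and
#'   deprotonated species.
#' @param constants A [thermo_constants()] list.
#' @param unit `"kcal"` (default) or `"hartree"` (auto-converted).
#' @return pKa value(s), unitless.
#' @export
pka_from_free_energies <- function(g_neutral, g_anion,
                                   constants = thermo_constants(),
                                   unit = c("kcal", "hartree")) {
  unit <- match.arg(unit)
  if (unit == "hartree") {
    g_neutral <- g_neutral * constants$hartree_to_kcal
    g_anion <- g_anion * constants$hartree_to_kcal
  }
  dg <- g_anion + constants$proton_aqueous_free_energy - g_neutral +
    constants$standard_state_correction
  dg / (log(10) * constants$gas_constant_kcal * constants$temperature)
}

#' pKa uncertainty from a free-energy error
#'
#' Propagates a free-energy error (e.g. the 1-2 kcal/mol DFT error) to
#' pKa units through the same linear relation as
#' [pka_from_free_energies()]: `d pKa = dG_err / (ln(10) R T)`.
#'
#' @param dg_error Free-energy error in kcal/mol.
#' @param constants A [thermo_constants()] list.
#' @return Error in pKa units.
#' @export
pka_uncertainty <- function(dg_error, constants = thermo_constants()) {
  dg_error / (log(10) * constants$gas_constant_kcal * constants$temperature)
}

#' Formal rate constants of a stepwise migration
#'
#' An acetyl migration proceeds in two elementary steps through an
#' orthoester intermediate: formation (`k_a`, reverse `k_minus_a`) and
#' breakdown (`k_b`, reverse `k_minus_b`).  Applying the steady-state
#' approximation to the transient intermediate collapses the two barriers
#' into formal one-step constants
#' `k_forward = k_a k_b / (k_minus_a + k_b)` and
#' `k_reverse = k_minus_a k_minus_b / (k_minus_a + k_b)`.
#'
#' @param k_a,k_minus_a,k_b,k_minus_b Elementary rate constants in 1/s,
#'   all > 0.
#' @return Named numeric vector `c(k_forward, k_reverse)` in 1/s.
#' @export
formal_constants <- function(k_a, k_minus_a, k_b, k_minus_b) {
  if (any(c(k_a, k_minus_a, k_b, k_minus_b) <= 0)) {
    stop("all elementary rate constants must be > 0")
  }
  denom <- k_minus_a + k_b
  c(k_forward = k_a * k_b / denom,
    k_reverse = k_minus_a * k_minus_b / denom)
}

#' Observed (pH-dependent) rate constant of an anionic migration
#'
#' The anionic mechanism runs through the deprotonated hydroxyl, so the
#' macroscopic observed constant is the formal constant weighted by the
#' anion fraction given by the Henderson-Hasselbalch relation:
#' `k_obs = k_formal * 10^(ph - pka) / (1 + 10^(ph - pka))`.
#'
#' @param k_formal Formal rate constant of the anionic path (1/s).
#' @param pka pKa of the accepting hydroxyl.
#' @param ph Solution pH.
#' @return Observed rate constant in 1/s.
#' @export
observed_rate <- function(k_formal, pka, ph) {
  stopifnot(is.finite(k_formal), is.finite(pka), is.finite(ph))
  frac <- 10^(ph - pka) / (1 + 10^(ph - pka))
  k_formal * frac
}

#' Convert a rate constant between 1/h and 1/s
#'
#' @param rate Rate constant value(s).
#' @param from,to Units, each `"h-1"` or `"s-1"`.
#' @return Converted value(s); exact factor 3600.
#' @export
rate_unit_convert <- function(rate, from, to) {
  units <- c("h-1", "s-1")
  if (!from %in% units || !to %in% units) {
    stop("units must be one of: ", paste(units, collapse = ", "))
  }
  if (from == to) return(rate)
  if (from == "h-1") rate / 3600 else rate * 3600
}

#' Thermochemical record of one rate constant
#'
#' @param label Constant label (e.g. `"k2_obs"`).
#' @param rate_constant Rate constant in 1/s, > 0.
#' @param kind One of `"formal_anionic"`, `"observed"`,
#'   `"predicted_observed"`.
#' @param temperature Temperature in K.
#' @param pka Optional associated hydroxyl pKa.
#' @return Object of class `migkin_thermo_record` carrying the Eyring
#'   barrier consistent with the rate at the record's temperature.
#' @export
thermo_record <- function(label, rate_constant,
                          kind = c("observed", "predicted_observed",
                                   "formal_anionic"),
                          temperature = 298.15, pka = NULL) {
  kind <- match.arg(kind)
  stopifnot(rate_constant > 0)
  structure(
    list(label = label, rate_constant = rate_constant,
         barrier = eyring_barrier(rate_constant, temperature),
         kind = kind, temperature = temperature, pka = pka),
    class = "migkin_thermo_record"
  )
}

#' Barrier gap between an experimental and a predicted rate constant
#'
#' Difference of activation free energies, predicted minus experimental,
#' each recomputed from the record's rate constant via [eyring_barrier()].
#' Positive values mean the prediction is slower than observed.
#'
#' @param experimental,predicted `migkin_thermo_record`s with the same
#'   label.
#' @return Barrier gap in kcal/mol.
#' @export
barrier_gap <- function(experimental, predicted) {
  stopifnot(inherits(experimental, "migkin_thermo_record"),
            inherits(predicted, "migkin_thermo_record"))
  if (!identical(experimental$label, predicted$label)) {
    stop("record labels differ: '", experimental$label, "' vs '",
         predicted$label, "'")
  }
  eyring_barrier(predicted$rate_constant, predicted$temperature) -
    eyring_barrier(experimental$rate_constant, experimental$temperature)
}
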