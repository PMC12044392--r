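# Membrane flux laws: ground electrodiffusive leaks, PIEZO1, Na/K pump,
# PMCA, Gardos channel, optional K:Cl cotransport.

#' Constant-field (Goldman) electrodiffusive flux
#'
#' `J = -P * u * (Ci - Co*exp(-u)) / (1 - exp(-u))` with
#' `u = z*F*Em/RT`; the sign convention is net influx positive (efflux
#' negative), matching the per-species flux columns of the simulator. The
#' singular limit u -> 0 is handled by series expansion, so at `Em = 0`
#' the flux reduces to `P * (Co - Ci)`.
#'
#' @param P permeability, h^-1 (>= 0).
#' @param z valence.
#' @param Em membrane potential, mV.
#' @param Ci,Co intracellular (mmol/Lcw) and plasma (mmol/L)
#'   concentrations.
#' @return net flux, mmol/Loch, influx positive.
#' @examples
#' goldman_flux(1.3, -1, 0, 80, 125)        # zero-field limit
#' goldman_flux(1, 1, nernst(130, 5), 130, 5)  # zero at Nernst equilibrium
#' @export
goldman_flux <- function(P, z, Em, Ci, Co) {
  if (any(P < 0)) stop("permeability must be non-negative")
  mapply(.cpp_ghk, P, z, Em, Ci, Co)
}

#' Na/K pump fluxes
#'
#' Forward extrusion with a cubic intracellular Na site whose apparent
#' affinity is competitively inhibited by intracellular K (the normal high
#' cell K strongly inhibits the pump; relief of this inhibition as K falls
#' drives the rising pump activity of phase 1), an Mg2+ activation factor
#' with half-activation at `KMg` = 50 umol/Lcw, and the multiplicative
#' inhibition factor used to trigger phase 3:
#' `JNa = -Fmax * inh * [CNa/(CNa + KmNa*(1 + CK/KiK))]^3 * MgF/(MgF+KMg)`
#' with `JK = -(2/3) * JNa` (3:2 stoichiometry, electrogenic).
#'
#' @param CNa,CK intracellular Na and K, mmol/Lcw.
#' @param MgF free [Mg2+]i, mmol/Lcw.
#' @param params packed parameter vector.
#' @return named vector `c(JNa_pump, JK_pump)`, mmol/Loch.
#' @export
na_pump_flux <- function(CNa, CK, MgF, params) {
  .cpp_na_pump(CNa, CK, MgF, unclass(params))
}

#' Plasma membrane calcium pump (PMCA) flux
#'
#' Saturating Michaelis extrusion `J = -Fmax * CaF / (CaF + KmCa)`.
#'
#' @param CaF free [Ca2+]i, mmol/Lcw.
#' @param params packed parameter vector.
#' @return Ca2+ flux, mmol/Loch (<= 0).
#' @export
pmca_flux <- function(CaF, params) {
  .cpp_pmca(CaF, unclass(params))
}

#' Gardos (KCNN4) channel flux
#'
#' Ca2+-activated K+ permeability with Hill kinetics,
#' `PK = PKmax * CaF^h / (CaF^h + K05Ca^h)`, driving a Goldman K+ flux.
#' Zero at resting calcium; zero net flux once the K gradient is
#' exhausted even with the channel fully open.
#'
#' @param CaF free [Ca2+]i, mmol/Lcw.
#' @param CK intracellular K, mmol/Lcw.
#' @param CKo plasma K, mmol/L.
#' @param Em membrane potential, mV.
#' @param params packed parameter vector.
#' @return K+ flux, mmol/Loch.
#' @export
gardos_flux <- function(CaF, CK, CKo, Em, params) {
  pk <- .cpp_gardos_perm(CaF, unclass(params))
  .cpp_ghk(pk, 1, Em, CK, CKo)
}

#' Gardos channel effective permeability
#' @inheritParams gardos_flux
#' @return Ca-activated K permeability, h^-1.
#' @export
gardos_perm <- function(CaF, params) {
  .cpp_gardos_perm(CaF, unclass(params))
}

#' PIEZO1 open-state flux contributions
#'
#' When HbS is deoxygenated the channel opens instantly with poor
#' selectivity, adding Goldman terms for Ca2+, Mg2+, Na+, K+ and A- with
#' permeabilities `amplitude * Pz_species`; the amplitude factor varies
#' randomly between successive deoxy transits. On reoxygenation the
#' contribution is identically zero (spontaneous inactivation restored).
#'
#' @param state a [cell_state()] (the `oxy` flag gates the channel).
#' @param params packed parameter vector.
#' @param amplitude dimensionless amplitude factor (>= 0).
#' @return named vector of PIEZO1-mediated fluxes, mmol/Loch.
#' @export
piezo_fluxes <- function(state, params, amplitude = 1) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  open <- as_state_vector(state)[["oxy"]] < 0.5
  fl <- .cpp_fluxes(as_state_vector(state), unclass(params), amplitude, open)
  fl[c("JNa_piezo", "JK_piezo", "JA_piezo", "JCa_piezo", "JMg_piezo")]
}

#' K:Cl cotransport flux
#'
#' Electroneutral coupled flux proportional to the product gradient,
#' `J = -kcl_rate * (CK*CA - CKo*CAo) / CAo`, with equal K and A
#' components. Off by default (`kcl_rate = 0`): its contribution to ISC
#' dehydration is negligible next to the PIEZO1-Gardos cascade.
#'
#' @param CK,CA intracellular concentrations, mmol/Lcw.
#' @param CKo,CAo plasma concentrations, mmol/L.
#' @param params packed parameter vector.
#' @return named vector `c(JK, JA)`, mmol/Loch.
#' @export
kcl_flux <- function(CK, CA, CKo, CAo, params) {
  r <- unclass(params)[["kcl_rate"]]
  j <- -r * (CK * CA - CKo * CAo) / CAo
  c(JK = j, JA = j)
}

#' All membrane fluxes of a state
#'
#' Evaluates every pathway (ground leaks, PIEZO1, Na/K pump, PMCA,
#' Gardos, K:Cl) at the given state and returns the per-pathway
#' decomposition together with the per-species totals. The decomposition
#' sums exactly to the species totals.
#'
#' @param state a [cell_state()].
#' @param params packed parameter vector.
#' @param amplitude PIEZO1 amplitude factor.
#' @param piezo_open logical; if `NULL` (default) the channel is open
#'   exactly when the state is deoxygenated.
#' @return named vector of fluxes, mmol/Loch, influx positive.
#' @export
cell_fluxes <- function(state, params, amplitude = 1, piezo_open = NULL) {
  v <- as_state_vector(state)
  if (is.null(piezo_open)) piezo_open <- v[["oxy"]] < 0.5
  .cpp_fluxes(v, unclass(params), amplitude, piezo_open)
}

#' Zero-current membrane potential
#'
#' Solves the potential at which the Goldman leak currents (including
#' open-channel PIEZO1 and Gardos permeabilities) plus the electrogenic
#' pump currents (net 1/3 of the Na-pump Na flux, plus 2x the PMCA flux)
#' sum to zero. With the anion permeability dominant this is within ~1 mV
#' of the anion Nernst potential EA.
#'
#' @inheritParams cell_fluxes
#' @return membrane potential, mV.
#' @export
solve_em <- function(state, params, amplitude = 1, piezo_open = NULL) {
  v <- as_state_vector(state)
  if (is.null(piezo_open)) piezo_open <- v[["oxy"]] < 0.5
  .cpp_em_solve(v, unclass(params), amplitude, piezo_open)
}
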