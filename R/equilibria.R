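# Fast algebraic sub-solvers applied after every flux step.

#' Net charge on hemoglobin (Dalmark titration line)
#'
#' `nHb = alpha * (pHi - pI)` with `alpha = -8` Eq/mol per pH unit for
#' HbS, so the charge is negative above the isoelectric point and becomes
#' slightly positive as acidified cells fall below it.
#'
#' @param pHi intracellular pH.
#' @param pI isoelectric point of hemoglobin at 37 C (oxy or deoxy value).
#' @param alpha proton titration slope, Eq/(mol * pH unit).
#' @return net charge on hemoglobin, Eq/mol.
#' @examples
#' hb_charge(6.4, 7.4)   # +8 Eq/mol in a deeply acidified deoxy cell
#' @export
hb_charge <- function(pHi, pI, alpha = -8) {
  mapply(.cpp_hb_charge, pHi, pI, alpha)
}

#' Osmotic coefficient of hemoglobin
#'
#' Virial expansion `fHb = 1 + b1*CHb + b2*CHb^2`; the osmotic
#' contribution of hemoglobin is `fHb * CHb` (mOsmol/Lcw), a steep power
#' function of concentration responsible for the colloid-osmotic
#' nonlinearity of dehydrating cells.
#'
#' @param CHb hemoglobin concentration, mmol/Lcw (must be >= 0).
#' @param b1,b2 virial coefficients, Lcw/mmol and (Lcw/mmol)^2.
#' @return dimensionless osmotic coefficient, >= 1.
#' @export
hb_osmotic_coeff <- function(CHb, b1 = 0.0645, b2 = 0.0258) {
  if (any(CHb < 0)) stop("CHb must be non-negative")
  mapply(.cpp_fhb, CHb, b1, b2)
}

#' Free ionized magnesium from total content
#'
#' Solves the 1:1 mass-action system for free Mg2+ given the total cell
#' magnesium and the ATP and 2,3-BPG buffer pools. Deoxygenation raises
#' the effective dissociation constants (deoxy-Hb sequesters ATP and
#' 2,3-BPG), releasing Mg2+ during deoxy transits.
#'
#' @param QMgT total magnesium content, mmol/Loc.
#' @param Vw cell water volume, Lcw/Loc.
#' @param params packed parameter vector (from [build_reference_state()]).
#' @param oxy logical oxygenation state (selects the effective Kd's).
#' @return free [Mg2+]i, mmol/Lcw.
#' @export
mg_free <- function(QMgT, Vw, params, oxy = TRUE) {
  p <- unclass(params)
  kda <- if (oxy) p[["KdATP_oxy"]] else p[["KdATP_deoxy"]]
  kdb <- if (oxy) p[["KdBPG_oxy"]] else p[["KdBPG_deoxy"]]
  .cpp_mg_free(QMgT / Vw, p[["QATP"]] / Vw, p[["QBPG"]] / Vw, kda, kdb)
}

#' Free ionized calcium from cytosolic content
#'
#' Linear buffer: `CaF = ca_buffer_ratio * QCaT / Vw`. The ratio lumps
#' fast cytosolic binding; organelle (vacuolar) accumulation is outside
#' the model's scope.
#'
#' @param QCaT cytosolic calcium content, mmol/Loc (>= 0).
#' @param Vw cell water volume, Lcw/Loc.
#' @param params packed parameter vector.
#' @return free [Ca2+]i, mmol/Lcw.
#' @export
ca_free <- function(QCaT, Vw, params) {
  if (any(QCaT < 0)) stop("QCaT must be non-negative")
  unclass(params)[["ca_buffer_ratio"]] * QCaT / Vw
}

#' Joint pH / volume / membrane potential equilibration
#'
#' At fixed cation and divalent contents, finds the unique
#' (pHi, Vw, QA) satisfying (i) the Jacobs-Stewart condition rH = rA
#' (anion exchanger plus CO2 shunt, treated as instantaneous), (ii)
#' electroneutrality with the Dalmark hemoglobin charge and the fixed
#' X-pool charge, and (iii) osmotic equality including the hemoglobin
#' virial term; then solves the zero-net-current membrane potential
#' (Goldman leak currents plus the electrogenic 3:2 Na pump and PMCA).
#' Free Ca2+ and Mg2+ are re-derived from their buffers.
#'
#' @param state a [cell_state()]; its `oxy` flag selects the oxy/deoxy
#'   isoelectric point and buffer constants.
#' @param params packed parameter vector.
#' @param amplitude PIEZO1 amplitude factor for this transit (used for the
#'   potential solve when the channel is open).
#' @param piezo_open logical; open deoxy-PIEZO1 permeabilities.
#' @return the equilibrated `cell_state`.
#' @export
solve_ph_em_water <- function(state, params, amplitude = 1,
                              piezo_open = FALSE) {
  v <- .cpp_equilibrate(as_state_vector(state), unclass(params),
                        amplitude, piezo_open)
  names(v) <- .state_names
  class(v) <- c("cell_state", "numeric")
  v
}

#' Equilibrium residuals of a state
#'
#' Recomputes the charge, osmotic and proton/anion-ratio residuals of a
#' state. All three are < 1e-6 after [solve_ph_em_water()].
#'
#' @param state a [cell_state()].
#' @param params packed parameter vector.
#' @return list with `charge` (mEq/Lcw), `osmotic` (mOsm/Lcw) and
#'   `ratio` (relative |rH - rA| / rA) residuals.
#' @export
equilibrium_residuals <- function(state, params) {
  p <- unclass(params)
  v <- as_state_vector(state)
  Vw <- v[["Vw"]]
  CA <- v[["QA"]] / Vw
  CHb <- p[["QHb"]] / Vw
  CX <- p[["QX"]] / Vw
  pI <- if (v[["oxy"]] > 0.5) p[["pI_oxy"]] else p[["pI_deoxy"]]
  nHb <- .cpp_hb_charge(v[["pHi"]], pI, p[["alpha"]])
  fHb <- .cpp_fhb(CHb, p[["b1"]], p[["b2"]])
  charge <- (v[["QNa"]] + v[["QK"]]) / Vw + 2 * v[["MgF"]] + 2 * v[["CaF"]] -
    CA + nHb * CHb + p[["nX"]] * CX
  osm <- (v[["QNa"]] + v[["QK"]]) / Vw + CA + v[["MgF"]] + v[["CaF"]] +
    fHb * CHb + CX - p[["Osmo"]]
  rA <- p[["CAo"]] / CA
  rH <- 10^(p[["pHo"]] - v[["pHi"]])
  list(charge = charge, osmotic = osm, ratio = abs(rH - rA) / rA)
}

#' Nernst equilibrium potential
#'
#' @param Ci,Co intracellular and plasma concentrations.
#' @param z valence.
#' @return potential in mV (RT/F = 26.73 mV at 37 C).
#' @export
nernst <- function(Ci, Co, z = 1) {
  26.73 / z * log(Co / Ci)
}
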