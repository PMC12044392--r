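# Construction of the self-consistent oxygenated reference steady state.

#' Build the reference (initial steady) state of the cell
#'
#' Constructs an oxygenated state in which every species is at pump-leak
#' balance, electroneutrality and osmotic equality hold, and pHi, Em and
#' the free divalent concentrations are mutually consistent.
#'
#' The construction is "pump-leak": the ground electrodiffusive
#' permeabilities for Na+ and K+ are back-computed so that the passive
#' leaks exactly cancel the specified pump fluxes at the reference
#' composition, and the ground Ca2+ permeability likewise balances the
#' reference PMCA flux. The impermeant-anion pool X (organic and
#' inorganic phosphates, including the ATP and 2,3-BPG that buffer Mg)
#' gets its amount from osmotic closure and its fixed charge per mole
#' `nX` from electroneutrality closure. The membrane potential is the
#' diffusible-anion Nernst potential EA, which is also the zero-current
#' solution because the 3:2 Na pump and PMCA currents cancel the cation
#' leak excess exactly at balance. The deoxy-PIEZO1 calcium permeability
#' is set so that the mean (amplitude 1) deoxygenated Ca2+ influx is
#' `ca_ratio` times the reference PMCA flux.
#'
#' @param config a configuration list from [reference_config()].
#' @return list with elements `state` (a [cell_state()]), `params`
#'   (packed parameter vector, class `rcm_params`, carrying the config and
#'   fitted constants as attributes) and `fitted` (the back-computed
#'   constants).
#' @examples
#' ref <- build_reference_state(reference_config())
#' ref$state[["Em"]]            # ~ -12.3 mV, the anion Nernst potential
#' @export
build_reference_state <- function(config = reference_config()) {
  cfg <- config
  if (cfg$kcl_rate > 0)
    stop("K:Cl cotransport cannot be pump-leak balanced at the reference ",
         "state (the anion permeability is fixed); enable it during a run ",
         "via a parameter_change stage instead")
  Vw <- cfg$Vw_ref
  CHb <- cfg$QHb / Vw
  CA <- cfg$CAo * 10^(cfg$pHi - cfg$pHo)      # Jacobs-Stewart: rH = rA
  rA <- cfg$CAo / CA
  Em <- -26.73 * log(rA)

  QATP <- cfg$ATP_cw * Vw
  QBPG <- cfg$BPG_cw * Vw
  MgF <- .cpp_mg_free(cfg$MgT_cw, QATP / Vw, QBPG / Vw,
                      cfg$KdATP_oxy, cfg$KdBPG_oxy)
  CaF <- cfg$CaF
  QCaT <- CaF * Vw / cfg$ca_buffer_ratio
  QMgT <- cfg$MgT_cw * Vw

  fHb <- .cpp_fhb(CHb, cfg$b1, cfg$b2)
  nHb <- .cpp_hb_charge(cfg$pHi, cfg$pI_oxy, cfg$alpha)

  # osmotic closure -> amount of impermeant X
  CX <- cfg$Osmo - (cfg$CNa + cfg$CK + CA + MgF + CaF + fHb * CHb)
  if (CX <= 0)
    stop("no steady state: osmotic closure requires negative impermeant ",
         "pool (reduce QHb or intracellular cations)")
  QX <- CX * Vw
  # electroneutrality closure -> charge per mole of X
  nX <- (CA - cfg$CNa - cfg$CK - 2 * MgF - 2 * CaF - nHb * CHb) / CX

  # pump scales at the reference composition
  s_na <- cfg$CNa / (cfg$CNa + cfg$KmNa * (1 + cfg$CK / cfg$KiK))
  f_mg <- MgF / (MgF + cfg$KMg)
  napump_Fmax <- cfg$na_pump_ref / (s_na^3 * f_mg)
  jca_pump <- cfg$pmca_Fmax * CaF / (CaF + cfg$KmCa)  # reference PMCA flux

  # back-computed ground leaks (unit-permeability Goldman fluxes)
  g_na <- .cpp_ghk(1, 1, Em, cfg$CNa, cfg$CNao)       # influx > 0
  g_k  <- .cpp_ghk(1, 1, Em, cfg$CK, cfg$CKo)         # efflux < 0
  g_ca <- .cpp_ghk(1, 2, Em, CaF, cfg$CaO)            # influx > 0
  if (g_na <= 0 || g_ca <= 0 || g_k >= 0)
    stop("no steady state: leak driving forces have unexpected signs at ",
         "the reference potential")
  PNa <- cfg$na_pump_ref / g_na

  # K: ground leak balances pump influx plus the (tiny) resting Gardos efflux
  PKg_rest <- cfg$gardos_PKmax * CaF^cfg$hill /
    (CaF^cfg$hill + cfg$K05Ca^cfg$hill)
  jk_gardos <- .cpp_ghk(PKg_rest, 1, Em, cfg$CK, cfg$CKo)
  jk_pump <- (2 / 3) * cfg$na_pump_ref
  PK <- (-jk_pump - jk_gardos) / g_k
  if (PK <= 0)
    stop("no steady state: resting Gardos efflux exceeds the pump K influx")

  PCa <- jca_pump / g_ca
  PzCa <- cfg$ca_ratio * jca_pump / g_ca

  fitted <- list(QX = QX, nX = nX, PNa = PNa, PK = PK, PCa = PCa,
                 PzCa = PzCa, napump_Fmax = napump_Fmax,
                 pmca_ref_flux = jca_pump, Em_ref = Em)
  pars <- pack_params(cfg, fitted)
  attr(pars, "config") <- cfg
  attr(pars, "fitted") <- fitted
  class(pars) <- c("rcm_params", "numeric")

  st <- cell_state(Vw = Vw, QNa = cfg$CNa * Vw, QK = cfg$CK * Vw,
                   QA = CA * Vw, QCaT = QCaT, QMgT = QMgT,
                   pHi = cfg$pHi, Em = Em, CaF = CaF, MgF = MgF, oxy = TRUE)

  # verify: the constructed state is a fixed point of the equilibrium
  # solver and every species flux vanishes
  st2 <- solve_ph_em_water(st, pars)
  fl <- cell_fluxes(st2, pars)
  net <- abs(fl[c("JNa", "JK", "JA", "JCaT", "JMgT")])
  if (any(net > 1e-8))
    stop("reference state is not at pump-leak balance; residual fluxes: ",
         paste(sprintf("%s=%.3g", names(net), net), collapse = ", "))
  resid <- equilibrium_residuals(st2, pars)
  if (any(abs(unlist(resid)) > 1e-6))
    stop("reference state violates equilibrium invariants: ",
         paste(sprintf("%s=%.3g", names(resid), unlist(resid)),
               collapse = ", "))

  list(state = st2, params = pars, fitted = fitted)
}

#' @export
print.rcm_params <- function(x, ...) {
  cat("<rcm_params>", length(unclass(x)), "model constants\n")
  f <- attr(x, "fitted")
  cat(sprintf("  fitted at reference: PNa=%.4g PK=%.4g PCa=%.4g PzCa=%.4g\n",
              f$PNa, f$PK, f$PCa, f$PzCa))
  cat(sprintf("  X pool: QX=%.4g mmol/Loc, nX=%.4g Eq/mmol\n", f$QX, f$nX))
  cat(sprintf("  Na pump Fmax=%.4g, reference PMCA flux=%.4g mmol/Loch\n",
              f$napump_Fmax, f$pmca_ref_flux))
  invisible(x)
}
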