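# Model configuration and the packed parameter vector shared with the
# compiled core. The packed layout must match the enum in src/rcm.cpp.

.par_names <- c(
  "CNao", "CKo", "CAo", "pHo", "CaO", "MgO", "Osmo",
  "alpha", "pI_oxy", "pI_deoxy", "b1", "b2",
  "QHb", "QX", "nX",
  "PNa", "PK", "PA", "PCa", "PMg",
  "PzNa", "PzK", "PzA", "PzCa", "PzMg",
  "napump_Fmax", "KmNa", "KiK", "KMg",
  "pmca_Fmax", "KmCa",
  "gardos_PKmax", "K05Ca", "hill",
  "kcl_rate",
  "inh",
  "QATP", "QBPG", "KdATP_oxy", "KdATP_deoxy", "KdBPG_oxy", "KdBPG_deoxy",
  "ca_buffer_ratio"
)

.state_names <- c("Vw", "QNa", "QK", "QA", "QCaT", "QMgT",
                  "pHi", "Em", "CaF", "MgF", "oxy")

#' Default configuration of the ISC-destined stress reticulocyte
#'
#' Returns the full model configuration: plasma composition, the
#' constitutive properties of the reference cell, hemoglobin titration and
#' osmotic parameters, transport and buffering constants. Every entry can
#' be overridden, either here or through the `[reference]` block of a
#' protocol file.
#'
#' The reference cell is a macrocytic stress reticulocyte with a reduced
#' hemoglobin content (lowest among sickle cell subtypes) and pump
#' turnovers roughly 10-fold (Na) and 40-fold (Ca) above mature red cells.
#' `na_pump_ref` is the reference Na extrusion flux (mmol/Loch);
#' `pmca_Fmax` is the saturated PMCA capacity (mmol/Loch), the reference
#' Ca pump-leak flux being the smaller Michaelis value at the resting free
#' calcium `CaF`. `ca_ratio` sets the mean deoxy-PIEZO1 calcium influx as
#' a multiple of that reference Ca pump flux.
#'
#' @param ... named overrides of any default entry.
#' @return a named list of configuration values (class `isc_config`).
#' @examples
#' cfg <- reference_config(PzA = 100)  # non-rate-limiting anion permeability
#' cfg$PzA
#' @export
reference_config <- function(...) {
  cfg <- list(
    # plasma (infinite reservoir, 37 C)
    CNao = 140, CKo = 5, CAo = 125, pHo = 7.40,
    CaO = 1.2, MgO = 0.5, Osmo = 290,
    # reference cell composition
    Vw_ref = 0.85,       # Lcw per Loc; macrocytic stress reticulocyte
    CNa = 10, CK = 130,  # mmol/Lcw
    pHi = 7.2,
    QHb = 3.5,           # mmol/Loc (~70% of normal MCH)
    CaF = 5e-5,          # mmol/Lcw resting free calcium (0.05 uM)
    MgT_cw = 2.8,        # mmol/Lcw total magnesium at reference
    # hemoglobin: Dalmark titration line and osmotic virial coefficients
    alpha = -8, pI_oxy = 6.7, pI_deoxy = 7.4,
    b1 = 0.0645, b2 = 0.0258,
    # magnesium buffers (concentrations at the reference water volume)
    ATP_cw = 1.5, BPG_cw = 7.0,
    KdATP_oxy = 0.08, KdATP_deoxy = 0.14,
    KdBPG_oxy = 1.0, KdBPG_deoxy = 3.5,
    ca_buffer_ratio = 8e-4,
    # pumps
    na_pump_ref = 26,    # mmol/Loch reference Na pump flux
    KmNa = 4, KiK = 70, KMg = 0.050,
    pmca_Fmax = 36, KmCa = 7e-4,
    # Gardos channel
    gardos_PKmax = 1.8, K05Ca = 2e-3, hill = 2,
    # permeabilities
    PA_ground = 1.3,     # h^-1, native anion permeability
    PzA = 50,            # h^-1, deoxy-PIEZO1 anion permeability
    PzNa = 0.05, PzK = 0.05, PzMg = 0.02,
    ca_ratio = 10,       # deoxy Ca influx / reference PMCA flux
    kcl_rate = 0,
    # collapse detection threshold (fraction of initial relative volume)
    collapse_fraction = 0.7
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad))
      stop("unknown configuration entries: ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  structure(cfg, class = "isc_config")
}

# Pack a full parameter list (config + fitted entries) into the numeric
# vector layout expected by the compiled core.
pack_params <- function(cfg, fitted) {
  p <- c(
    cfg$CNao, cfg$CKo, cfg$CAo, cfg$pHo, cfg$CaO, cfg$MgO, cfg$Osmo,
    cfg$alpha, cfg$pI_oxy, cfg$pI_deoxy, cfg$b1, cfg$b2,
    cfg$QHb, fitted$QX, fitted$nX,
    fitted$PNa, fitted$PK, cfg$PA_ground, fitted$PCa, 0,
    cfg$PzNa, cfg$PzK, cfg$PzA, fitted$PzCa, cfg$PzMg,
    fitted$napump_Fmax, cfg$KmNa, cfg$KiK, cfg$KMg,
    cfg$pmca_Fmax, cfg$KmCa,
    cfg$gardos_PKmax, cfg$K05Ca, cfg$hill,
    cfg$kcl_rate,
    1,
    cfg$ATP_cw * cfg$Vw_ref, cfg$BPG_cw * cfg$Vw_ref,
    cfg$KdATP_oxy, cfg$KdATP_deoxy, cfg$KdBPG_oxy, cfg$KdBPG_deoxy,
    cfg$ca_buffer_ratio
  )
  names(p) <- .par_names
  p
}

#' Construct a cell state vector
#'
#' A cell state is a named numeric vector holding water volume, ion and
#' hemoglobin-independent contents, pH, membrane potential, free divalent
#' concentrations and the oxygenation flag. States are produced by
#' [build_reference_state()] and advanced by [step_state()] /
#' [run_simulation()]; this constructor is mainly useful for tests and
#' custom initial conditions.
#'
#' @param Vw cell water volume, Lcw per liter of original cells.
#' @param QNa,QK,QA,QCaT,QMgT contents, mmol/Loc.
#' @param pHi intracellular pH.
#' @param Em membrane potential, mV.
#' @param CaF,MgF free ionized cytosolic Ca2+ and Mg2+, mmol/Lcw.
#' @param oxy logical or 0/1 oxygenation flag.
#' @return named numeric state vector (class `cell_state`).
#' @export
cell_state <- function(Vw, QNa, QK, QA, QCaT, QMgT, pHi, Em, CaF, MgF,
                       oxy = TRUE) {
  s <- c(Vw, QNa, QK, QA, QCaT, QMgT, pHi, Em, CaF, MgF, as.numeric(oxy))
  names(s) <- .state_names
  if (any(s[c("Vw", "QNa", "QK", "QA")] <= 0))
    stop("water volume and Na/K/A contents must be strictly positive")
  class(s) <- c("cell_state", "numeric")
  s
}

as_state_vector <- function(s) {
  v <- unclass(s)[.state_names]
  storage.mode(v) <- "double"
  v
}

#' Concentrations of a cell state
#'
#' @param state a `cell_state`.
#' @return named vector of intracellular concentrations (mmol/Lcw).
#' @export
state_concentrations <- function(state) {
  v <- as_state_vector(state)
  c(CNa = v[["QNa"]] / v[["Vw"]], CK = v[["QK"]] / v[["Vw"]],
    CA = v[["QA"]] / v[["Vw"]], CaT = v[["QCaT"]] / v[["Vw"]],
    MgT = v[["QMgT"]] / v[["Vw"]])
}
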