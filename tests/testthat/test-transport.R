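# Membrane flux laws: Goldman limits, pump kinetics and stoichiometry,
# PMCA, Gardos, PIEZO1 gating, K:Cl, pathway decomposition, Donnan oracle.

test_that("Goldman flux limits: zero field, equilibrium, Nernst", {
  expect_equal(goldman_flux(1.3, -1, 0, 80, 125), 1.3 * (125 - 80))
  expect_equal(goldman_flux(2, 1, 0, 100, 100), 0)
  em <- nernst(130, 5, 1)
  expect_equal(goldman_flux(1, 1, em, 130, 5), 0, tolerance = 1e-10)
  # divalent Nernst
  em2 <- nernst(1e-4, 1.2, 2)
  expect_equal(goldman_flux(1, 2, em2, 1e-4, 1.2), 0, tolerance = 1e-10)
  expect_error(goldman_flux(-1, 1, 0, 1, 1), "non-negative")
})

test_that("Goldman series branch is continuous at u = 0", {
  j0 <- goldman_flux(1, 1, 1e-10, 50, 140)
  j1 <- goldman_flux(1, 1, 1e-4, 50, 140)
  expect_equal(j0, j1, tolerance = 1e-5)
})

test_that("Na pump: substrate, Mg half-activation, K inhibition, 3:2 ratio", {
  ref <- ref_default()
  expect_equal(unname(na_pump_flux(0, 130, 0.25, ref$params)), c(0, 0))
  # Mg factor is exactly 1/2 at the 50 umol/Lcw half-activation point
  j_half <- na_pump_flux(10, 130, 0.050, ref$params)[["JNa_pump"]]
  j_sat <- na_pump_flux(10, 130, 1e9, ref$params)[["JNa_pump"]]
  expect_equal(j_half / j_sat, 0.5, tolerance = 1e-9)
  # K-inhibition relief: dropping CK from 130 to 5 boosts extrusion
  j_hi <- na_pump_flux(10, 130, 0.25, ref$params)[["JNa_pump"]]
  j_lo <- na_pump_flux(10, 5, 0.25, ref$params)[["JNa_pump"]]
  expect_gt(abs(j_lo), abs(j_hi))
  # 3:2 stoichiometry exact
  j <- na_pump_flux(25, 60, 0.4, ref$params)
  expect_identical(j[["JK_pump"]], -(2 / 3) * j[["JNa_pump"]])
  # reference flux matches the configured turnover
  cfg <- reference_config()
  mgf <- unclass(ref$state)[["MgF"]]
  expect_equal(na_pump_flux(10, 130, mgf, ref$params)[["JNa_pump"]],
               -cfg$na_pump_ref, tolerance = 1e-9)
})

test_that("PMCA: zero, half-saturation, saturation at Fmax", {
  ref <- ref_default()
  p <- unclass(ref$params)
  expect_equal(pmca_flux(0, ref$params), 0)
  expect_equal(pmca_flux(p[["KmCa"]], ref$params), -p[["pmca_Fmax"]] / 2)
  expect_equal(pmca_flux(1, ref$params), -p[["pmca_Fmax"]], tolerance = 1e-3)
})

test_that("Gardos channel: silent at rest, Hill midpoint, gradient exhaustion", {
  ref <- ref_default()
  p <- unclass(ref$params)
  expect_equal(gardos_flux(0, 130, 5, -12, ref$params), 0)
  expect_equal(gardos_perm(p[["K05Ca"]], ref$params),
               p[["gardos_PKmax"]] / 2)
  # K at its electrochemical equilibrium: no net flux with channels open
  em <- -60
  ck_eq <- 5 * exp(-em / 26.73)
  expect_equal(gardos_flux(1, ck_eq, 5, em, ref$params), 0,
               tolerance = 1e-10)
})

test_that("PIEZO1: closed when oxygenated, voltage-sensitized Ca influx, PA step", {
  ref <- ref_default()
  expect_true(all(piezo_fluxes(ref$state, ref$params, 1) == 0))
  st <- ref$state
  st[["oxy"]] <- 0
  fl <- piezo_fluxes(st, ref$params, 1)
  expect_gt(fl[["JCa_piezo"]], 0)
  expect_gt(fl[["JNa_piezo"]], 0)
  # hyperpolarization strictly increases the Ca influx
  st2 <- st; st2[["Em"]] <- st[["Em"]] - 30
  expect_gt(piezo_fluxes(st2, ref$params, 1)[["JCa_piezo"]],
            fl[["JCa_piezo"]])
  # amplitude scales the open-state permeabilities linearly
  expect_equal(piezo_fluxes(st, ref$params, 1.75)[["JA_piezo"]],
               1.75 * fl[["JA_piezo"]], tolerance = 1e-9)
  expect_error(piezo_fluxes(st, ref$params, -0.1), "non-negative")
  # deoxy/ground anion permeability ratio as configured
  p <- unclass(ref$params)
  expect_equal(p[["PzA"]] / p[["PA"]], 50 / 1.3, tolerance = 1e-9)
})

test_that("K:Cl cotransport: off by default, zero at product equilibrium", {
  ref <- ref_default()
  expect_equal(unname(kcl_flux(130, 80, 5, 125, ref$params)), c(0, 0))
  p <- params_mod(ref$params, kcl_rate = 0.02)
  expect_equal(unname(kcl_flux(5 * 125 / 80, 80, 5, 125, p)), c(0, 0))
  j <- kcl_flux(130, 80, 5, 125, p)
  expect_lt(j[["JK"]], 0)                 # outward when product exceeds
  expect_identical(j[["JK"]], j[["JA"]])  # electroneutral coupling
})

test_that("pathway decomposition sums exactly to the species totals", {
  ref <- ref_default()
  st <- ref$state
  st[["oxy"]] <- 0
  st[["CaF"]] <- 1e-3
  fl <- cell_fluxes(st, params_mod(ref$params, kcl_rate = 0.02),
                    amplitude = 1.3)
  expect_equal(fl[["JNa"]],
               fl[["JNa_ground"]] + fl[["JNa_piezo"]] + fl[["JNa_pump"]],
               tolerance = 1e-12)
  expect_equal(fl[["JK"]],
               fl[["JK_ground"]] + fl[["JK_piezo"]] + fl[["JK_pump"]] +
                 fl[["JK_gardos"]] + fl[["JK_kcl"]],
               tolerance = 1e-12)
  expect_equal(fl[["JA"]],
               fl[["JA_ground"]] + fl[["JA_piezo"]] + fl[["JK_kcl"]],
               tolerance = 1e-12)
  expect_equal(fl[["JCaT"]],
               fl[["JCa_ground"]] + fl[["JCa_piezo"]] + fl[["JCa_pump"]],
               tolerance = 1e-12)
})

test_that("with pumps off and channels open the cell relaxes to Donnan equilibrium", {
  ref <- ref_default()
  p <- params_mod(ref$params, napump_Fmax = 0, pmca_Fmax = 0,
                  gardos_PKmax = 0, PCa = 0, PzCa = 0, PzMg = 0,
                  PNa = 0.5, PK = 0.5)
  st <- ref$state
  st[["QCaT"]] <- 0
  st[["QMgT"]] <- 1e-9
  st <- solve_ph_em_water(st, p)
  ts <- run_simulation(st, p, one_transit("oxy", 400), dt = 240,
                       record_s = 36000)
  fin <- attr(ts, "final_state")

  # independent analytic oracle: r = exp(-u) with all permeant species at
  # electrochemical equilibrium, water balanced, charge balanced
  pp <- unclass(p)
  osm_vw <- function(r) {
    CA <- pp[["CAo"]] / r
    f <- function(Vw) {
      CHb <- pp[["QHb"]] / Vw
      pp[["CNao"]] * r + pp[["CKo"]] * r + CA +
        hb_osmotic_coeff(CHb, pp[["b1"]], pp[["b2"]]) * CHb +
        pp[["QX"]] / Vw - pp[["Osmo"]]
    }
    uniroot(f, c(0.02, 60), tol = 1e-12)$root
  }
  charge_res <- function(r) {
    pHi <- pp[["pHo"]] - log10(r)
    Vw <- osm_vw(r)
    CHb <- pp[["QHb"]] / Vw
    (pp[["CNao"]] + pp[["CKo"]]) * r - pp[["CAo"]] / r +
      hb_charge(pHi, pp[["pI_oxy"]], pp[["alpha"]]) * CHb +
      pp[["nX"]] * pp[["QX"]] / Vw
  }
  # bracket restricted to r where CA < total osmolarity (water can balance)
  r_star <- uniroot(charge_res, c(0.75, 1.3), tol = 1e-12)$root
  em_star <- -26.73 * log(r_star)
  vw_star <- osm_vw(r_star)

  expect_equal(fin[["Em"]], em_star, tolerance = 0.05)
  expect_equal(fin[["Vw"]], vw_star, tolerance = 0.01)
  expect_equal(fin[["QNa"]] / fin[["Vw"]], pp[["CNao"]] * r_star,
               tolerance = 0.05)
  expect_equal(fin[["QK"]] / fin[["Vw"]], pp[["CKo"]] * r_star,
               tolerance = 0.05)
  # rNa = rK = 1/rA = r at Donnan equilibrium
  rA <- pp[["CAo"]] / (fin[["QA"]] / fin[["Vw"]])
  expect_equal(1 / rA, r_star, tolerance = 1e-3)
})
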