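# Fast algebraic sub-solvers: Dalmark charge, Hb osmotic coefficient,
# Jacobs-Stewart / charge / osmotic equilibration, Mg and Ca buffering.

test_that("Dalmark titration line evaluates with the documented sign convention", {
  expect_equal(hb_charge(7.4, 7.4), 0)                    # isoelectric point
  expect_equal(hb_charge(6.4, 7.4, -8), 8)                # acid -> positive
  expect_equal(hb_charge(7.65, 7.4, -8), -2)
})

test_that("Hb osmotic coefficient is 1 at zero and strictly convex-increasing", {
  expect_equal(hb_osmotic_coeff(0), 1)
  ch <- seq(0, 12, by = 0.5)
  contrib <- hb_osmotic_coeff(ch) * ch
  expect_true(all(diff(contrib) > 0))
  expect_true(all(diff(diff(contrib)) > 0))
  expect_error(hb_osmotic_coeff(-1), "non-negative")
})

test_that("reference hemoglobin osmotic contribution is ~7 mOsmol/Lcw", {
  cfg <- reference_config()
  chb <- cfg$QHb / cfg$Vw_ref
  expect_equal(hb_osmotic_coeff(chb, cfg$b1, cfg$b2) * chb, 7, tolerance = 0.05)
})

test_that("anion Nernst potential limits", {
  expect_equal(nernst(125, 125, -1), 0)
  # rA = 1.4: EA = -(RT/F) ln 1.4 at 37 C
  expect_equal(-26.73 * log(1.4), -8.9936, tolerance = 1e-4)
  expect_equal(nernst(125 / 1.4, 125, -1), -26.73 * log(1.4))
})

test_that("equilibration enforces rH = rA and is idempotent", {
  ref <- ref_default()
  st <- ref$state
  # perturb the contents, then equilibrate
  st[["QK"]] <- st[["QK"]] - 20
  st[["QNa"]] <- st[["QNa"]] + 5
  eq <- solve_ph_em_water(st, ref$params)
  res <- equilibrium_residuals(eq, ref$params)
  expect_lt(res$ratio, 1e-6)
  expect_lt(abs(res$charge), 1e-6)
  expect_lt(abs(res$osmotic), 1e-6)
  eq2 <- solve_ph_em_water(eq, ref$params)
  expect_lt(max(abs(unclass(eq2) - unclass(eq))), 1e-10)
})

test_that("solver solution attains the minimal residual norm on a grid", {
  # brute-force oracle: scan (pHi, Vw) with CA tied to pHi by the
  # Jacobs-Stewart condition and score charge^2 + osmotic^2
  ref <- ref_default()
  p <- unclass(ref$params)
  st <- ref$state
  st[["QK"]] <- st[["QK"]] - 30
  eq <- solve_ph_em_water(st, ref$params)
  score <- function(pHi, Vw) {
    CA <- p[["CAo"]] * 10^(pHi - p[["pHo"]])
    CHb <- p[["QHb"]] / Vw
    MgF <- mg_free(st[["QMgT"]], Vw, ref$params, oxy = TRUE)
    CaF <- ca_free(st[["QCaT"]], Vw, ref$params)
    nHb <- hb_charge(pHi, p[["pI_oxy"]], p[["alpha"]])
    fHb <- hb_osmotic_coeff(CHb, p[["b1"]], p[["b2"]])
    ch <- (st[["QNa"]] + st[["QK"]]) / Vw + 2 * MgF + 2 * CaF - CA +
      nHb * CHb + p[["nX"]] * p[["QX"]] / Vw
    os <- (st[["QNa"]] + st[["QK"]]) / Vw + CA + MgF + CaF + fHb * CHb +
      p[["QX"]] / Vw - p[["Osmo"]]
    ch^2 + os^2
  }
  grid <- expand.grid(pHi = seq(6.5, 7.6, by = 0.02),
                      Vw = seq(0.5, 1.1, by = 0.01))
  vals <- mapply(score, grid$pHi, grid$Vw)
  best <- grid[which.min(vals), ]
  expect_equal(eq[["pHi"]], best$pHi, tolerance = 0.02)
  expect_equal(eq[["Vw"]], best$Vw, tolerance = 0.01)
  expect_lt(score(eq[["pHi"]], eq[["Vw"]]), min(vals) + 1e-12)
})

test_that("dehydration raising [X] forces the anions down and the pH down", {
  ref <- ref_default()
  st <- ref$state
  st[["QK"]] <- st[["QK"]] - 40          # KA loss drives water loss
  st[["QA"]] <- st[["QA"]] - 30
  eq <- solve_ph_em_water(st, ref$params)
  expect_lt(eq[["Vw"]], ref$state[["Vw"]])
  expect_lt(eq[["QA"]] / eq[["Vw"]], unclass(ref$state)[["QA"]] / 0.85)
  expect_lt(eq[["pHi"]], ref$state[["pHi"]])
  expect_lt(eq[["Em"]], ref$state[["Em"]])  # hyperpolarization
})

test_that("free Mg: mass-action limits and the deoxy release direction", {
  ref <- ref_default()
  p_nobuf <- params_mod(ref$params, QATP = 0, QBPG = 0)
  expect_equal(mg_free(2.38, 0.85, p_nobuf, oxy = TRUE), 2.38 / 0.85)
  oxy <- mg_free(2.38, 0.85, ref$params, oxy = TRUE)
  deoxy <- mg_free(2.38, 0.85, ref$params, oxy = FALSE)
  expect_gt(deoxy, oxy)
  expect_gt(mg_free(4, 0.85, ref$params), mg_free(2.38, 0.85, ref$params))
  # conservation: free + bound reproduces the total
  p <- unclass(ref$params)
  bound <- p[["QATP"]] / 0.85 * oxy / (oxy + p[["KdATP_oxy"]]) +
    p[["QBPG"]] / 0.85 * oxy / (oxy + p[["KdBPG_oxy"]])
  expect_equal(oxy + bound, 2.38 / 0.85, tolerance = 1e-10)
})

test_that("free Ca is the linear buffer fraction of content", {
  ref <- ref_default()
  expect_equal(ca_free(0, 0.85, ref$params), 0)
  p1 <- params_mod(ref$params, ca_buffer_ratio = 1)
  expect_equal(ca_free(0.2, 0.85, p1), 0.2 / 0.85)
  expect_equal(ca_free(0.2, 0.425, ref$params),
               2 * ca_free(0.2, 0.85, ref$params))
  expect_error(ca_free(-1, 0.85, ref$params), "non-negative")
})

test_that("Em equals EA exactly when the anion leak is the only pathway", {
  ref <- ref_default()
  p <- params_mod(ref$params, PNa = 0, PK = 0, PCa = 0, PMg = 0,
                  napump_Fmax = 0, pmca_Fmax = 0, gardos_PKmax = 0)
  em <- solve_em(ref$state, p)
  v <- unclass(ref$state)
  ea <- -26.73 * log(unclass(p)[["CAo"]] / (v[["QA"]] / v[["Vw"]]))
  expect_equal(em, ea, tolerance = 1e-8)
  # and within 1 mV of EA with the full default permeability set
  expect_lt(abs(solve_em(ref$state, ref$params) - ea), 1)
})
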