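# Time integration: stationarity, convergence, bookkeeping, conservation,
# determinism, calcium restoration kinetics.

test_that("a steady state does not move under stepping", {
  ref <- ref_default()
  st <- step_state(ref$state, ref$params, dt = 1)
  expect_lt(max(abs(unclass(st) - unclass(ref$state))), 1e-9)
})

test_that("halving dt changes the 1-minute solution by < 0.1% (fine-step oracle)", {
  ref <- ref_default()
  st0 <- set_oxygenation(ref$state, ref$params, FALSE, amplitude = 1)
  advance <- function(dt) {
    s <- st0
    for (i in seq_len(60 / dt))
      s <- step_state(s, ref$params, dt = dt, amplitude = 1)
    unclass(s)[c("Vw", "QNa", "QK", "QA", "QCaT", "pHi", "Em")]
  }
  x1 <- advance(1)
  x05 <- advance(0.5)
  x01 <- advance(0.1)          # fine-step oracle
  rel <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-6))
  expect_lt(rel(x1, x05), 0.001)
  # first-order convergence: halving dt roughly halves the error
  # against the fine-step oracle
  expect_lt(rel(x05, x01), 0.75 * rel(x1, x01))
})

test_that("content updates are exact flux bookkeeping over one step", {
  ref <- ref_default()
  st <- set_oxygenation(ref$state, ref$params, FALSE, amplitude = 1)
  fl <- cell_fluxes(st, ref$params, amplitude = 1)
  st2 <- step_state(st, ref$params, dt = 1, amplitude = 1)
  h <- 1 / 3600
  # explicit species: exact Euler increments
  expect_lt(abs(st2[["QNa"]] - st[["QNa"]] - fl[["JNa"]] * h), 1e-14)
  expect_lt(abs(st2[["QK"]] - st[["QK"]] - fl[["JK"]] * h), 1e-14)
  expect_lt(abs(st2[["QMgT"]] - st[["QMgT"]] - fl[["JMgT"]] * h), 1e-14)
  # calcium uses the trapezoidal corrector: the increment matches the
  # start-of-step flux to second order in dt
  expect_equal(st2[["QCaT"]] - st[["QCaT"]], fl[["JCaT"]] * h,
               tolerance = 0.02)
})

test_that("an all-oxy 5-day run preserves the reference volume to 0.5%", {
  ref <- ref_default()
  ts <- run_simulation(ref$state, ref$params, one_transit("oxy", 120),
                       dt = 120, record_s = 7200)
  expect_lt(max(abs(ts$relvol - 1)), 0.005)
})

test_that("calcium loaded in one deoxy transit is cleared within minutes of reoxygenation", {
  ref <- ref_default()
  st <- set_oxygenation(ref$state, ref$params, FALSE, amplitude = 1)
  for (i in 1:60) st <- step_state(st, ref$params, dt = 1, amplitude = 1)
  expect_gt(st[["CaF"]], 2 * ref$state[["CaF"]])
  st <- set_oxygenation(st, ref$params, TRUE)
  peak <- st[["CaF"]]
  mins <- 0
  repeat {
    for (i in 1:60) st <- step_state(st, ref$params, dt = 1)
    mins <- mins + 1
    if (mins == 2) expect_lt(st[["CaF"]], peak / 2)
    if (st[["CaF"]] <= 1.05 * ref$state[["CaF"]] || mins >= 12) break
  }
  expect_lte(mins, 8)
})

test_that("hemoglobin and X pools are conserved over a stochastic run", {
  sim <- typical_run(1)
  ts <- sim$timeseries
  p <- unclass(sim$params)
  # CX * Vw must reproduce QX exactly at every output row
  expect_lt(max(abs(ts$CX * ts$Vw - p[["QX"]])), 1e-12 * p[["QX"]] + 1e-9)
  chb <- p[["QHb"]] / ts$Vw
  expect_lt(max(abs(ts$Hb_osm - ts$fHb * chb)), 1e-9)
})

test_that("same seed and protocol give byte-identical CSV output", {
  p <- typical_isc_protocol(seed = 4)
  p$duration_h <- 6
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_timeseries_csv(isc_sim(p, detect = FALSE)$timeseries, f1)
  write_timeseries_csv(isc_sim(p, detect = FALSE)$timeseries, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("phase-1 trend: smoothed volume and Em decline monotonically to the trough", {
  p <- typical_isc_protocol(seed = 2, lingering_h = numeric(0))
  sim <- cached("phase1_trend", isc_sim(p))
  ph <- sim$phases
  tr <- sim$transits
  rv <- cycle_means(tr, "mean_relvol")
  em <- cycle_means(tr, "mean_Em")
  k <- 6
  n <- length(rv$v)
  roll <- function(v) vapply(seq_len(n), function(i)
    stats::median(v[max(1, i - k):min(n, i + k)]), 0)
  pre <- rv$t < ph$t_trough
  rvs <- roll(rv$v)[pre]
  ems <- roll(em$v)[pre]
  # non-increasing up to a small slack for residual stochastic wobble
  expect_true(all(diff(rvs) < 0.005))
  expect_true(all(diff(ems) < 2.5))
  expect_lt(tail(rvs, 1), 0.66)
  expect_lt(tail(ems, 1), -30)
  expect_lt(tail(ems, 1), ems[1] - 20)   # overall hyperpolarization
})

test_that("steps that would drive contents negative are rejected at the dt floor", {
  ref <- ref_default()
  # an absurd efflux rate exhausts K faster than any admissible sub-step
  expect_error(step_state(ref$state, params_mod(ref$params, kcl_rate = 1e6),
                          dt = 100), "negative")
})
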