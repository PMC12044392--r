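# The 5-day ISC experiment: protocol construction, the phase-3 pump
# inhibition trigger, phase detection and summary statistics, parameter
# scans, and the Mg-depletion hypothesis test.

#' Simulation protocol
#'
#' A protocol bundles the reference-state overrides, the circulation
#' configuration and an ordered list of dynamic stages (lingering
#' episodes, the sudden Na-pump inhibitory step, generic parameter
#' changes). Protocols serialize to an editable text format via
#' [write_protocol()] / [parse_protocol()].
#'
#' @param name protocol name (used for output file naming).
#' @param duration_h total simulated time, hours.
#' @param seed RNG seed for the transit schedule.
#' @param reference named list of [reference_config()] overrides.
#' @param circulation named list of [circulation_config()] overrides
#'   (duration ranges, amplitude bounds).
#' @param stages list of stages; each a list with `type` one of
#'   `"lingering"`, `"pump_inhibition"`, `"parameter_change"` plus its
#'   parameters (`time_h` always; `duration_min`, `factor`, or
#'   `param`/`value`).
#' @param dt_s integration step, seconds.
#' @param record_s output cadence, seconds.
#' @return list of class `isc_protocol`.
#' @export
isc_protocol <- function(name = "protocol", duration_h = 120, seed = 1L,
                         reference = list(), circulation = list(),
                         stages = list(), dt_s = 1, record_s = 60) {
  # validate reference/circulation keys against their constructors
  do.call(reference_config, reference)
  ok_circ <- c("oxy_range", "deoxy_range", "amp_range")
  bad <- setdiff(names(circulation), ok_circ)
  if (length(bad))
    stop("unknown circulation entries: ", paste(bad, collapse = ", "))
  times <- vapply(stages, function(s) as.numeric(s$time_h), 0)
  if (is.unsorted(times))
    stop("stage times must be non-decreasing")
  for (s in stages) {
    if (!s$type %in% c("lingering", "pump_inhibition", "parameter_change"))
      stop("unknown stage type: ", s$type)
    if (s$type == "pump_inhibition") {
      f <- s$factor
      if (!(f > 0 && f <= 1)) stop("pump inhibition factor must be in (0,1]")
    }
    if (s$type == "parameter_change" && !s$param %in% .par_names)
      stop("unknown parameter in parameter_change stage: ", s$param)
  }
  structure(list(name = name, duration_h = duration_h,
                 seed = as.integer(seed), reference = reference,
                 circulation = circulation, stages = stages,
                 dt_s = dt_s, record_s = record_s),
            class = "isc_protocol")
}

#' The "typical" 5-day ISC protocol
#'
#' The representative 5-day ISC life-cycle protocol: stress-reticulocyte
#' reference with Ca/Na pump turnovers 36/26 mmol/Loch, deoxy-PIEZO1
#' anion permeability 50 h^-1, mean deoxy Ca influx 10x the reference
#' PMCA flux, three 40-min lingering episodes (at 0.5 days, ~1.1 days and
#' 3.5 days), and a single sudden Na-pump inhibitory step at day 4
#' initiating terminal rehydration.
#'
#' @param ... overrides passed to [isc_protocol()] (e.g. `seed`,
#'   `reference = list(PzA = 100)`).
#' @param inhibition_time_h time of the Na-pump inhibitory step, hours.
#' @param inhibition_factor multiplicative pump scale applied at the
#'   step; the default is calibrated so the settled phase-3 pump flux is
#'   about -10 mmol/Loch.
#' @param lingering_h times of the lingering episodes, hours.
#' @return an [isc_protocol()].
#' @examples
#' p <- typical_isc_protocol(seed = 7)
#' p$duration_h   # 120 h = 5 days
#' @export
typical_isc_protocol <- function(...,
                                 inhibition_time_h = 96,
                                 inhibition_factor = 0.04,
                                 lingering_h = c(12, 26.4, 84)) {
  stages <- c(
    lapply(sort(lingering_h), function(t)
      list(type = "lingering", time_h = t, duration_min = 40)),
    if (!is.null(inhibition_time_h))
      list(list(type = "pump_inhibition", time_h = inhibition_time_h,
                factor = inhibition_factor))
  )
  # keep stages ordered by time
  stages <- stages[order(vapply(stages, `[[`, 0, "time_h"))]
  isc_protocol(name = "typical_5day_isc", duration_h = 120,
               stages = stages, ...)
}

#' Apply (or change) the sudden Na-pump inhibitory step
#'
#' Replaces any existing pump-inhibition stages of a protocol by a single
#' sudden step (or a multi-step ramp when vectors are given, representing
#' progressive metabolic decline).
#'
#' @param protocol an [isc_protocol()].
#' @param t_event event time(s), hours.
#' @param factor multiplicative pump scale(s) in (0, 1]; 1 leaves the
#'   pump untouched.
#' @return the modified protocol.
#' @export
apply_pump_inhibition <- function(protocol, t_event, factor) {
  stopifnot(inherits(protocol, "isc_protocol"),
            length(t_event) == length(factor),
            all(factor > 0), all(factor <= 1))
  if (any(t_event < 36))
    warning("pump inhibition before ~1.5 days will precede the volume ",
            "trough; the step is normally applied during phase 2")
  keep <- Filter(function(s) s$type != "pump_inhibition", protocol$stages)
  add <- mapply(function(t, f)
    list(type = "pump_inhibition", time_h = t, factor = f),
    t_event, factor, SIMPLIFY = FALSE)
  stages <- c(keep, add)
  stages <- stages[order(vapply(stages, `[[`, 0, "time_h"))]
  protocol$stages <- stages
  protocol
}

protocol_events <- function(protocol) {
  ev <- lapply(protocol$stages, function(s) {
    switch(s$type,
      pump_inhibition = data.frame(time_h = s$time_h, param = "inh",
                                   value = s$factor,
                                   stringsAsFactors = FALSE),
      parameter_change = data.frame(time_h = s$time_h, param = s$param,
                                    value = s$value,
                                    stringsAsFactors = FALSE),
      NULL)
  })
  ev <- do.call(rbind, ev)
  if (is.null(ev)) ev <- data.frame(time_h = numeric(0),
                                    param = character(0),
                                    value = numeric(0))
  ev
}

protocol_lingering <- function(protocol) {
  st <- Filter(function(s) s$type == "lingering", protocol$stages)
  list(times = vapply(st, `[[`, 0, "time_h"),
       duration_min = if (length(st)) st[[1]]$duration_min else 40)
}

inhibition_time <- function(protocol) {
  st <- Filter(function(s) s$type == "pump_inhibition", protocol$stages)
  if (!length(st)) return(NA_real_)
  min(vapply(st, `[[`, 0, "time_h"))
}

# ---------------------------------------------------------------------------

#' Approximate per-transit statistics from a recorded time series
#'
#' Reconstructs a per-transit summary table from the recorded rows of a
#' CSV time series (grouping consecutive rows of the same transit kind).
#' The native table produced during integration is exact; this
#' reconstruction is limited by the output cadence and is intended for
#' re-analysis of runs available only as CSV.
#'
#' @param ts an `isc_timeseries` (e.g. from [read_timeseries_csv()]).
#' @return per-transit summary data frame.
#' @export
approximate_transits <- function(ts) {
  grp <- cumsum(c(TRUE, ts$transit_kind[-1] != ts$transit_kind[-nrow(ts)]))
  idx <- split(seq_len(nrow(ts)), grp)
  t_end <- vapply(idx, function(i) max(ts$t[i]), 0)
  t_start <- c(0, t_end[-length(t_end)])
  mk <- function(col, f) vapply(idx, function(i) f(ts[[col]][i]), 0)
  data.frame(
    transit = seq_along(idx),
    kind = vapply(idx, function(i) ts$transit_kind[i[1]], ""),
    t_start = t_start, t_end = t_end,
    duration_s = pmax(t_end - t_start, 1e-6) * 3600,
    amplitude = mk("amplitude", function(x) x[1]),
    mean_relvol = mk("relvol", mean), mean_pHi = mk("pHi", mean),
    min_pHi = mk("pHi", min), mean_Em = mk("Em", mean),
    mean_CNa = mk("CNa", mean), mean_CK = mk("CK", mean),
    mean_CA = mk("CA", mean), mean_MgT = mk("MgT", mean),
    mean_MgF = mk("MgF", mean), mean_CaF = mk("CaF", mean),
    min_JNa_pump = mk("JNa_pump", min),
    max_JNa_pump = mk("JNa_pump", max),
    mean_JNa_pump = mk("JNa_pump", mean),
    mean_JCa_pump = mk("JCa_pump", mean),
    mean_JK_gardos = mk("JK_gardos", mean),
    mean_JNa_passive = vapply(idx, function(i)
      mean(ts$JNa_ground[i] + ts$JNa_piezo[i]), 0),
    mean_Hb_osm = mk("Hb_osm", mean),
    row.names = NULL)
}

#' Detect the three life-cycle phases and summarize them
#'
#' Phase 1 runs from circulatory emergence to the volume trough of the
#' hyperdense collapse; phase 2 from the trough to the pump-inhibition
#' event; phase 3 from the event to the end. Statistics are computed on
#' transit-averaged traces smoothed over one full oxy+deoxy cycle to
#' suppress oscillation aliasing.
#'
#' @param x an `isc_sim`, or an `isc_timeseries` from [run_simulation()].
#' @param collapse_fraction a run whose smoothed relative volume never
#'   falls below this fraction of its initial value did not produce an
#'   ISC; an error is raised.
#' @param t_inhibition inhibition event time (hours); taken from the
#'   run's events when omitted.
#' @return object of class `phase_summary`: trough time and volume,
#'   phase boundaries, the phase-1 pH dip, phase-2 mean pH and
#'   oscillation range, the phase-2 Na-pump flux envelope, the settled
#'   phase-3 pump flux, the hemoglobin osmotic contribution at reference
#'   and trough, the phase-2 Na flux balance and volume drift, and the
#'   phase-2 ATP turnover ratio over the mature-RBC baseline.
#' @export
detect_phases <- function(x, collapse_fraction = NULL, t_inhibition = NULL) {
  ts <- if (inherits(x, "isc_sim")) x$timeseries else x
  stopifnot(inherits(ts, "isc_timeseries"))
  tr <- attr(ts, "transits")
  if (is.null(tr)) tr <- approximate_transits(ts)
  params <- attr(ts, "params")
  cfg <- attr(params, "config")
  if (is.null(collapse_fraction)) {
    collapse_fraction <- cfg$collapse_fraction
    if (is.null(collapse_fraction)) collapse_fraction <- 0.7
  }
  if (is.null(t_inhibition)) {
    ev <- attr(ts, "events")
    t_inhibition <-
      if (!is.null(ev) && any(ev$param == "inh"))
        min(ev$time_h[ev$param == "inh"]) else NA_real_
  }

  # smooth over one full cycle: each oxy transit opens a new cycle
  cyc <- cumsum(tr$kind == "oxy")
  w <- tr$duration_s
  agg <- function(v) {
    vapply(split(seq_len(nrow(tr)), cyc), function(i)
      sum(v[i] * w[i]) / sum(w[i]), 0)
  }
  cyc_t <- vapply(split(seq_len(nrow(tr)), cyc), function(i)
    (min(tr$t_start[i]) + max(tr$t_end[i])) / 2, 0)
  cyc_rv <- agg(tr$mean_relvol)
  cyc_mgt <- agg(tr$mean_MgT)

  pre <- if (is.na(t_inhibition)) rep(TRUE, length(cyc_t)) else
    cyc_t < t_inhibition
  if (!any(pre)) stop("no cycles before the inhibition event")
  # The volume trough is the knee at the end of the steep phase-1
  # descent. A rolling median over ~9 cycles suppresses single-cycle
  # excursions (lingering episodes), and the trough time is the first
  # entry of the smoothed trace into a narrow band just above the
  # plateau floor -- robust against slow wander of the long, nearly
  # flat phase-2 plateau.
  k <- 4L
  n_c <- length(cyc_rv)
  roll <- vapply(seq_len(n_c), function(i)
    stats::median(cyc_rv[max(1, i - k):min(n_c, i + k)]), 0)
  V0 <- cyc_rv[1]
  V_floor <- min(roll[pre])
  thresh <- V_floor + 0.20 * (V0 - V_floor)
  i_tr <- which(pre & roll <= thresh)[1]
  V_trough <- unname(V_floor)
  if (V_trough >= collapse_fraction * V0)
    stop(sprintf(paste0("no collapse: smoothed relative volume never fell ",
                        "below %.2f of initial (minimum %.3f)"),
                 collapse_fraction, V_trough / V0))
  t_trough <- unname(cyc_t[i_tr])

  # phase-1 pH dip: minimum transit-averaged pHi over the first 1.5 days
  first15 <- tr$t_start < 36
  pH_dip <- min(tr$mean_pHi[first15])

  ph2 <- tr$t_start >= t_trough &
    (is.na(t_inhibition) | tr$t_end <= t_inhibition)
  ph2_w <- tr$duration_s[ph2]
  pH2_mean <- sum(tr$mean_pHi[ph2] * ph2_w) / sum(ph2_w)
  pH2_range <- stats::quantile(tr$mean_pHi[ph2], c(0.05, 0.95), names = FALSE)
  env <- c(stats::quantile(tr$min_JNa_pump[ph2 & tr$kind != "oxy"], 0.05,
                           names = FALSE),
           stats::quantile(tr$max_JNa_pump[ph2], 0.95, names = FALSE))

  # phase-2 stability: systematic trend of the smoothed volume over the
  # plateau (first 3 h after the trough excluded as settling), expressed
  # as total drift over the phase; oscillation/wander is reported
  # separately as the 5-95% spread of the cycle means
  cyc2 <- cyc_t >= t_trough + 3 &
    (is.na(t_inhibition) | cyc_t < t_inhibition)
  drift <- if (sum(cyc2) > 2) {
    sl <- unname(stats::coef(stats::lm(cyc_rv[cyc2] ~ cyc_t[cyc2]))[2])
    abs(sl) * diff(range(cyc_t[cyc2])) / stats::median(cyc_rv[cyc2])
  } else NA_real_
  spread <- diff(stats::quantile(cyc_rv[cyc2], c(0.05, 0.95), names = FALSE)) /
    stats::median(cyc_rv[cyc2])
  na_in <- sum(tr$mean_JNa_passive[ph2] * ph2_w) / sum(ph2_w)
  na_pump <- sum(tr$mean_JNa_pump[ph2] * ph2_w) / sum(ph2_w)
  na_balance <- (na_in + na_pump) / abs(na_pump)

  # settled phase-3 pump flux: time average over the final 12 h
  t_end <- max(tr$t_end)
  ph3_flux <- NA_real_
  if (!is.na(t_inhibition)) {
    sel <- tr$t_start >= t_end - 12
    ph3_flux <- sum(tr$mean_JNa_pump[sel] * tr$duration_s[sel]) /
      sum(tr$duration_s[sel])
  }

  # hemoglobin osmotic contribution at the instantaneous volume trough
  # (the peak of the fHb*CHb trace before the inhibition event)
  hb_ref <- ts$Hb_osm[1]
  pre_ts <- if (is.na(t_inhibition)) rep(TRUE, nrow(ts)) else
    ts$t < t_inhibition
  hb_trough <- max(ts$Hb_osm[pre_ts])

  atp <- atp_turnover_ratio(tr, t_from = t_trough,
                            t_to = if (is.na(t_inhibition)) t_end
                                   else t_inhibition,
                            params = params,
                            baseline = if (is.null(params))
                              26 / 10 / 3 + 36 / 40 else NULL)

  mgt_slope <- if (sum(cyc2) > 2)
    unname(stats::coef(stats::lm(cyc_mgt[cyc2] ~ cyc_t[cyc2]))[2])
  else NA_real_

  structure(list(
    t_trough = t_trough, V_trough = V_trough, V0 = V0,
    t_inhibition = t_inhibition, t_end = t_end,
    phase1 = c(0, t_trough),
    phase2 = c(t_trough, if (is.na(t_inhibition)) t_end else t_inhibition),
    phase3 = if (is.na(t_inhibition)) NULL else c(t_inhibition, t_end),
    pH_dip = pH_dip, pH_phase2_mean = pH2_mean, pH_phase2_range = pH2_range,
    pump_envelope = env, pump_phase3_settled = ph3_flux,
    Hb_osm_ref = hb_ref, Hb_osm_trough = hb_trough,
    phase2_drift = drift, phase2_spread = spread,
    phase2_na_balance = na_balance,
    phase2_MgT_slope = mgt_slope,
    atp_turnover_ratio = atp
  ), class = "phase_summary")
}

#' @export
print.phase_summary <- function(x, ...) {
  cat("ISC life-cycle phase summary\n")
  cat(sprintf("  trough: t = %.2f h (%.2f d), relative volume %.3f\n",
              x$t_trough, x$t_trough / 24, x$V_trough))
  if (!is.na(x$t_inhibition))
    cat(sprintf("  pump inhibition at t = %.1f h; end of run %.1f h\n",
                x$t_inhibition, x$t_end))
  cat(sprintf("  pH: dip %.2f, phase-2 mean %.2f (range %.2f-%.2f)\n",
              x$pH_dip, x$pH_phase2_mean,
              x$pH_phase2_range[1], x$pH_phase2_range[2]))
  cat(sprintf("  Hb osmotic contribution: %.1f -> %.1f mOsmol/Lcw\n",
              x$Hb_osm_ref, x$Hb_osm_trough))
  cat(sprintf("  phase-2 Na-pump envelope: %.1f to %.1f mmol/Loch\n",
              x$pump_envelope[1], x$pump_envelope[2]))
  if (!is.na(x$pump_phase3_settled))
    cat(sprintf("  phase-3 settled Na-pump flux: %.1f mmol/Loch\n",
                x$pump_phase3_settled))
  cat(sprintf("  phase-2 volume drift %.2f%%, Na-flux balance %.2f%%\n",
              100 * x$phase2_drift, 100 * x$phase2_na_balance))
  cat(sprintf("  ATP turnover ratio vs mature baseline: %.1f-fold\n",
              x$atp_turnover_ratio))
  invisible(x)
}

#' Plasma-membrane pump ATP turnover relative to the mature-RBC baseline
#'
#' Time-averaged `|JNa_pump|/3 + |JCa_pump|` (one ATP per pump cycle:
#' 3 Na per ATP, 1 Ca per ATP) over a window, divided by the same
#' quantity for a mature red cell whose Na and Ca pump rates are the
#' reference values divided by 10 and 40 respectively.
#'
#' @param transits per-transit summary table (see [transit_summary()]).
#' @param t_from,t_to window, hours.
#' @param params packed parameter vector (supplies the reference rates);
#'   alternatively give `baseline` directly.
#' @param baseline mature baseline ATP turnover, mmol ATP/Loch.
#' @return dimensionless fold-ratio.
#' @export
atp_turnover_ratio <- function(transits, t_from, t_to, params = NULL,
                               baseline = NULL) {
  sel <- transits$t_start >= t_from & transits$t_end <= t_to
  if (!any(sel)) stop("empty transit window")
  if (is.null(baseline)) {
    cfg <- attr(params, "config")
    baseline <- (cfg$na_pump_ref / 10) / 3 + cfg$pmca_Fmax / 40
  }
  w <- transits$duration_s[sel]
  atp <- sum((abs(transits$mean_JNa_pump[sel]) / 3 +
                abs(transits$mean_JCa_pump[sel])) * w) / sum(w)
  atp / baseline
}

# ---------------------------------------------------------------------------

#' Scan the deoxy-PIEZO1 anion permeability
#'
#' Runs the protocol once per PA value with a shared seed (so differences
#' are attributable to PA alone) and reports the collapse and rehydration
#' timing: PA is rate-limiting at the native ground value and saturates
#' near 100 h^-1.
#'
#' @param values anion permeabilities to scan, h^-1.
#' @param protocol base protocol.
#' @param seed shared schedule seed.
#' @return data frame with `PA`, `t_trough`, `V_trough`,
#'   `t_rehydration_half` (hours to recover half the volume lost, from
#'   the inhibition event), plus the runs as attribute `"runs"`.
#' @export
scan_pa <- function(values = c(1.3, 50, 100),
                    protocol = typical_isc_protocol(), seed = protocol$seed) {
  runs <- lapply(values, function(pa) {
    p <- protocol
    p$reference$PzA <- pa
    isc_sim(p, seed = seed)
  })
  out <- data.frame(
    PA = values,
    t_trough = vapply(runs, function(r)
      if (is.null(r$phases)) NA_real_ else r$phases$t_trough, 0),
    V_trough = vapply(runs, function(r)
      if (is.null(r$phases)) NA_real_ else r$phases$V_trough, 0),
    t_rehydration_half = vapply(runs, rehydration_half_time, 0)
  )
  attr(out, "runs") <- runs
  class(out) <- c("pa_scan", "data.frame")
  out
}

# time (hours from the inhibition event) at which the smoothed relative
# volume recovers half-way from its value at the event to its final value
rehydration_half_time <- function(sim) {
  if (is.null(sim$phases) || is.na(sim$phases$t_inhibition)) return(NA_real_)
  tr <- sim$transits
  cyc <- cumsum(tr$kind == "oxy")
  w <- tr$duration_s
  rv <- vapply(split(seq_len(nrow(tr)), cyc), function(i)
    sum(tr$mean_relvol[i] * w[i]) / sum(w[i]), 0)
  tt <- vapply(split(seq_len(nrow(tr)), cyc), function(i)
    (min(tr$t_start[i]) + max(tr$t_end[i])) / 2, 0)
  t0 <- sim$phases$t_inhibition
  v0 <- rv[which.min(abs(tt - t0))]
  vend <- rv[length(rv)]
  if (vend <= v0) return(NA_real_)
  half <- (v0 + vend) / 2
  after <- tt >= t0
  i <- which(after & rv >= half)
  if (!length(i)) return(NA_real_)
  tt[min(i)] - t0
}

#' Scan the deoxy Ca permeability to PMCA ratio
#'
#' For each ratio (mean deoxy-PIEZO1 Ca influx divided by the reference
#' PMCA flux), runs the protocol with a shared seed and reports the
#' collapse time; ratios near zero never collapse, and a ratio of about
#' 10 is the smallest that produces hyperdense collapse within ~1.5 days.
#'
#' @param ratios positive ratios to scan.
#' @param protocol base protocol.
#' @param seed shared schedule seed.
#' @return data frame with `ratio`, `collapsed`, `t_trough` (NA when no
#'   collapse occurred within the horizon).
#' @export
scan_ca_ratio <- function(ratios = c(1, 2, 5, 10, 15),
                          protocol = typical_isc_protocol(),
                          seed = protocol$seed) {
  rows <- lapply(ratios, function(r) {
    p <- protocol
    p$reference$ca_ratio <- r
    sim <- isc_sim(p, seed = seed)
    data.frame(ratio = r, collapsed = !is.null(sim$phases),
               t_trough = if (is.null(sim$phases)) NA_real_
                          else sim$phases$t_trough)
  })
  do.call(rbind, rows)
}

#' Test the Mg-depletion hypothesis for phase-3 triggering
#'
#' Runs phase 2 out to `duration_h` with the pump-inhibition event
#' removed and asks whether deoxy-induced Mg depletion could ever lower
#' free [Mg2+]i below the 50 umol/Lcw half-activation of the Na pump.
#' The expected outcome is negative: the hyperpolarized phase-2 membrane
#' potential reverses the Mg2+ gradient inward, so total Mg rises during
#' phase 2 and [Mg2+]i never approaches inhibitory levels.
#'
#' @param protocol base protocol (its inhibition stage is stripped).
#' @param duration_h horizon, hours (default 7 days).
#' @param seed schedule seed.
#' @return list with `min_MgF`, `crosses_KMg`, the phase-2 total-Mg
#'   slope (mmol/Lcw per hour) and the underlying run.
#' @export
mg_depletion_test <- function(protocol = typical_isc_protocol(),
                              duration_h = 168, seed = protocol$seed) {
  p <- protocol
  p$stages <- Filter(function(s) s$type != "pump_inhibition", p$stages)
  p$duration_h <- duration_h
  sim <- isc_sim(p, seed = seed)
  tr <- sim$transits
  kmg <- unclass(sim$params)[["KMg"]]
  min_mgf <- min(tr$mean_MgF)
  res <- list(min_MgF = min_mgf,
              KMg = kmg,
              crosses_KMg = min_mgf < kmg,
              phase2_MgT_slope = if (is.null(sim$phases)) NA_real_
                                 else sim$phases$phase2_MgT_slope,
              sim = sim)
  class(res) <- "mg_depletion_test"
  res
}

#' @export
print.mg_depletion_test <- function(x, ...) {
  cat("Mg-depletion hypothesis test (no pump-inhibition event)\n")
  cat(sprintf("  minimum transit-averaged [Mg2+]i: %.4f mmol/Lcw\n",
              x$min_MgF))
  cat(sprintf("  Na-pump half-activation KMg:      %.4f mmol/Lcw\n", x$KMg))
  cat(sprintf("  [Mg2+]i %s the inhibitory level\n",
              if (x$crosses_KMg) "CROSSES" else "never approaches"))
  if (!is.na(x$phase2_MgT_slope))
    cat(sprintf("  phase-2 total-Mg trend: %+.2g mmol/Lcw per hour\n",
                x$phase2_MgT_slope))
  invisible(x)
}
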