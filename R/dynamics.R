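# Time integration: explicit content updates at dt <= 1 s inside each
# transit, with the fast equilibria re-solved after every step (operator
# splitting), and per-transit summary statistics accumulated on the fly.

#' Advance a cell state by one explicit step
#'
#' Updates the contents by `flux * dt`, then re-solves the fast
#' equilibria ([solve_ph_em_water()], Mg/Ca buffers). If an update would
#' drive a content negative the step is retried at dt/2 (down to
#' dt/1024, then a hard error).
#'
#' @param state an equilibrated [cell_state()].
#' @param params packed parameter vector.
#' @param dt step, seconds.
#' @param amplitude PIEZO1 amplitude factor.
#' @param piezo_open logical; if `NULL`, open exactly when deoxygenated.
#' @return the advanced, equilibrated `cell_state`.
#' @export
step_state <- function(state, params, dt = 1, amplitude = 1,
                       piezo_open = NULL) {
  v <- as_state_vector(state)
  if (is.null(piezo_open)) piezo_open <- v[["oxy"]] < 0.5
  out <- .cpp_step(v, unclass(params), dt, amplitude, piezo_open)
  names(out) <- .state_names
  class(out) <- c("cell_state", "numeric")
  out
}

#' Set the oxygenation of a state and re-equilibrate
#'
#' Switching to deoxy raises the isoelectric point of HbS (7.4) and the
#' effective Mg-buffer dissociation constants, and opens PIEZO1; the fast
#' equilibria are re-solved immediately.
#'
#' @param state a [cell_state()].
#' @param params packed parameter vector.
#' @param oxy logical target oxygenation.
#' @param amplitude PIEZO1 amplitude factor for the deoxy transit.
#' @return the re-equilibrated `cell_state`.
#' @export
set_oxygenation <- function(state, params, oxy, amplitude = 1) {
  v <- as_state_vector(state)
  v[["oxy"]] <- as.numeric(oxy)
  out <- .cpp_equilibrate(v, unclass(params), amplitude, !oxy)
  names(out) <- .state_names
  class(out) <- c("cell_state", "numeric")
  out
}

#' Run a full simulation over a transit schedule
#'
#' Executes the transits in order, toggling the oxygenation flag, the
#' HbS isoelectric point, the Mg-buffer constants and the PIEZO1 open
#' state at each boundary, applying timed parameter-change events (e.g.
#' the sudden Na-pump inhibitory step), and recording the complete system
#' state at the output cadence plus every transit boundary.
#'
#' @param state initial (reference) [cell_state()].
#' @param params packed parameter vector.
#' @param schedule a [sample_schedule()] result.
#' @param events optional data frame with columns `time_h`, `param`
#'   (parameter name, e.g. `"inh"`) and `value`.
#' @param dt integration step during transits, seconds.
#' @param record_s output cadence, seconds.
#' @return an `isc_timeseries`: data frame of all system variables over
#'   time, with the per-transit summary table as attribute `"transits"`
#'   and the final state as attribute `"final_state"`.
#' @export
run_simulation <- function(state, params, schedule, events = NULL,
                           dt = 1, record_s = 60) {
  ev <- matrix(numeric(0), 0, 3)
  if (!is.null(events) && nrow(events)) {
    idx <- match(events$param, .par_names)
    if (anyNA(idx))
      stop("unknown event parameter(s): ",
           paste(events$param[is.na(idx)], collapse = ", "))
    ev <- cbind(events$time_h, idx - 1, events$value)
  }
  cfg <- attr(params, "config")
  res <- .cpp_simulate(as_state_vector(state), unclass(params),
                       schedule_matrix(schedule), ev, dt, record_s,
                       cfg$Vw_ref)
  ts <- as.data.frame(res$ts)
  kinds <- c("oxy", "deoxy", "lingering")
  ts$transit_kind <- kinds[ts$transit_kind + 1]
  tr <- as.data.frame(res$transits)
  tr$kind <- kinds[tr$kind + 1]
  fin <- res$final_state
  names(fin) <- .state_names
  class(fin) <- c("cell_state", "numeric")
  structure(ts, transits = tr, final_state = fin, params = params,
            events = events, class = c("isc_timeseries", "data.frame"))
}

#' Per-transit summary statistics of a run
#'
#' @param ts an `isc_timeseries` from [run_simulation()].
#' @return data frame with one row per transit: duration-weighted means,
#'   minima and maxima of the key variables (used for transit-averaged
#'   smoothing and oscillation-envelope statistics).
#' @export
transit_summary <- function(ts) {
  attr(ts, "transits")
}
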