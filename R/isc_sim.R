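# The top-level simulation object and its methods.

#' Simulate the circulatory life cycle of an ISC
#'
#' Builds the reference stress-reticulocyte state from the protocol's
#' reference block, samples the stochastic oxy/deoxy transit schedule,
#' integrates the homeostatic model over the full protocol (applying
#' lingering episodes and the Na-pump inhibitory step at their scheduled
#' times), and detects the three life-cycle phases.
#'
#' @param protocol an [isc_protocol()]; default [typical_isc_protocol()].
#' @param seed schedule seed (defaults to the protocol's).
#' @param dt integration step, seconds.
#' @param record_s output cadence, seconds.
#' @param detect logical; run [detect_phases()] (stored as `NULL`, with
#'   the message in `$no_collapse`, when the run never collapses).
#' @return object of class `isc_sim` with components `timeseries`,
#'   `transits`, `phases`, `reference` (initial state), `params`,
#'   `schedule`, `protocol`, `seed`.
#' @examples
#' \donttest{
#' sim <- isc_sim(typical_isc_protocol(seed = 1))
#' summary(sim)
#' }
#' @export
isc_sim <- function(protocol = typical_isc_protocol(),
                    seed = protocol$seed, dt = protocol$dt_s,
                    record_s = protocol$record_s, detect = TRUE) {
  stopifnot(inherits(protocol, "isc_protocol"))
  cfg <- do.call(reference_config, protocol$reference)
  ref <- build_reference_state(cfg)

  ling <- protocol_lingering(protocol)
  circ <- do.call(circulation_config, c(
    protocol$circulation,
    list(lingering_h = ling$times, lingering_min = ling$duration_min,
         total_h = protocol$duration_h, seed = seed)))
  schedule <- sample_schedule(circ)
  events <- protocol_events(protocol)

  ts <- run_simulation(ref$state, ref$params, schedule, events = events,
                       dt = dt, record_s = record_s)

  phases <- NULL
  no_collapse <- NULL
  if (detect) {
    phases <- tryCatch(detect_phases(ts),
                       error = function(e) { no_collapse <<- conditionMessage(e); NULL })
  }
  structure(list(timeseries = ts, transits = transit_summary(ts),
                 phases = phases, no_collapse = no_collapse,
                 reference = ref$state, params = ref$params,
                 schedule = schedule, protocol = protocol,
                 seed = as.integer(seed)),
            class = "isc_sim")
}

#' @export
print.isc_sim <- function(x, ...) {
  p <- x$protocol
  cat(sprintf("<isc_sim> protocol '%s', %.0f h, seed %d\n",
              p$name, p$duration_h, x$seed))
  cat(sprintf("  %d transits, %d recorded rows\n",
              nrow(x$transits), nrow(x$timeseries)))
  if (!is.null(x$phases)) {
    cat(sprintf("  hyperdense collapse at %.2f d (relative volume %.3f)\n",
                x$phases$t_trough / 24, x$phases$V_trough))
  } else if (!is.null(x$no_collapse)) {
    cat("  ", x$no_collapse, "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.isc_sim <- function(object, ...) {
  if (is.null(object$phases))
    stop("no phase summary: ", object$no_collapse)
  object$phases
}

#' Model constants of a simulation
#'
#' @param object an `isc_sim`.
#' @param ... unused.
#' @return named numeric vector of all model constants (including the
#'   constants back-computed at the reference state).
#' @export
coef.isc_sim <- function(object, ...) {
  p <- unclass(object$params)
  attributes(p) <- list(names = .par_names)
  p
}

#' Re-run a simulation under new schedule seeds
#'
#' Repeats the protocol with fresh stochastic transit schedules; the
#' model and protocol are unchanged, so run-to-run differences reflect
#' circulatory randomness only.
#'
#' @param object an `isc_sim`.
#' @param nsim number of replicate runs.
#' @param seed base seed; replicate i uses `seed + i - 1`.
#' @param ... unused.
#' @return list of `isc_sim` objects.
#' @importFrom stats simulate
#' @export
simulate.isc_sim <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$seed + 1L
  lapply(seq_len(nsim), function(i)
    isc_sim(object$protocol, seed = seed + i - 1L))
}
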