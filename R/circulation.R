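# Synthetic-input generator: the stochastic oxy/deoxy transit schedule.

#' Circulation configuration
#'
#' Defines the stochastic structure of circulatory exposure: uniform
#' duration ranges for oxygenated (arterial) and deoxygenated (venous)
#' inter-capillary transits, a bounded mean-1 amplitude distribution for
#' the fraction of PIEZO1 channels opening in each deoxy transit, optional
#' 40-minute lingering episodes (cells trapped in venules), and the RNG
#' seed.
#'
#' @param oxy_range,deoxy_range two-element numeric, transit duration
#'   bounds in seconds.
#' @param amp_range two-element numeric, bounds of the uniform PIEZO1
#'   amplitude distribution; its mean must be 1 (amplitudes scale the
#'   configured mean permeabilities).
#' @param lingering_h schedule times (hours) of lingering episodes; each
#'   replaces the deoxy transit in progress at that time.
#' @param lingering_min lingering duration, minutes.
#' @param total_h total simulated time, hours.
#' @param seed integer seed; duration and amplitude streams are derived
#'   as independent substreams so either can be frozen for mechanism
#'   dissection.
#' @return list of class `circulation_config`.
#' @export
circulation_config <- function(oxy_range = c(30, 60),
                               deoxy_range = c(30, 90),
                               amp_range = c(0.25, 1.75),
                               lingering_h = numeric(0),
                               lingering_min = 40,
                               total_h = 120,
                               seed = 1L) {
  stopifnot(length(oxy_range) == 2, length(deoxy_range) == 2,
            all(oxy_range > 0), all(deoxy_range > 0),
            diff(oxy_range) >= 0, diff(deoxy_range) >= 0,
            total_h > 0, lingering_min > 0)
  if (abs(mean(amp_range) - 1) > 1e-6)
    stop("amplitude distribution must have mean 1 (got ",
         mean(amp_range), ")")
  if (is.unsorted(lingering_h)) lingering_h <- sort(lingering_h)
  if (length(lingering_h) > 1 &&
      any(diff(lingering_h) * 3600 < lingering_min * 60))
    stop("overlapping lingering events")
  structure(list(oxy_range = oxy_range, deoxy_range = deoxy_range,
                 amp_range = amp_range, lingering_h = lingering_h,
                 lingering_min = lingering_min, total_h = total_h,
                 seed = as.integer(seed)),
            class = "circulation_config")
}

#' Sample a stochastic transit schedule
#'
#' Generates the alternating oxy/deoxy transit sequence covering
#' `total_h`, with per-transit durations drawn uniformly within the
#' configured ranges and per-deoxy-transit PIEZO1 amplitude factors drawn
#' from the mean-1 uniform distribution. Lingering episodes replace the
#' deoxy transit in progress at their scheduled time. The last transit is
#' truncated so durations sum to `total_h` exactly. The same seed yields
#' a bit-identical schedule.
#'
#' @param config a [circulation_config()].
#' @return data frame of class `transit_schedule` with columns `kind`
#'   ("oxy", "deoxy" or "lingering"), `duration_s`, `amplitude` (0 for
#'   oxy transits) and `t_start_h`.
#' @examples
#' sch <- sample_schedule(circulation_config(total_h = 1, seed = 42))
#' table(sch$kind)
#' @export
sample_schedule <- function(config) {
  stopifnot(inherits(config, "circulation_config"))
  total_s <- config$total_h * 3600
  n_max <- ceiling(total_s / (min(config$oxy_range) +
                                min(config$deoxy_range))) + 2L

  # independent substreams for durations and amplitudes
  set.seed(config$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 2L)
  set.seed(sub[1])
  oxy_d <- stats::runif(n_max, config$oxy_range[1], config$oxy_range[2])
  deoxy_d <- stats::runif(n_max, config$deoxy_range[1], config$deoxy_range[2])
  set.seed(sub[2])
  amps <- stats::runif(n_max, config$amp_range[1], config$amp_range[2])

  ling_s <- sort(config$lingering_h) * 3600
  ling_dur <- config$lingering_min * 60
  li <- 1L

  kind <- character(2L * n_max)
  dur <- numeric(2L * n_max)
  amp <- numeric(2L * n_max)
  t0 <- numeric(2L * n_max)
  t <- 0
  k <- 0L
  i <- 1L
  while (t < total_s - 1e-9) {
    # oxy transit
    k <- k + 1L
    kind[k] <- "oxy"; dur[k] <- oxy_d[i]; amp[k] <- 0; t0[k] <- t
    t <- t + dur[k]
    if (t >= total_s) { dur[k] <- dur[k] - (t - total_s); t <- total_s; break }
    # deoxy transit; becomes a lingering episode if one is pending
    k <- k + 1L
    if (li <= length(ling_s) && t + deoxy_d[i] > ling_s[li]) {
      kind[k] <- "lingering"; dur[k] <- ling_dur
      li <- li + 1L
    } else {
      kind[k] <- "deoxy"; dur[k] <- deoxy_d[i]
    }
    amp[k] <- amps[i]; t0[k] <- t
    t <- t + dur[k]
    if (t >= total_s) { dur[k] <- dur[k] - (t - total_s); t <- total_s }
    i <- i + 1L
  }
  out <- data.frame(kind = kind[seq_len(k)], duration_s = dur[seq_len(k)],
                    amplitude = amp[seq_len(k)],
                    t_start_h = t0[seq_len(k)] / 3600,
                    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  class(out) <- c("transit_schedule", "data.frame")
  out
}

# numeric kind codes used by the compiled core
schedule_matrix <- function(schedule) {
  codes <- c(oxy = 0, deoxy = 1, lingering = 2)
  m <- cbind(kind = codes[schedule$kind],
             duration_s = schedule$duration_s,
             amplitude = schedule$amplitude)
  rownames(m) <- NULL
  m
}

#' Write / read a transit schedule as tabular text
#'
#' One transit per line (`kind duration_s amplitude`), for replay.
#'
#' @param schedule a `transit_schedule`.
#' @param path file path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule`
#'   returns the `transit_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  df <- schedule[c("kind", "duration_s", "amplitude")]
  df$duration_s <- sprintf("%.17g", df$duration_s)
  df$amplitude <- sprintf("%.17g", df$amplitude)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric", "numeric"),
                          stringsAsFactors = FALSE)
  df$t_start_h <- cumsum(c(0, df$duration_s[-nrow(df)])) / 3600
  class(df) <- c("transit_schedule", "data.frame")
  df
}
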