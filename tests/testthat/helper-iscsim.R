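# Shared fixtures: expensive 5-day runs are computed once per session and
# reused across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

typical_run <- function(seed) {
  cached(paste0("typical_", seed),
         isc_sim(typical_isc_protocol(seed = seed)))
}

ref_default <- function() {
  cached("ref_default", build_reference_state(reference_config()))
}

# modify entries of a packed parameter vector, keeping class/attributes
params_mod <- function(params, ...) {
  ch <- list(...)
  p <- params
  for (nm in names(ch)) {
    stopifnot(nm %in% names(unclass(p)))
    p[[which(names(unclass(p)) == nm)]] <- ch[[nm]]
  }
  p
}

# a single-transit schedule of the given kind/duration (hours)
one_transit <- function(kind, hours, amplitude = 1) {
  out <- data.frame(kind = kind, duration_s = hours * 3600,
                    amplitude = amplitude, t_start_h = 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("transit_schedule", "data.frame")
  out
}

# duration-weighted per-cycle means of a transit table column
cycle_means <- function(tr, col) {
  cyc <- cumsum(tr$kind == "oxy")
  w <- tr$duration_s
  list(t = vapply(split(seq_len(nrow(tr)), cyc), function(i)
         (min(tr$t_start[i]) + max(tr$t_end[i])) / 2, 0),
       v = vapply(split(seq_len(nrow(tr)), cyc), function(i)
         sum(tr[[col]][i] * w[i]) / sum(w[i]), 0))
}
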