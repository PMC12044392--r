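# CSV emission of the simulated time series. Columns display all the
# variables of the system; rows report their changing values with time.
# Period decimal separator, comma delimiter, full (round-trippable)
# precision.

#' Write a simulated time series to CSV
#'
#' First row holds the column names (documented in the README; the set
#' covers every state variable, equilibrium quantity and per-pathway
#' flux), one row per record, numbers at full precision so that
#' re-reading reproduces the values bit-exactly. An optional units row
#' is emitted as a `#`-prefixed comment line.
#'
#' @param ts an `isc_timeseries` (or any data frame).
#' @param path output path.
#' @param units_row logical; include a commented units line.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(ts, path, units_row = FALSE) {
  if (!nrow(ts)) stop("refusing to write an empty time series")
  df <- as.data.frame(ts)
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (units_row) writeLines(paste0("# units: ", .ts_units_line()), con)
  utils::write.table(df, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.ts_units_line <- function() {
  paste("t h; volumes L/Loc; contents mmol/Loc; concentrations mmol/Lcw;",
        "fluxes mmol/Loch (influx positive); Em/EA/EK/ENa mV;",
        "Hb_charge mEq/Lcw; Hb_osm mOsmol/Lcw")
}

#' Read a time series CSV written by [write_timeseries_csv()]
#'
#' @param path file path.
#' @return data frame of class `isc_timeseries` (summary attributes of
#'   the original run are not restored).
#' @export
read_timeseries_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  for (j in seq_along(df))                 # all-zero columns sniff as
    if (is.integer(df[[j]])) df[[j]] <- as.double(df[[j]])  # integer
  class(df) <- c("isc_timeseries", "data.frame")
  df
}
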