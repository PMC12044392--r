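# The line-oriented protocol text format ("directive value" lines in
# [section] blocks) and its reader/writer.

fmt_num <- function(x) {
  if (is.numeric(x)) sprintf("%.15g", x) else as.character(x)
}

#' Write a protocol to its editable text format
#'
#' @param protocol an [isc_protocol()].
#' @param path output file path (conventionally `*.txt`).
#' @return `path`, invisibly.
#' @seealso [parse_protocol()]
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "isc_protocol"))
  p <- protocol
  ln <- c("# iscsim protocol",
          paste("name", p$name),
          paste("duration_h", fmt_num(p$duration_h)),
          paste("seed", p$seed),
          paste("dt_s", fmt_num(p$dt_s)),
          paste("record_s", fmt_num(p$record_s)))
  if (length(p$reference)) {
    ln <- c(ln, "", "[reference]")
    for (k in names(p$reference))
      ln <- c(ln, paste(k, paste(fmt_num(p$reference[[k]]), collapse = " ")))
  }
  if (length(p$circulation)) {
    ln <- c(ln, "", "[circulation]")
    for (k in names(p$circulation))
      ln <- c(ln, paste(k, paste(fmt_num(p$circulation[[k]]), collapse = " ")))
  }
  for (s in p$stages) {
    ln <- c(ln, "", paste0("[stage ", s$type, "]"))
    for (k in setdiff(names(s), "type"))
      ln <- c(ln, paste(k, paste(fmt_num(s[[k]]), collapse = " ")))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Parse a protocol text file
#'
#' Parses and validates the line-oriented protocol format written by
#' [write_protocol()]. Every violation (unknown directive, missing
#' value, non-monotone stage times) is reported with its line number;
#' `parse_protocol(write_protocol(p))` reproduces `p`.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character vector of protocol lines (overrides
#'   `path`).
#' @return an [isc_protocol()].
#' @export
parse_protocol <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  errs <- character(0)
  err <- function(i, msg) errs <<- c(errs, sprintf("line %d: %s", i, msg))

  top <- list(name = "protocol", duration_h = 120, seed = 1L,
              dt_s = 1, record_s = 60)
  reference <- list()
  circulation <- list()
  stages <- list()
  section <- "top"
  stage_cur <- NULL

  top_keys <- c("name", "duration_h", "seed", "dt_s", "record_s")
  circ_keys <- c("oxy_range", "deoxy_range", "amp_range")
  stage_keys <- list(lingering = c("time_h", "duration_min"),
                     pump_inhibition = c("time_h", "factor"),
                     parameter_change = c("time_h", "param", "value"))
  ref_keys <- names(reference_config())

  flush_stage <- function() {
    if (!is.null(stage_cur)) stages[[length(stages) + 1L]] <<- stage_cur
    stage_cur <<- NULL
  }

  for (i in seq_along(lines)) {
    l <- trimws(lines[i])
    if (l == "" || startsWith(l, "#")) next
    if (startsWith(l, "[")) {
      flush_stage()
      hdr <- sub("^\\[(.*)\\]$", "\\1", l)
      if (hdr == "reference") section <- "reference"
      else if (hdr == "circulation") section <- "circulation"
      else if (startsWith(hdr, "stage ")) {
        type <- sub("^stage ", "", hdr)
        if (!type %in% names(stage_keys)) {
          err(i, paste0("unknown stage type '", type, "'"))
          section <- "skip"
        } else {
          section <- "stage"
          stage_cur <- list(type = type)
        }
      } else err(i, paste0("unknown section '", hdr, "'"))
      next
    }
    sp <- regmatches(l, regexpr("\\s+", l))
    if (!length(sp)) { err(i, "expected 'directive value'"); next }
    key <- sub("\\s.*$", "", l)
    val <- trimws(sub("^\\S+\\s+", "", l))
    num <- suppressWarnings(as.numeric(strsplit(val, "\\s+")[[1]]))
    if (section == "top") {
      if (!key %in% top_keys) { err(i, paste0("unknown directive '", key, "'")); next }
      top[[key]] <- if (key == "name") val
                    else if (key == "seed") as.integer(num)
                    else num
      if (key != "name" && anyNA(num)) err(i, "non-numeric value")
    } else if (section == "reference") {
      if (!key %in% ref_keys) { err(i, paste0("unknown reference entry '", key, "'")); next }
      if (anyNA(num)) err(i, "non-numeric value") else reference[[key]] <- num
    } else if (section == "circulation") {
      if (!key %in% circ_keys) { err(i, paste0("unknown circulation entry '", key, "'")); next }
      if (anyNA(num)) err(i, "non-numeric value") else circulation[[key]] <- num
    } else if (section == "stage") {
      ok <- stage_keys[[stage_cur$type]]
      if (!key %in% ok) { err(i, paste0("unknown '", stage_cur$type, "' entry '", key, "'")); next }
      if (key == "param") stage_cur[[key]] <- val
      else if (anyNA(num)) err(i, "non-numeric value")
      else stage_cur[[key]] <- num
    }
  }
  flush_stage()

  times <- vapply(stages, function(s) as.numeric(s$time_h %||% NA), 0)
  if (anyNA(times)) errs <- c(errs, "every stage needs a time_h entry")
  else if (is.unsorted(times)) errs <- c(errs, "stage times must be non-decreasing")

  if (length(errs))
    stop("invalid protocol:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  isc_protocol(name = top$name, duration_h = top$duration_h,
               seed = top$seed, reference = reference,
               circulation = circulation, stages = stages,
               dt_s = top$dt_s, record_s = top$record_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.isc_protocol <- function(x, ...) {
  cat(sprintf("<isc_protocol> '%s': %.0f h, seed %d, %d stage(s)\n",
              x$name, x$duration_h, x$seed, length(x$stages)))
  for (s in x$stages)
    cat(sprintf("  %-17s t = %6.1f h  %s\n", s$type, s$time_h,
                if (s$type == "pump_inhibition")
                  sprintf("factor %.3g", s$factor)
                else if (s$type == "parameter_change")
                  sprintf("%s = %.4g", s$param, s$value)
                else sprintf("%.0f min", s$duration_min)))
  if (length(x$reference))
    cat("  reference overrides:",
        paste(names(x$reference), collapse = ", "), "\n")
  invisible(x)
}
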