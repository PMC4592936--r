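# Plain-text trace and table exchange: CSV signal files with a JSON sidecar
# carrying protocol, drug state and model parameters.

#' Write a trace as CSV plus a JSON sidecar
#'
#' The CSV holds `time_ms`, `signal`, `command`; `<path>.json` holds mode,
#' dt, protocol segments, drug state and cell parameters.
#'
#' @param trace an `ephys_trace`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(data.frame(time_ms = trace$time_ms, signal = trace$signal,
                       command = trace$command),
            path, row.names = FALSE)
  sidecar <- list(
    schema = "fusiform-trace-1",
    mode = trace$mode, dt = trace$dt,
    segments = trace$protocol$segments,
    bias_to = trace$protocol$bias_to,
    drug = unclass(trace$drug),
    cell = unclass(trace$cell)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trace written by [write_trace_csv()]
#'
#' @param path CSV path (sidecar expected at `<path>.json`).
#' @return an `ephys_trace`.
#' @export
read_trace_csv <- function(path) {
  d <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$schema, "fusiform-trace-1"))
    stop("unrecognized trace schema: ", meta$schema)
  protocol <- clamp_protocol(meta$mode, as.data.frame(meta$segments),
                             bias_to = meta$bias_to, dt = meta$dt)
  structure(list(
    signal = d$signal, currents = NULL, spike_times = NULL,
    time_ms = d$time_ms, command = d$command, mode = meta$mode,
    dt = meta$dt, cell = meta$cell, protocol = protocol, drug = meta$drug
  ), class = "ephys_trace")
}

#' Write a ratio table (or any tidy result table) to CSV
#'
#' @param table data.frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ratio_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a ratio table written by [write_ratio_table()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_ratio_table <- function(path) read.csv(path, stringsAsFactors = FALSE)
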