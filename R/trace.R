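#' Uniformly sampled electrophysiological trace
#'
#' Container for a uniformly sampled signal: intracellular membrane
#' potential or LFP (mV or uV) or a clamp current (pA).
#'
#' @param samples numeric vector of sample values (length >= 2).
#' @param dt sampling interval in seconds (> 0).
#' @param units one of \code{"mV"}, \code{"pA"}, \code{"uV"}.
#' @param channel_id free-form channel label.
#' @return An object of class \code{trace_record} with fields
#'   \code{samples}, \code{dt}, \code{units}, \code{channel_id}.
#' @examples
#' tr <- trace_record(sin(seq(0, 1, by = 1e-3)), dt = 1e-3)
#' @export
trace_record <- function(samples, dt, units = "mV", channel_id = "ch1") {
  samples <- as.numeric(samples)
  units <- sub("µ", "u", units)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (seconds)")
  if (length(samples) < 2L)
    stop("a trace needs at least 2 samples")
  if (!units %in% c("mV", "pA", "uV"))
    stop("units must be one of 'mV', 'pA', 'uV'")
  structure(list(samples = samples, dt = dt, units = units,
                 channel_id = as.character(channel_id)),
            class = "trace_record")
}

#' @export
print.trace_record <- function(x, ...) {
  cat(sprintf("<trace_record> %s: %d samples @ %g kHz (%.3f s), %s\n",
              x$channel_id, length(x$samples), 1e-3 / x$dt,
              length(x$samples) * x$dt, x$units))
  invisible(x)
}

#' @export
length.trace_record <- function(x) length(x$samples)

#' Sample times of a trace
#' @param trace a \code{trace_record}.
#' @return numeric vector of times in seconds, starting at 0.
#' @export
trace_times <- function(trace) (seq_along(trace$samples) - 1) * trace$dt

#' Read a trace from a delimited text file
#'
#' Accepts two layouts (header row required): a two-column \code{t,V} file
#' from which \code{dt} is inferred, or a single value column with
#' \code{dt} supplied explicitly. Field separator is auto-detected among
#' comma / tab / semicolon.
#'
#' @param path path to a CSV/TSV file.
#' @param format \code{"delimited"} (native) or \code{"nwb"} (not
#'   available in this build; errors with a pointer to conversion).
#' @param dt sampling interval in seconds; required when the file has no
#'   time column.
#' @param units,channel_id passed to [trace_record()].
#' @return a \code{trace_record}.
#' @export
read_trace <- function(path, format = c("delimited", "nwb"), dt = NULL,
                       units = "mV", channel_id = NULL) {
  format <- match.arg(format)
  if (format == "nwb")
    stop("NWB reading is not available in this build; convert to delimited text")
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- c("," = ",", "\t" = "\t", ";" = ";")[
    which.max(c(lengths(regmatches(first, gregexpr(",", first))),
                lengths(regmatches(first, gregexpr("\t", first))),
                lengths(regmatches(first, gregexpr(";", first))))
  )]
  d <- utils::read.table(path, header = TRUE, sep = unname(sep))
  if (is.null(channel_id)) channel_id <- basename(path)
  if (ncol(d) >= 2L) {
    tcol <- d[[1]]
    if (length(tcol) < 2L)
      stop("a trace needs at least 2 samples")
    if (any(diff(tcol) <= 0))
      stop("time column must be strictly increasing")
    steps <- diff(tcol)
    if (max(steps) - min(steps) > 1e-6 * stats::median(steps))
      stop("time column is not uniformly sampled")
    trace_record(d[[2]], dt = stats::median(steps), units = units,
                 channel_id = channel_id)
  } else {
    if (is.null(dt))
      stop("file has no time column; dt must be supplied")
    trace_record(d[[1]], dt = dt, units = units, channel_id = channel_id)
  }
}

#' Write a trace to a delimited text file
#'
#' Two-column CSV (\code{t_s}, value) with header; round-trips through
#' [read_trace()].
#'
#' @param trace a \code{trace_record}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trace_record"))
  d <- data.frame(t_s = trace_times(trace), value = trace$samples)
  names(d)[2] <- paste0("value_", trace$units)
  utils::write.csv(format(d, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
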