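#' Uniformly sampled electrophysiological trace
#'
#' Container for a single-channel EMG or LFP time series in microvolts.
#'
#' @param samples numeric vector of sample values (microvolts).
#' @param rate_hz sampling rate (Hz), > 0.
#' @param t0_s time of the first sample (s).
#' @param channel_label free-text channel name, e.g. `"ECR"`, `"C5_LFP"`.
#' @return an object of class `emg_trace`.
#' @export
emg_trace <- function(samples, rate_hz, t0_s = 0, channel_label = "EMG") {
  stopifnot(is.numeric(samples), is.numeric(rate_hz), length(rate_hz) == 1L,
            rate_hz > 0, is.finite(rate_hz), is.numeric(t0_s), length(t0_s) == 1L)
  if (length(samples) && any(!is.finite(samples)))
    stop("trace samples must be finite")
  structure(list(samples = as.numeric(samples), rate_hz = rate_hz,
                 t0_s = t0_s, channel_label = channel_label),
            class = "emg_trace")
}

#' Sample times of a trace
#' @param trace an [emg_trace()].
#' @return numeric vector of sample times (s).
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "emg_trace"))
  trace$t0_s + (seq_along(trace$samples) - 1L) / trace$rate_hz
}

#' Duration of a trace
#' @param trace an [emg_trace()].
#' @return duration in seconds (`n / rate`).
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$rate_hz

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf("emg_trace '%s': %d samples @ %g Hz (%.3f s from t0 = %g s)\n",
              x$channel_label, length(x$samples), x$rate_hz,
              trace_duration(x), x$t0_s))
  invisible(x)
}

# extract [from_s, to_s) as a new trace; bounds clamped to the trace extent
trace_window <- function(trace, from_s, to_s) {
  i0 <- max(1L, 1L + as.integer(round((from_s - trace$t0_s) * trace$rate_hz)))
  i1 <- min(length(trace$samples),
            as.integer(round((to_s - trace$t0_s) * trace$rate_hz)))
  if (i1 < i0) stop("empty trace window")
  emg_trace(trace$samples[i0:i1], trace$rate_hz,
            t0_s = trace$t0_s + (i0 - 1L) / trace$rate_hz,
            channel_label = trace$channel_label)
}

#' Write a trace to a plain-text file
#'
#' Two-column (time_s, value_uV) tab-delimited text with a small `#`-prefixed
#' header carrying the sampling rate and channel label, so that traces can be
#' exchanged with other tools or replayed through the analysis.
#'
#' @param trace an [emg_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_emg_trace <- function(trace, path) {
  stopifnot(inherits(trace, "emg_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate_hz=%.10g", trace$rate_hz),
               sprintf("# channel_label=%s", trace$channel_label),
               "time_s\tvalue_uV"), con)
  utils::write.table(data.frame(time_s = trace_times(trace),
                                value_uV = trace$samples),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a trace written by [write_emg_trace()]
#' @param path file path.
#' @return an [emg_trace()].
#' @export
read_emg_trace <- function(path) {
  hdr <- readLines(path, n = 2L)
  rate <- as.numeric(sub("# rate_hz=", "", hdr[1], fixed = TRUE))
  lab <- sub("# channel_label=", "", hdr[2], fixed = TRUE)
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  emg_trace(d$value_uV, rate, t0_s = d$time_s[1], channel_label = lab)
}

#' Stimulus event
#'
#' One electrical stimulation pulse, at the cortex or the muscle.
#'
#' @param time_s event time (s).
#' @param site `"cortex"` or `"muscle"`.
#' @param amplitude current amplitude (uA for cortex, mA for muscle), > 0.
#' @param pulse_width_ms biphasic pulse duration (ms), default 0.2.
#' @param phase which protocol phase issued the pulse: `"probe"`, `"pas"`
#'   or `"acute"`.
#' @return an object of class `stimulus_event`.
#' @export
stimulus_event <- function(time_s, site = c("cortex", "muscle"),
                           amplitude = 1000, pulse_width_ms = 0.2,
                           phase = c("probe", "pas", "acute")) {
  site <- match.arg(site)
  phase <- match.arg(phase)
  stopifnot(is.numeric(time_s), length(time_s) == 1L, is.finite(time_s),
            amplitude > 0, pulse_width_ms > 0)
  structure(list(time_s = time_s, site = site, amplitude = amplitude,
                 pulse_width_ms = pulse_width_ms, phase = phase),
            class = "stimulus_event")
}

#' Write / read a stimulus event table
#'
#' Delimited table (time_s, site, amplitude, pulse_width_ms, phase).
#'
#' @param events a list of [stimulus_event()] objects.
#' @param path file path.
#' @return `write_stimulus_events` returns `path` invisibly;
#'   `read_stimulus_events` returns a list of [stimulus_event()]s.
#' @export
write_stimulus_events <- function(events, path) {
  d <- do.call(rbind, lapply(events, function(e)
    data.frame(time_s = e$time_s, site = e$site, amplitude = e$amplitude,
               pulse_width_ms = e$pulse_width_ms, phase = e$phase)))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_events
#' @export
read_stimulus_events <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  lapply(seq_len(nrow(d)), function(i)
    stimulus_event(d$time_s[i], d$site[i], d$amplitude[i],
                   d$pulse_width_ms[i], d$phase[i]))
}
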