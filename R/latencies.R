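#' Corticospinal conduction latencies
#'
#' Bookkeeping container for the conduction delays that link cortical and
#' muscle stimulation to pre- and postsynaptic activity at the spinal cord and
#' the motor cortex. Defaults are the values measured in acute preparations:
#' a cortical stimulus takes ~9 ms to reach the motoneurons (including
#' synaptic integration time), efferent/antidromic conduction between
#' motoneurons and muscle takes ~3 ms, the afferent volley from muscle
#' stimulation peaks in motor cortex at ~16 ms, and the resulting MEP onset in
#' a forelimb muscle follows cortical stimulation by ~12 ms.
#'
#' The MEP onset latency must equal the sum of the cortex-to-motoneuron and
#' motoneuron-to-muscle delays; a mismatch is a configuration error.
#'
#' @param cortex_to_motoneuron_ms delay from cortical stimulus to the
#'   corticospinal volley arriving at the motoneurons (ms).
#' @param motoneuron_to_muscle_ms efferent conduction delay between motoneuron
#'   and muscle; the same value is used for antidromic propagation from a
#'   muscle stimulus back to the motoneuron somata (ms).
#' @param muscle_to_cortex_afferent_ms delay from muscle stimulus to the peak
#'   of the evoked afferent volley in motor cortex (ms).
#' @param cortical_stim_to_mep_onset_ms delay from cortical stimulus to MEP
#'   onset in the target muscle (ms). Must equal
#'   `cortex_to_motoneuron_ms + motoneuron_to_muscle_ms`.
#' @return an object of class `conduction_latencies`.
#' @export
#' @examples
#' conduction_latencies()
conduction_latencies <- function(cortex_to_motoneuron_ms = 9,
                                 motoneuron_to_muscle_ms = 3,
                                 muscle_to_cortex_afferent_ms = 16,
                                 cortical_stim_to_mep_onset_ms =
                                   cortex_to_motoneuron_ms + motoneuron_to_muscle_ms) {
  lat <- list(
    cortex_to_motoneuron_ms = cortex_to_motoneuron_ms,
    motoneuron_to_muscle_ms = motoneuron_to_muscle_ms,
    muscle_to_cortex_afferent_ms = muscle_to_cortex_afferent_ms,
    cortical_stim_to_mep_onset_ms = cortical_stim_to_mep_onset_ms
  )
  for (nm in names(lat)) {
    v <- lat[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("latency '%s' must be a single positive finite number", nm))
  }
  if (abs(cortical_stim_to_mep_onset_ms -
          (cortex_to_motoneuron_ms + motoneuron_to_muscle_ms)) > 1e-9)
    stop("inconsistent latencies: cortical_stim_to_mep_onset_ms must equal ",
         "cortex_to_motoneuron_ms + motoneuron_to_muscle_ms")
  structure(lat, class = "conduction_latencies")
}

#' @export
print.conduction_latencies <- function(x, ...) {
  cat("Conduction latencies (ms):\n")
  cat(sprintf("  cortex -> motoneurons : %g\n", x$cortex_to_motoneuron_ms))
  cat(sprintf("  motoneuron <-> muscle : %g\n", x$motoneuron_to_muscle_ms))
  cat(sprintf("  muscle -> cortex      : %g\n", x$muscle_to_cortex_afferent_ms))
  cat(sprintf("  cortical stim -> MEP  : %g\n", x$cortical_stim_to_mep_onset_ms))
  invisible(x)
}
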