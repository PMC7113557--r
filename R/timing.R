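#' Interstimulus interval to pre/post synaptic timing offsets
#'
#' Converts a signed cortex-muscle interstimulus interval (ISI, positive when
#' the muscle is stimulated after the cortex) into the presynaptic minus
#' postsynaptic activity offsets at the spinal cord and the motor cortex,
#' given the conduction latencies.
#'
#' With cortical stimulation at t = 0 and muscle stimulation at t = ISI: the
#' orthodromic corticospinal volley reaches the motoneurons at
#' `cortex_to_motoneuron_ms`; the antidromic volley from the muscle arrives at
#' `ISI + motoneuron_to_muscle_ms`; the afferent volley reaches motor cortex
#' at `ISI + muscle_to_cortex_afferent_ms`. The spinal offset is positive when
#' the orthodromic (presynaptic) volley arrives before the antidromic
#' (postsynaptic) one; the cortical offset is positive when the afferent
#' (presynaptic) volley arrives before the cortical stimulation.
#'
#' @param isi_ms signed interstimulus interval(s) in ms. Vectorized.
#' @param lat a [conduction_latencies()].
#' @return a data frame with columns `spinal_offset_ms` and
#'   `cortical_offset_ms`.
#' @export
#' @examples
#' isi_to_offsets(6)    # spinal offset 0, cortical offset -22
#' isi_to_offsets(-16)  # cortical offset 0
isi_to_offsets <- function(isi_ms, lat = conduction_latencies()) {
  stopifnot(inherits(lat, "conduction_latencies"), is.numeric(isi_ms))
  spinal <- (isi_ms + lat$motoneuron_to_muscle_ms) - lat$cortex_to_motoneuron_ms
  cortical <- -(isi_ms + lat$muscle_to_cortex_afferent_ms)
  data.frame(spinal_offset_ms = spinal, cortical_offset_ms = cortical)
}

#' Predicted plasticity effect at one site
#'
#' Classifies a timing offset under an STDP window: LTP if the per-pair gain
#' change exceeds `effect_floor`, LTD if it is below `-effect_floor`, and none
#' otherwise (including the zero-offset convention and offsets far outside the
#' exponential window).
#'
#' @param offset_ms signed pre-minus-post timing offset(s) in ms. Vectorized.
#' @param window an [stdp_window()].
#' @return character vector in `{"LTP", "LTD", "none"}`.
#' @export
predict_effect <- function(offset_ms, window = stdp_window()) {
  d <- stdp_delta(offset_ms, window)
  out <- rep("none", length(d))
  out[d > window$effect_floor] <- "LTP"
  out[d < -window$effect_floor] <- "LTD"
  out
}

#' One PAS condition
#'
#' Builds a single ISI condition with its derived timing offsets and predicted
#' per-site effects. Paired conditions require an ISI; controls
#' (`cortex_only`, `muscle_only`, `no_stim`) have no derived fields.
#'
#' @param kind `"paired"`, `"cortex_only"`, `"muscle_only"` or `"no_stim"`.
#' @param isi_ms signed ISI in ms; required iff `kind = "paired"`.
#' @param lat a [conduction_latencies()].
#' @param window an [stdp_window()] for effect prediction.
#' @param label condition label; defaults to `"ISI<isi>"` or the kind.
#' @return an object of class `isi_condition` (a one-row list).
#' @export
isi_condition <- function(kind = c("paired", "cortex_only", "muscle_only",
                                   "no_stim"),
                          isi_ms = NULL, lat = conduction_latencies(),
                          window = stdp_window(), label = NULL) {
  kind <- match.arg(kind)
  if (kind == "paired") {
    if (is.null(isi_ms) || !is.finite(isi_ms))
      stop("paired condition requires a finite isi_ms")
    off <- isi_to_offsets(isi_ms, lat)
    cond <- list(kind = kind, isi_ms = isi_ms,
                 spinal_offset_ms = off$spinal_offset_ms,
                 cortical_offset_ms = off$cortical_offset_ms,
                 predicted_spinal = predict_effect(off$spinal_offset_ms, window),
                 predicted_cortical = predict_effect(off$cortical_offset_ms, window),
                 label = if (is.null(label)) sprintf("ISI%+g", isi_ms) else label)
  } else {
    if (!is.null(isi_ms)) stop("control conditions take no isi_ms")
    cond <- list(kind = kind, isi_ms = NA_real_,
                 spinal_offset_ms = NA_real_, cortical_offset_ms = NA_real_,
                 predicted_spinal = "none", predicted_cortical = "none",
                 label = if (is.null(label)) kind else label)
  }
  structure(cond, class = "isi_condition")
}

#' Default reconstructed ISI list
#'
#' The experiment tested 11 paired ISIs; only -15, +6 and +505 ms are named in
#' the main text (+505 being the extralong timing control counted among the
#' four controls). This default list is a plausible reconstruction spanning
#' spinal offsets of about -31 to +15 ms plus cortically relevant timings; it
#' is fully user-overridable and no analysis depends on the exact values.
#'
#' @return numeric vector of 11 ISIs (ms).
#' @export
default_isi_list <- function() c(-25, -15, -10, -5, -1, 2, 6, 9, 12, 15, 21)

#' Build the full condition table
#'
#' Derives one [isi_condition()] per paired ISI plus the requested controls.
#' With the 11 reconstructed ISIs and the four controls of the study (cortex
#' only, muscle only, no stimulation, and the +505 ms extralong timing
#' control) the table has 15 rows.
#'
#' @param isi_list paired ISIs in ms (default [default_isi_list()]).
#' @param controls character vector of control kinds; `"extralong"` denotes
#'   the +505 ms paired timing control.
#' @param lat a [conduction_latencies()].
#' @param window an [stdp_window()].
#' @param extralong_isi_ms ISI of the extralong control (ms, default +505).
#' @return a data frame of class `isi_condition_table`, one row per condition,
#'   with unique labels.
#' @export
build_condition_table <- function(isi_list = default_isi_list(),
                                  controls = c("cortex_only", "muscle_only",
                                               "no_stim", "extralong"),
                                  lat = conduction_latencies(),
                                  window = stdp_window(),
                                  extralong_isi_ms = 505) {
  conds <- lapply(isi_list, function(isi)
    isi_condition("paired", isi, lat, window))
  for (ctl in controls) {
    conds[[length(conds) + 1L]] <- if (ctl == "extralong") {
      isi_condition("paired", extralong_isi_ms, lat, window,
                    label = sprintf("ISI%+g (extralong control)",
                                    extralong_isi_ms))
    } else {
      isi_condition(ctl, lat = lat, window = window)
    }
  }
  tab <- do.call(rbind, lapply(conds, function(cn)
    data.frame(label = cn$label, kind = cn$kind, isi_ms = cn$isi_ms,
               spinal_offset_ms = cn$spinal_offset_ms,
               cortical_offset_ms = cn$cortical_offset_ms,
               predicted_spinal = cn$predicted_spinal,
               predicted_cortical = cn$predicted_cortical,
               stringsAsFactors = FALSE)))
  if (anyDuplicated(tab$label))
    stop("duplicate condition labels")
  class(tab) <- c("isi_condition_table", "data.frame")
  tab
}

# one row of a condition table back into an isi_condition-shaped list
condition_row <- function(tab, i) {
  cn <- as.list(tab[i, , drop = FALSE])
  cn <- lapply(cn, unlist, use.names = FALSE)
  structure(cn, class = "isi_condition")
}
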