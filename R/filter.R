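#' Continuous-data filter specification
#'
#' Zero-phase (forward-backward) Butterworth filtering: high-pass to remove
#' slow drifts, low-pass to remove high-frequency (stimulator) artifacts, and
#' a narrow band-stop for line noise.
#'
#' @param highpass_hz high-pass cutoff (Hz), `NULL` to skip.
#' @param lowpass_hz low-pass cutoff (Hz), `NULL` to skip.
#' @param bandstop_hz length-2 stop band (Hz), `NULL` to skip.
#' @param order filter order per pass (applied bidirectionally).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(highpass_hz = 0.5, lowpass_hz = 95,
                        bandstop_hz = c(49.5, 50.5), order = 4) {
  if (!is.null(highpass_hz) && !is.null(lowpass_hz) &&
      highpass_hz >= lowpass_hz) stopf("highpass must be below lowpass")
  if (!is.null(bandstop_hz) && !is.null(lowpass_hz) &&
      bandstop_hz[2] > lowpass_hz)
    stopf("bandstop must lie inside the passband")
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 bandstop_hz = bandstop_hz, order = order),
            class = "filter_spec")
}

.apply_filtfilt <- function(signal, flt) {
  t(apply(signal, 1, function(ch) signal::filtfilt(flt, ch)))
}

#' Zero-phase filtering of a continuous recording
#'
#' Applies the configured high-pass, low-pass and band-stop Butterworth
#' filters forward and backward (zero group delay by construction).
#'
#' @param rec a `tp_recording`.
#' @param spec a [filter_spec()].
#' @return the filtered `tp_recording`.
#' @export
filter_continuous <- function(rec, spec = filter_spec()) {
  fs <- rec$fs
  nyq <- fs / 2
  sig <- rec$signal
  if (!is.null(spec$highpass_hz)) {
    if (spec$highpass_hz >= nyq) stopf("highpass at/above Nyquist")
    sig <- .apply_filtfilt(sig, signal::butter(spec$order,
                                               spec$highpass_hz / nyq, "high"))
  }
  if (!is.null(spec$lowpass_hz)) {
    if (spec$lowpass_hz >= nyq) stopf("lowpass at/above Nyquist")
    sig <- .apply_filtfilt(sig, signal::butter(spec$order,
                                               spec$lowpass_hz / nyq, "low"))
  }
  if (!is.null(spec$bandstop_hz)) {
    if (spec$bandstop_hz[2] >= nyq) stopf("bandstop at/above Nyquist")
    sig <- .apply_filtfilt(sig, signal::butter(spec$order,
                                               spec$bandstop_hz / nyq, "stop"))
  }
  rownames(sig) <- rownames(rec$signal)
  rec$signal <- sig
  rec$filtered <- spec
  rec
}

#' Cut variable-length epochs around each trial
#'
#' Each epoch runs from `epoch_pad_ms` before movement onset to
#' `epoch_pad_ms` after the reappeared stimulus' offset, so epoch lengths
#' vary with the movement interval and \eqn{\Delta t}. Trials whose epoch
#' would leave the recording, or with missing markers, are dropped with a log
#' entry.
#'
#' @param rec a `tp_recording` with markers.
#' @param design a [task_design()] (defaults to the recording's schedule
#'   design).
#' @return object of class `tp_epochs`: `trials` (list of channel x sample
#'   matrices), `events` (per-trial event latencies in ms from epoch start),
#'   `fs`, `layout`, `dropped` (trial ids).
#' @export
epoch_recording <- function(rec, design = NULL) {
  design <- design %||% attr(rec$schedule, "design")
  fs <- rec$fs
  pad <- round(design$epoch_pad_ms * fs / 1000)
  mk <- rec$markers
  ids <- sort(unique(mk$trial_id))
  trials <- list(); events <- list(); dropped <- integer(0)
  for (id in ids) {
    m <- mk[mk$trial_id == id, ]
    need <- c("move_on", "disappear", "reappear", "offset")
    if (!all(need %in% m$label)) {
      dropped <- c(dropped, id)
      next
    }
    smp <- vapply(need, function(l) m$sample[m$label == l][1], 0L)
    from <- smp["move_on"] - pad
    to <- smp["offset"] + pad
    if (from < 1 || to > ncol(rec$signal)) {
      dropped <- c(dropped, id)
      next
    }
    trials[[length(trials) + 1]] <- rec$signal[, from:to, drop = FALSE]
    events[[length(events) + 1]] <-
      data.frame(trial_id = id, t((smp - from) / fs * 1000))
  }
  if (length(dropped))
    message(sprintf("epoch_recording: dropped %d trial(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  ev <- do.call(rbind, events)
  structure(list(trials = trials, events = ev, fs = fs,
                 layout = rec$layout, dropped = dropped,
                 n_scheduled = length(ids)),
            class = "tp_epochs")
}

#' @export
print.tp_epochs <- function(x, ...) {
  durs <- vapply(x$trials, ncol, 0L) / x$fs * 1000
  cat(sprintf("Epochs: %d trials (%d dropped), %d channels, durations %g-%g ms\n",
              length(x$trials), length(x$dropped),
              nrow(x$trials[[1]]), min(durs), max(durs)))
  invisible(x)
}

#' Keep a subset of epochs (e.g. subjectively correct trials)
#' @param epochs a `tp_epochs`.
#' @param keep logical or integer index over trials.
#' @return the subset `tp_epochs`.
#' @export
subset_epochs <- function(epochs, keep) {
  if (is.logical(keep)) keep <- which(keep)
  epochs$trials <- epochs$trials[keep]
  epochs$events <- epochs$events[keep, , drop = FALSE]
  epochs
}
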