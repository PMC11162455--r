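# Minimal EEG preprocessing: zero-phase Butterworth filtering, anti-aliased
# downsampling, average re-referencing, epoch extraction, baseline
# correction and condition averaging.

#' Construct a continuous EEG recording
#'
#' @param data Channels x samples numeric matrix, in microvolt.
#' @param channel_names Character vector, one name per row of `data`.
#' @param sfreq Sampling rate in Hz.
#' @param events Data frame with columns `sample` (1-based sample index) and
#'   `code`; may be empty.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, channel_names, sfreq,
                          events = data.frame(sample = integer(), code = integer())) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == length(channel_names))
  stopifnot_scalar(sfreq, "sfreq", lower = 1e-9)
  if (nrow(events) && (any(events$sample < 1) || any(events$sample > ncol(data)))) {
    stop("event sample indices must lie within the recording", call. = FALSE)
  }
  rownames(data) <- channel_names
  structure(list(data = data, channel_names = channel_names,
                 sfreq = sfreq, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$sfreq, nrow(x$events)))
  invisible(x)
}

#' Construct an epoch set
#'
#' @param data Trials x channels x samples array, microvolt.
#' @param times_ms Time axis in ms relative to the event, one per sample.
#' @param labels Binary (0/1) trial labels, 1 = correct response.
#' @param channel_names Channel names.
#' @param sfreq Sampling rate in Hz.
#' @param subject_id Optional subject identifier.
#' @return An `eeg_epochs` object.
#' @export
eeg_epochs <- function(data, times_ms, labels, channel_names, sfreq,
                       subject_id = NULL) {
  stopifnot(length(dim(data)) == 3L,
            dim(data)[2] == length(channel_names),
            dim(data)[3] == length(times_ms),
            dim(data)[1] == length(labels))
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  dimnames(data) <- list(NULL, channel_names, NULL)
  structure(list(data = data, times_ms = as.numeric(times_ms),
                 labels = as.integer(labels),
                 channel_names = channel_names, sfreq = sfreq,
                 subject_id = subject_id),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs%s> %d trials x %d channels x %d samples, [%g, %g] ms @ %g Hz (%d correct / %d incorrect)\n",
              if (!is.null(x$subject_id)) paste0(" ", x$subject_id) else "",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times_ms), max(x$times_ms), x$sfreq,
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

apply_filtfilt <- function(data, filt) {
  out <- t(apply(data, 1L, function(ch) signal::filtfilt(filt, ch)))
  dimnames(out) <- dimnames(data)
  out
}

#' High-pass filter a recording
#'
#' 4th-order Butterworth applied forward-backward (zero phase), so component
#' latencies are preserved while DC offsets and sub-cutoff drift are removed.
#'
#' @param recording An `eeg_recording`.
#' @param cutoff Cutoff frequency in Hz; must be below Nyquist.
#' @return The filtered `eeg_recording`.
#' @export
highpass <- function(recording, cutoff = 1) {
  stopifnot(inherits(recording, "eeg_recording"))
  nyq <- recording$sfreq / 2
  if (cutoff <= 0 || cutoff >= nyq) {
    stop("`cutoff` must lie in (0, Nyquist)", call. = FALSE)
  }
  filt <- signal::butter(4, cutoff / nyq, type = "high")
  recording$data <- apply_filtfilt(recording$data, filt)
  recording
}

#' Notch-filter line noise
#'
#' Second-order Butterworth band-stop, zero-phase. Not part of the default
#' synthetic pipeline (the generator injects no line noise) but provided for
#' real recordings.
#'
#' @param recording An `eeg_recording`.
#' @param freq Centre frequency in Hz (50 or 60 typically).
#' @param width Half-width of the stop band in Hz.
#' @return The filtered `eeg_recording`.
#' @export
notch <- function(recording, freq = 50, width = 2) {
  stopifnot(inherits(recording, "eeg_recording"))
  nyq <- recording$sfreq / 2
  if (freq + width >= nyq || freq - width <= 0) {
    stop("stop band must lie inside (0, Nyquist)", call. = FALSE)
  }
  filt <- signal::butter(2, c(freq - width, freq + width) / nyq, type = "stop")
  recording$data <- apply_filtfilt(recording$data, filt)
  recording
}

#' Downsample a recording
#'
#' Anti-alias low-pass (4th-order Butterworth at 80% of the new Nyquist,
#' zero-phase) followed by decimation. Only integer decimation factors are
#' supported; event sample indices are rescaled onto the new grid.
#'
#' @param recording An `eeg_recording`.
#' @param target_sfreq New sampling rate; `sfreq / target_sfreq` must be a
#'   whole number.
#' @return The decimated `eeg_recording`.
#' @export
downsample <- function(recording, target_sfreq = 250) {
  stopifnot(inherits(recording, "eeg_recording"))
  q <- recording$sfreq / target_sfreq
  if (target_sfreq > recording$sfreq) {
    stop("`target_sfreq` must not exceed the current rate", call. = FALSE)
  }
  if (abs(q - round(q)) > 1e-9) {
    stop("only integer decimation factors are supported", call. = FALSE)
  }
  q <- as.integer(round(q))
  if (q == 1L) return(recording)
  filt <- signal::butter(4, 0.8 / q, type = "low")
  filtered <- apply_filtfilt(recording$data, filt)
  keep <- seq(1L, ncol(filtered), by = q)
  recording$data <- filtered[, keep, drop = FALSE]
  recording$sfreq <- target_sfreq
  if (nrow(recording$events)) {
    recording$events$sample <- as.integer((recording$events$sample - 1L) %/% q + 1L)
  }
  recording
}

#' Re-reference to the channel average
#'
#' Subtracts the per-sample mean across channels, making every column of the
#' data sum to (numerically) zero. Idempotent.
#'
#' @param recording An `eeg_recording` with at least two channels.
#' @return The re-referenced `eeg_recording`.
#' @export
average_reference <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (nrow(recording$data) < 2L) {
    stop("average reference needs at least two channels", call. = FALSE)
  }
  recording$data <- sweep(recording$data, 2L, colMeans(recording$data))
  recording
}

#' Extract fixed-window epochs around events
#'
#' Cuts one epoch per event, spanning `window` (ms, inclusive endpoints when
#' they fall exactly on a sample: at 250 Hz a \[-100, 1000\] ms window yields
#' 276 samples). The sample at t = 0 is the event sample. Events whose window
#' does not fit inside the recording are dropped with a warning, together
#' with their labels.
#'
#' @param recording An `eeg_recording` with events.
#' @param window `c(start_ms, end_ms)` relative to each event.
#' @param labels Binary labels aligned with the event order.
#' @param event_code Optional: use only events with this code.
#' @param subject_id Passed through to the result.
#' @return An `eeg_epochs` object.
#' @export
extract_epochs <- function(recording, window = c(-100, 1000), labels,
                           event_code = NULL, subject_id = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  ev <- recording$events
  if (!is.null(event_code)) ev <- ev[ev$code == event_code, , drop = FALSE]
  if (!nrow(ev)) stop("no events to epoch", call. = FALSE)
  if (length(labels) != nrow(ev)) {
    stop("`labels` must have one entry per event", call. = FALSE)
  }
  o1 <- round(window[1] * recording$sfreq / 1000)
  o2 <- round(window[2] * recording$sfreq / 1000)
  ok <- ev$sample + o1 >= 1L & ev$sample + o2 <= ncol(recording$data)
  if (any(!ok)) {
    warning(sum(!ok), " event(s) rejected: epoch window out of bounds")
  }
  ev <- ev[ok, , drop = FALSE]
  labels <- labels[ok]
  if (!nrow(ev)) stop("all events rejected", call. = FALSE)
  ns <- o2 - o1 + 1L
  arr <- array(0, c(nrow(ev), nrow(recording$data), ns))
  for (i in seq_len(nrow(ev))) {
    arr[i, , ] <- recording$data[, (ev$sample[i] + o1):(ev$sample[i] + o2)]
  }
  eeg_epochs(arr, (o1:o2) * 1000 / recording$sfreq, labels,
             recording$channel_names, recording$sfreq, subject_id)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline interval
#' (default the pre-stimulus \[-100, 0\] ms).
#'
#' @param epochs An `eeg_epochs`.
#' @param interval `c(start_ms, end_ms)` of the baseline.
#' @return The corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, interval = c(-100, 0)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  idx <- which(epochs$times_ms >= interval[1] & epochs$times_ms <= interval[2])
  if (!length(idx)) stop("baseline interval contains no samples", call. = FALSE)
  base <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - array(base, dim(epochs$data))
  epochs
}

#' Condition-average waveform
#'
#' Arithmetic mean over the trials with the requested label.
#'
#' @param epochs An `eeg_epochs`.
#' @param label_value 0 or 1.
#' @return Channels x samples matrix.
#' @export
condition_average <- function(epochs, label_value) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  sel <- which(epochs$labels == label_value)
  if (!length(sel)) stop("no epochs with label ", label_value, call. = FALSE)
  out <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  rownames(out) <- epochs$channel_names
  out
}
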