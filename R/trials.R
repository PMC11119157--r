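#' Construct an EEG trial
#'
#' An `eeg_trial` is the atomic input of the package: a channels x samples
#' real matrix recorded at a fixed sampling rate, carrying an ordered list of
#' channel names, a binary class label and an identifier.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channels character vector of unique channel names, one per row of
#'   `data`.  Defaults to `"ch1" ... "chC"`.
#' @param label class label, one of the two labels of the task.
#' @param trial_id identifier string, unique within a dataset.
#' @return An object of class `eeg_trial`.
#' @export
eeg_trial <- function(data, fs, channels = NULL, label = NA_character_,
                      trial_id = "trial") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L) stop("an EEG trial needs at least 2 channels")
  if (ncol(data) < 1L) stop("an EEG trial needs at least 1 sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz")
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  channels <- as.character(channels)
  if (length(channels) != nrow(data))
    stop("`channels` must name every row of `data`")
  if (anyDuplicated(channels)) stop("channel names must be unique")
  rownames(data) <- channels
  structure(
    list(data = data, fs = as.numeric(fs), channels = channels,
         label = as.character(label), trial_id = as.character(trial_id)),
    class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial '%s'> %d channels x %d samples @ %g Hz (%.3g s), label = %s\n",
              x$trial_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs, x$label))
  invisible(x)
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d x %d @ %g Hz, label = %s, trial '%s', start sample %d\n",
              nrow(x$data), ncol(x$data), x$fs, x$label,
              x$parent_trial_id, x$start_sample))
  invisible(x)
}

n_samples <- function(trial) ncol(trial$data)
n_channels <- function(trial) nrow(trial$data)

#' Cut a trial into overlapping windows
#'
#' Trials are segmented into fixed-length windows that slide by
#' `window_s - overlap_s` seconds; every segment inherits the trial's label
#' and records its parent trial and start sample.  Windows are half-open
#' sample ranges `[s, s + w)`; an incomplete tail is dropped.  A 60 s trial
#' at 128 Hz cut with a 4 s window and 2 s overlap yields 29 segments.
#'
#' @param trial an [eeg_trial()].
#' @param window_s window length in seconds.
#' @param overlap_s overlap between consecutive windows in seconds;
#'   `0 <= overlap_s < window_s`.
#' @return A list of `eeg_segment` objects (which are also `eeg_trial`s),
#'   each with `parent_trial_id` and 0-based `start_sample` fields.
#' @export
segment_trial <- function(trial, window_s, overlap_s = 0) {
  stopifnot(inherits(trial, "eeg_trial"))
  if (!(window_s > 0)) stop("`window_s` must be positive")
  if (overlap_s < 0 || overlap_s >= window_s)
    stop("`overlap_s` must satisfy 0 <= overlap_s < window_s")
  w <- round_half_up(window_s * trial$fs)
  step <- round_half_up((window_s - overlap_s) * trial$fs)
  if (step < 1L) stop("window step rounds to zero samples")
  T_len <- n_samples(trial)
  if (w > T_len)
    stop(sprintf("window (%d samples) longer than trial '%s' (%d samples)",
                 w, trial$trial_id, T_len))
  starts <- seq.int(0L, T_len - w, by = step)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    seg <- eeg_trial(trial$data[, (s + 1L):(s + w), drop = FALSE],
                     fs = trial$fs, channels = trial$channels,
                     label = trial$label,
                     trial_id = sprintf("%s/seg%03d", trial$trial_id, i))
    seg$parent_trial_id <- trial$trial_id
    seg$start_sample <- as.integer(s)
    class(seg) <- c("eeg_segment", class(seg))
    seg
  })
}

#' Segment a list of trials
#'
#' @param trials list of [eeg_trial()] objects.
#' @inheritParams segment_trial
#' @return A flat list of segments.
#' @export
segment_trials <- function(trials, window_s, overlap_s = 0) {
  unlist(lapply(trials, segment_trial, window_s = window_s,
                overlap_s = overlap_s), recursive = FALSE)
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero-phase) to every channel.
#'
#' @param trial an [eeg_trial()] (or segment).
#' @param lo_hz,hi_hz band edges in Hz; must satisfy
#'   `0 < lo_hz < hi_hz < fs/2`.
#' @param order filter order (of the underlying one-pass Butterworth).
#' @return The trial with filtered data; shape, label and metadata preserved.
#' @export
eeg_bandpass <- function(trial, lo_hz, hi_hz, order = 4L) {
  stopifnot(inherits(trial, "eeg_trial"))
  nyq <- trial$fs / 2
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < nyq))
    stop(sprintf("band [%g, %g] Hz outside (0, Nyquist = %g) Hz",
                 lo_hz, hi_hz, nyq))
  bf <- signal::butter(order, c(lo_hz, hi_hz) / nyq, type = "pass")
  out <- t(apply(trial$data, 1L, function(x) signal::filtfilt(bf, x)))
  dimnames(out) <- dimnames(trial$data)
  trial$data <- out
  trial
}
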