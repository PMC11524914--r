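# Shared data model: the containers every pipeline stage consumes.
# Conventions fixed across the package: amplitudes in microvolts, epoch
# times in milliseconds relative to stimulus onset, frequencies in Hz,
# windows half-open [start, end).  At 250 Hz sample k of an epoch starting
# at t_start maps to t_start + 4 k ms.

DEVICE_RANGE_UV <- 393

#' Two-channel continuous EEG recording
#'
#' Container for a continuous prefrontal EEG recording.  The pipeline is
#' specialised to exactly two channels (left/right prefrontal, Fp1 and Fp2
#' of the 10/20 system) referenced to the right earlobe, sampled uniformly.
#'
#' @param samples Numeric matrix `[2 x timepoints]` of amplitudes in
#'   microvolts, one row per channel.
#' @param fs Sampling rate in Hz (the portable device records at 250 Hz).
#' @param channel_labels Character vector of channel names, ordered as the
#'   rows of `samples`.
#' @param start_time Recording clock zero in seconds; event onsets are
#'   expressed on the same clock.
#' @param check_range If `TRUE`, enforce the acquisition device's input
#'   range of +/- 393 microvolts.  Internal filtered copies disable the
#'   check because pass-band ringing may overshoot marginally.
#' @return An object of class `recording`.
#' @export
recording <- function(samples, fs, channel_labels = c("Fp1", "Fp2"),
                      start_time = 0, check_range = TRUE) {
  samples <- as.matrix(samples)
  if (nrow(samples) != 2) {
    stop("a recording must have exactly 2 channels, got ", nrow(samples))
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("'fs' must be a single positive number")
  }
  if (length(channel_labels) != 2) stop("need 2 channel labels")
  if (!all(is.finite(samples))) stop("recording contains non-finite samples")
  if (check_range && max(abs(samples)) > DEVICE_RANGE_UV + 1e-9) {
    stop(
      "amplitudes exceed the device input range of +/-",
      DEVICE_RANGE_UV, " uV"
    )
  }
  rownames(samples) <- channel_labels
  structure(
    list(
      samples = samples, fs = fs, channel_labels = channel_labels,
      start_time = start_time
    ),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(
    sprintf(
      "<recording> %s | %d samples @ %g Hz (%.1f s)\n",
      paste(x$channel_labels, collapse = "/"),
      ncol(x$samples), x$fs, ncol(x$samples) / x$fs
    )
  )
  invisible(x)
}

n_samples <- function(rec) ncol(rec$samples)

#' Stimulus event log
#'
#' Onsets and kinds of the auditory stimuli of an oddball session.
#'
#' @param onsets Stimulus onset times in seconds from recording start,
#'   strictly increasing.
#' @param kinds Character or factor vector, one of `"standard"` (frequent
#'   750 Hz tone) or `"target"` (rare 2000 Hz tone), one per onset.
#' @param stimulus_duration Tone duration in ms.
#' @return An object of class `event_log` (a data frame with columns
#'   `onset_s` and `kind`).
#' @export
event_log <- function(onsets, kinds, stimulus_duration = 50) {
  if (length(onsets) == 0) stop("event log must contain at least one stimulus")
  if (length(onsets) != length(kinds)) stop("onsets/kinds length mismatch")
  kinds <- as.character(kinds)
  bad <- setdiff(unique(kinds), c("standard", "target"))
  if (length(bad)) stop("unknown stimulus kind: ", paste(bad, collapse = ", "))
  if (any(diff(onsets) <= 0)) stop("stimulus onsets must be strictly increasing")
  structure(
    data.frame(onset_s = as.numeric(onsets), kind = kinds,
               stringsAsFactors = FALSE),
    stimulus_duration = stimulus_duration,
    class = c("event_log", "data.frame")
  )
}

#' Button-press response log
#'
#' @param press_times Key-press times in seconds from recording start,
#'   strictly increasing; may be empty.
#' @return An object of class `response_log`.
#' @export
response_log <- function(press_times = numeric(0)) {
  press_times <- as.numeric(press_times)
  if (length(press_times) > 1 && any(diff(press_times) <= 0)) {
    stop("press times must be strictly increasing")
  }
  structure(list(press_times = press_times), class = "response_log")
}

#' Set of stimulus-locked epochs
#'
#' The unit consumed by every analysis: a `[epochs x time x channels]`
#' array cut around stimulus onsets, with window and baseline metadata.
#'
#' @param data Numeric array `[epochs x timepoints x channels]`, microvolts.
#' @param fs Sampling rate, Hz.
#' @param window Length-2 numeric, epoch window in ms relative to onset,
#'   half-open `[start, end)`.
#' @param baseline Length-2 numeric, baseline window in ms (subset of
#'   `window`), or `NULL` when no baseline has been defined.
#' @param kind `"standard"` or `"target"`.
#' @param epoch_event_index Integer vector mapping each epoch to its row in
#'   the originating event log (presentation order).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, window, baseline = c(-200, 0),
                      kind = "standard", epoch_event_index = NULL) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == 2)
  n_t <- dim(data)[2]
  expect_n <- round((window[2] - window[1]) * fs / 1000)
  if (n_t != expect_n) {
    stop("window of ", window[1], "..", window[2], " ms at ", fs,
         " Hz implies ", expect_n, " samples, got ", n_t)
  }
  if (dim(data)[1] < 1) stop("epoch set must contain at least one epoch")
  if (!is.null(baseline)) {
    if (baseline[1] < window[1] || baseline[2] > window[2] ||
        baseline[2] <= baseline[1]) {
      stop("baseline must be a non-empty subwindow of the epoch window")
    }
  }
  if (is.null(epoch_event_index)) epoch_event_index <- seq_len(dim(data)[1])
  structure(
    list(
      data = data, fs = fs, window = as.numeric(window),
      baseline = if (is.null(baseline)) NULL else as.numeric(baseline),
      kind = kind, epoch_event_index = as.integer(epoch_event_index)
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d %s epochs, %d samples (%g..%g ms) @ %g Hz\n",
    dim(x$data)[1], x$kind, dim(x$data)[2], x$window[1], x$window[2], x$fs
  ))
  invisible(x)
}

#' Time axis of an epoch set or waveform
#'
#' @param x An `epoch_set` or `erp_waveform`.
#' @return Numeric vector of sample times in ms relative to stimulus onset.
#' @export
epoch_times <- function(x) {
  n <- if (inherits(x, "epoch_set")) dim(x$data)[2] else nrow(x$values)
  x$window[1] + (0:(n - 1)) * 1000 / x$fs
}

n_epochs <- function(ep) dim(ep$data)[1]

# [time x epochs] matrix of one channel.
chan_mat <- function(ep, ch) t(ep$data[, , ch, drop = TRUE])

# Column indices of a half-open [lo, hi) ms window on a time axis.
window_idx <- function(times, win) which(times >= win[1] & times < win[2])

#' Map a subgroup label to its main diagnostic group
#'
#' Cognitively normal (CN) and subjective cognitive decline (SCD)
#' participants form the healthy-control (HC) group; amnestic and
#' non-amnestic mild cognitive impairment (aMCI, naMCI) form the MCI group.
#'
#' @param subgroup Character vector of subgroup labels.
#' @return Character vector `"HC"`/`"MCI"`.
#' @export
main_group <- function(subgroup) {
  map <- c(CN = "HC", SCD = "HC", aMCI = "MCI", naMCI = "MCI")
  bad <- setdiff(unique(as.character(subgroup)), names(map))
  if (length(bad)) stop("unknown subgroup: ", paste(bad, collapse = ", "))
  unname(map[as.character(subgroup)])
}

#' Participant covariate record
#'
#' @param participant_id Identifier string.
#' @param age Age in years.
#' @param sex `"M"` or `"F"`.
#' @param education Education in years.
#' @param subgroup One of `"CN"`, `"SCD"`, `"aMCI"`, `"naMCI"`.
#' @return One-row data frame including the derived `main_group`.
#' @export
covariate_record <- function(participant_id, age, sex, education, subgroup) {
  stopifnot(age >= 0, education >= 0, sex %in% c("M", "F"))
  data.frame(
    participant_id = as.character(participant_id),
    age = age, sex = sex, education = education,
    subgroup = subgroup, main_group = main_group(subgroup),
    stringsAsFactors = FALSE
  )
}
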