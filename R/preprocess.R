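# Preprocessing chain: band-pass filtering, epoching, baseline correction,
# amplitude-based artifact rejection, random epoch selection, averaging.

#' Zero-phase FIR band-pass filter for a continuous recording
#'
#' Applies a Hamming-window linear-phase FIR band-pass (default 0.1-30 Hz)
#' to the continuous recording before epoching, with group-delay
#' compensation so the net delay is zero.  Channel means (DC) are removed
#' first.  The default order of `8 * fs` gives a transition band narrow
#' enough for the 0.1 Hz low edge.
#'
#' @param rec A [recording].
#' @param low,high Band edges in Hz; `0 < low < high < fs / 2`.
#' @param n_taps Odd filter length; default `8 * fs + 1`.
#' @return A filtered [recording].
#' @export
bandpass_fir <- function(rec, low = 0.1, high = 30, n_taps = NULL) {
  fs <- rec$fs
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("need 0 < low < high < fs/2")
  }
  if (is.null(n_taps)) n_taps <- 8 * round(fs) + 1
  if (n_samples(rec) < 3 * n_taps) {
    stop("recording shorter than 3x the filter length (",
         3 * n_taps, " samples needed)")
  }
  h <- fir_design(n_taps, low, high, fs)
  x <- rec$samples - rowMeans(rec$samples)
  y <- t(filter_zerophase(t(x), h))
  recording(y, fs = fs, channel_labels = rec$channel_labels,
            start_time = rec$start_time, check_range = FALSE)
}

#' Cut stimulus-locked epochs from a recording
#'
#' One epoch per event of the requested kind, over a half-open window
#' (default -200 to 800 ms, i.e. 250 samples at 250 Hz).  Events whose
#' window would fall outside the recording are dropped with a warning.
#'
#' @param rec A [recording].
#' @param events An [event_log].
#' @param kind `"standard"` or `"target"`.
#' @param window Epoch window in ms relative to onset, half-open.
#' @param baseline Baseline window metadata attached to the result.
#' @return An [epoch_set].
#' @export
make_epochs <- function(rec, events, kind = c("standard", "target"),
                        window = c(-200, 800), baseline = c(-200, 0)) {
  kind <- match.arg(kind)
  fs <- rec$fs
  sel <- which(events$kind == kind)
  if (!length(sel)) stop("no events of kind '", kind, "'")
  k_lo <- round(window[1] * fs / 1000)
  n_t <- round((window[2] - window[1]) * fs / 1000)
  i0 <- round((events$onset_s[sel] - rec$start_time) * fs)  # 0-based
  first <- i0 + k_lo
  ok <- first >= 0 & (first + n_t) <= n_samples(rec)
  if (any(!ok)) {
    warning(sum(!ok), " epoch(s) fall outside the recording and were dropped")
  }
  if (!any(ok)) stop("no epoch fits inside the recording")
  first <- first[ok]
  data <- array(0, c(length(first), n_t, 2))
  for (e in seq_along(first)) {
    idx <- (first[e] + 1):(first[e] + n_t)
    data[e, , 1] <- rec$samples[1, idx]
    data[e, , 2] <- rec$samples[2, idx]
  }
  epoch_set(data, fs, window, baseline = baseline, kind = kind,
            epoch_event_index = sel[ok])
}

#' Subtract the pre-stimulus baseline mean from every epoch
#'
#' Per epoch and channel, the mean over the baseline window (default -200
#' to 0 ms) is subtracted, so the baseline mean of the output is zero.
#'
#' @param ep An [epoch_set].
#' @param baseline Baseline window in ms, half-open, inside the epoch
#'   window.
#' @return The corrected [epoch_set] (with updated baseline metadata).
#' @export
baseline_correct <- function(ep, baseline = c(-200, 0)) {
  idx <- window_idx(epoch_times(ep), baseline)
  if (!length(idx)) stop("baseline window contains no samples")
  data <- ep$data
  for (ch in 1:2) {
    bl <- rowMeans(data[, idx, ch, drop = FALSE])
    data[, , ch] <- data[, , ch] - bl
  }
  epoch_set(data, ep$fs, ep$window, baseline = baseline, kind = ep$kind,
            epoch_event_index = ep$epoch_event_index)
}

#' Reject epochs exceeding an absolute amplitude threshold
#'
#' An automated stand-in for visual artifact screening: any epoch with a
#' sample beyond the threshold on either channel is removed.  Surviving
#' epochs are untouched.
#'
#' @param ep An [epoch_set].
#' @param threshold Absolute amplitude bound in microvolts.
#' @return List with the cleaned `epochs` and a `report` (class
#'   `preprocess_report`) with counts.
#' @export
reject_artifacts <- function(ep, threshold = 100) {
  stopifnot(threshold > 0)
  peak <- apply(abs(ep$data), 1, max)
  keep <- peak <= threshold
  if (!any(keep)) {
    stop("all epochs exceed ", threshold,
         " uV; participant excluded from analysis")
  }
  out <- epoch_set(
    ep$data[keep, , , drop = FALSE], ep$fs, ep$window,
    baseline = ep$baseline, kind = ep$kind,
    epoch_event_index = ep$epoch_event_index[keep]
  )
  report <- structure(
    list(
      n_epochs_in = n_epochs(ep),
      n_rejected_amplitude = sum(!keep),
      n_selected = sum(keep),
      rejection_threshold = threshold,
      seed = NA_integer_
    ),
    class = "preprocess_report"
  )
  list(epochs = out, report = report)
}

#' Randomly select a fixed number of epochs
#'
#' Draws `k` epochs uniformly without replacement, preserving presentation
#' order -- used to equate the number of standard epochs entering
#' variability analyses with the number of target epochs.
#'
#' @param ep An [epoch_set].
#' @param k Number of epochs to keep.
#' @param seed Integer seed; the selection is deterministic under it.
#' @return An [epoch_set] with `k` epochs.
#' @export
random_select <- function(ep, k, seed) {
  n <- n_epochs(ep)
  if (k > n) stop("cannot select ", k, " epochs from ", n)
  keep <- sort(withr::with_seed(seed, sample.int(n, k)))
  epoch_set(
    ep$data[keep, , , drop = FALSE], ep$fs, ep$window,
    baseline = ep$baseline, kind = ep$kind,
    epoch_event_index = ep$epoch_event_index[keep]
  )
}

#' Pool several epoch sets into one
#'
#' Concatenates compatible epoch sets (same window, rate and kind) along
#' the epoch axis -- used to pool trials across participants for
#' grand-average time-frequency analysis.
#'
#' @param eps List of [epoch_set] objects.
#' @return A single [epoch_set]; `epoch_event_index` is renumbered
#'   sequentially.
#' @export
combine_epochs <- function(eps) {
  stopifnot(length(eps) >= 1)
  ref <- eps[[1]]
  for (e in eps) {
    if (!identical(e$window, ref$window) || e$fs != ref$fs ||
        e$kind != ref$kind) {
      stop("epoch sets differ in window, rate or kind")
    }
  }
  n <- sum(vapply(eps, n_epochs, 0L))
  d <- array(0, c(n, dim(ref$data)[2], 2))
  at <- 0
  for (e in eps) {
    d[at + seq_len(n_epochs(e)), , ] <- e$data
    at <- at + n_epochs(e)
  }
  epoch_set(d, ref$fs, ref$window, baseline = ref$baseline,
            kind = ref$kind, epoch_event_index = seq_len(n))
}

#' Average epochs into an ERP waveform
#'
#' Pointwise mean per channel, plus the two-channel mean trace used for
#' component detection and grand averages.
#'
#' @param ep An [epoch_set].
#' @return An object of class `erp_waveform` with fields `values`
#'   `[time x 2]`, `channel_mean`, `time` (ms), `fs`, `window`, `kind`,
#'   `n_epochs`.
#' @export
average_epochs <- function(ep) {
  vals <- apply(ep$data, c(2, 3), mean)
  structure(
    list(
      values = vals, channel_mean = rowMeans(vals), time = epoch_times(ep),
      fs = ep$fs, window = ep$window, kind = ep$kind,
      n_epochs = n_epochs(ep)
    ),
    class = "erp_waveform"
  )
}
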