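# ERP component extraction (N100/P200/P300), single-trial P300 variability
# and behavioral measures.

default_component_windows <- function() {
  list(N100 = c(60, 200), P200 = c(180, 300), P300 = c(300, 600))
}

# Strict local extrema of a trace; sign +1 for maxima, -1 for minima.
local_extrema <- function(v, sign = 1) {
  v <- sign * v
  n <- length(v)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[v[i] > v[i - 1] & v[i] > v[i + 1]] + 0L
}

pick_peak <- function(values, times, win, sign, min_amp) {
  cand <- local_extrema(values, sign)
  # boundary rule: the peak must lie strictly inside the window
  cand <- cand[times[cand] > win[1] & times[cand] < win[2]]
  cand <- cand[sign * values[cand] >= min_amp]
  if (!length(cand)) {
    return(list(present = FALSE, latency = NA_real_, amplitude = NA_real_))
  }
  best <- cand[which.max(sign * values[cand])]
  ties <- cand[sign * values[cand] == sign * values[best]]
  best <- min(ties)  # earliest latency wins
  list(present = TRUE, latency = times[best], amplitude = values[best])
}

#' Detect N100, P200 and P300 components in an averaged waveform
#'
#' The N100 is the most negative strict local extremum in 60-200 ms, the
#' P200/P300 the most positive in 180-300 / 300-600 ms.  A peak must not
#' lie at a window boundary and must reach 2 microvolts in magnitude,
#' otherwise the component is marked absent (absence is a value, not an
#' error: analysis proceeds when the P300 is missing but N100 or P200 are
#' present).  Components are reported for the two-channel mean trace (the
#' participant value) and for each channel.
#'
#' @param erp An `erp_waveform` from [average_epochs()].
#' @param windows Named list of component windows in ms.
#' @param min_amp Minimum absolute peak amplitude in microvolts.
#' @return An object of class `component_set`: a list with one entry per
#'   component holding `present`, `latency`, `amplitude` for the mean
#'   trace plus `per_channel` results.
#' @export
detect_components <- function(erp, windows = default_component_windows(),
                              min_amp = 2) {
  signs <- c(N100 = -1, P200 = 1, P300 = 1)
  one_trace <- function(v) {
    out <- lapply(names(windows), function(nm) {
      pick_peak(v, erp$time, windows[[nm]], signs[[nm]], min_amp)
    })
    stats::setNames(out, names(windows))
  }
  res <- one_trace(erp$channel_mean)
  res$per_channel <- list(
    Fp1 = one_trace(erp$values[, 1]),
    Fp2 = one_trace(erp$values[, 2])
  )
  structure(res, class = "component_set")
}

#' Single-trial P300 latency and amplitude variability
#'
#' Per epoch, the two-channel mean trace is low-pass smoothed at 10 Hz
#' (zero-phase FIR) and the maximum within 300-600 ms gives that trial's
#' P300 latency and amplitude.  Sample SDs (n - 1) across trials quantify
#' latency/amplitude variability; `amp_mean` is the mean amplitude of the
#' averaged waveform over the P300 window.
#'
#' @param ep An [epoch_set] with at least two epochs.
#' @param window P300 search window in ms.
#' @param smooth_hz Low-pass cutoff for single-trial smoothing, Hz.
#' @return List with `latencies`, `amplitudes` (per epoch), `lat_std`,
#'   `amp_std`, `amp_mean`.
#' @export
single_trial_p300 <- function(ep, window = c(300, 600), smooth_hz = 10) {
  if (n_epochs(ep) < 2) stop("single-trial variability needs >= 2 epochs")
  times <- epoch_times(ep)
  idx <- window_idx(times, window)
  tr <- t((ep$data[, , 1] + ep$data[, , 2]) / 2)   # [time x epochs]
  h <- fir_design(2 * floor(0.1 * ep$fs) + 1, hi = smooth_hz, fs = ep$fs)
  sm <- filter_zerophase(tr, h)
  pk <- apply(sm[idx, , drop = FALSE], 2, which.max)
  lat <- times[idx[pk]]
  amp <- sm[idx, , drop = FALSE][cbind(pk, seq_along(pk))]
  avg <- rowMeans(tr)
  list(
    latencies = lat, amplitudes = amp,
    lat_std = stats::sd(lat), amp_std = stats::sd(amp),
    amp_mean = mean(avg[idx])
  )
}

#' Behavioral measures for one epoch kind
#'
#' A press within the response window after an onset is assigned to that
#' stimulus (first press claims the trial).  Targets: a claimed trial is
#' correct, an unclaimed one an error (miss).  Standards: a claimed trial
#' is an error (false alarm), an unclaimed one correct.  Response time
#' mean/SD are computed over correct target responses only.
#'
#' @param events An [event_log].
#' @param responses A [response_log].
#' @param kind `"standard"` or `"target"`.
#' @param resp_window Response window after onset, ms, half-open
#'   `(lo, hi]`.
#' @return List of class `behavioral_measures` with `Cor_no`, `Err_rate`
#'   (percent), and for targets `RT_mean`, `RT_std` (ms).
#' @export
behavioral_measures <- function(events, responses,
                                kind = c("standard", "target"),
                                resp_window = c(100, 1000)) {
  kind <- match.arg(kind)
  soa_ms <- min(diff(events$onset_s)) * 1000
  if (nrow(events) > 1 && soa_ms < resp_window[2] - 1e-9) {
    stop("response windows overlap: stimulus asynchrony ", soa_ms,
         " ms < window end ", resp_window[2], " ms")
  }
  onsets <- events$onset_s
  lo <- resp_window[1] / 1000
  hi <- resp_window[2] / 1000
  claimed <- rep(NA_real_, nrow(events))   # RT in ms of the claiming press
  for (p in responses$press_times) {
    i <- findInterval(p - lo, onsets)      # latest onset with onset + lo < p
    if (i >= 1 && p <= onsets[i] + hi && p > onsets[i] + lo &&
        is.na(claimed[i])) {
      claimed[i] <- (p - onsets[i]) * 1000
    }
  }
  sel <- events$kind == kind
  n <- sum(sel)
  responded <- !is.na(claimed[sel])
  if (kind == "target") {
    cor_no <- sum(responded)
    rts <- claimed[sel][responded]
    rt_mean <- if (length(rts)) mean(rts) else NA_real_
    rt_std <- if (length(rts) > 1) stats::sd(rts) else NA_real_
  } else {
    cor_no <- n - sum(responded)
    rt_mean <- NA_real_
    rt_std <- NA_real_
  }
  structure(
    list(
      Cor_no = cor_no, Err_rate = 100 * (n - cor_no) / n,
      RT_mean = rt_mean, RT_std = rt_std, n_trials = n, kind = kind
    ),
    class = "behavioral_measures"
  )
}
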