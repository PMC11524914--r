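# Time-frequency analysis: sliding-window Hann-tapered FFT per trial,
# event-related spectral perturbation (dB versus the pre-stimulus
# baseline), inter-trial coherence, permutation significance against the
# baseline, and the trial-by-time ("time-trial") map.

#' Short-time Fourier transform of every epoch
#'
#' Sliding Hann-tapered FFT (window 64 samples, hop 1 sample) of each
#' epoch and channel.  Frequency bins are `k * fs / win`; each time frame
#' is stamped with the centre of its window.
#'
#' @param ep An [epoch_set].
#' @param win Window length in samples.
#' @param crop Optional `[lo, hi]` Hz range to retain (default 0-30 Hz,
#'   the analysis band; use `NULL` to keep all bins).
#' @return Object of class `stft_epochs`: complex array
#'   `[trial x freq x time x channel]` plus `freq` (Hz), `time` (ms,
#'   frame centres), `fs`.
#' @export
stft_epochs <- function(ep, win = 64, crop = c(0, 30)) {
  n_t <- dim(ep$data)[2]
  if (win > n_t) stop("window longer than epoch (", win, " > ", n_t, ")")
  n_fr <- n_t - win + 1
  taper <- hann_window(win)
  freq <- (0:(win / 2)) * ep$fs / win
  keep_f <- seq_along(freq)
  if (!is.null(crop)) keep_f <- which(freq >= crop[1] & freq <= crop[2])
  n_ep <- n_epochs(ep)
  out <- array(0i, c(n_ep, length(keep_f), n_fr, 2))
  for (ch in 1:2) {
    x <- chan_mat(ep, ch)                       # [time x trials]
    for (fr in seq_len(n_fr)) {
      seg <- x[fr:(fr + win - 1), , drop = FALSE] * taper
      S <- stats::mvfft(seg)[keep_f, , drop = FALSE]
      out[, , fr, ch] <- t(S)
    }
  }
  times <- epoch_times(ep)
  structure(
    list(
      coefs = out, freq = freq[keep_f],
      time = (times[1:n_fr] + times[win:n_t]) / 2,
      fs = ep$fs, win = win, n_trials = n_ep, kind = ep$kind
    ),
    class = "stft_epochs"
  )
}

# Trial- and channel-averaged power [freq x time].
stft_power <- function(st) {
  apply(Mod(st$coefs)^2, c(2, 3), mean)
}

# Per-trial channel-averaged power [trial x freq x time].
stft_trial_power <- function(st) {
  (Mod(st$coefs[, , , 1])^2 + Mod(st$coefs[, , , 2])^2) / 2
}

baseline_frames <- function(st, baseline) {
  idx <- which(st$time >= baseline[1] & st$time < baseline[2])
  if (!length(idx)) stop("no time frames inside the baseline window")
  idx
}

#' Event-related spectral perturbation (ERSP)
#'
#' Trial-averaged power expressed in decibels relative to the mean
#' pre-stimulus baseline power of each frequency:
#' `10 * log10(P(f, t) / Pbase(f))`.  Positive values indicate
#' event-related synchronization (ERS), negative values event-related
#' desynchronization (ERD).
#'
#' @param st An `stft_epochs` object.
#' @param baseline Baseline window in ms (frame centres), half-open.
#' @return Object of class `tf_map` with `values` `[freq x time]` in dB,
#'   `kind = "ersp_dB"`, axes, `n_trials` and an empty significance
#'   `mask`.
#' @export
ersp <- function(st, baseline = c(-200, 0)) {
  P <- stft_power(st)
  b <- baseline_frames(st, baseline)
  base <- rowMeans(P[, b, drop = FALSE])
  if (any(base == 0)) stop("zero baseline power")
  tf_map(10 * log10(P / base), "ersp_dB", st)
}

#' Inter-trial coherence (ITC)
#'
#' Magnitude of the trial-averaged unit phasor at each time-frequency
#' point, computed per channel and averaged over the two channels; 1 means
#' perfect phase alignment across trials.
#'
#' @param st An `stft_epochs` object with at least two trials.
#' @return A `tf_map` with `values` in `[0, 1]`, `kind = "itc"`.
#' @export
itc <- function(st) {
  if (st$n_trials < 2) stop("ITC needs >= 2 trials")
  one <- function(ch) {
    z <- st$coefs[, , , ch]
    m <- Mod(z)
    m[m == 0] <- 1
    apply(z / m, c(2, 3), function(v) Mod(mean(v)))
  }
  tf_map((one(1) + one(2)) / 2, "itc", st)
}

tf_map <- function(values, kind, st, mask = NULL) {
  structure(
    list(values = values, kind = kind, freq = st$freq, time = st$time,
         mask = mask, n_trials = st$n_trials),
    class = "tf_map"
  )
}

#' Permutation significance of a TF map against its baseline
#'
#' Builds a null distribution by resampling trials with replacement and
#' drawing, for each resampled trial, a baseline time frame with
#' replacement, then recomputing the map statistic `n_perm` times.  (The
#' trial bootstrap is essential: with a one-sample hop the baseline
#' frames of a trial overlap almost completely, so resampling frames
#' alone would collapse the null variance.)  Each time-frequency point is
#' compared pointwise with the null of its frequency (two-sided for ERSP,
#' upper-sided for ITC), with the add-one permutation p-value
#' `(1 + #extreme) / (n_perm + 1)`.
#'
#' @param st An `stft_epochs` object.
#' @param type `"ersp"` or `"itc"`.
#' @param baseline Baseline window in ms.
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Pointwise significance level.
#' @param seed Integer seed; identical seeds give identical masks.
#' @return The corresponding `tf_map` with `mask` (TRUE where p < alpha)
#'   and an extra `p` matrix.
#' @export
permutation_baseline_test <- function(st, type = c("ersp", "itc"),
                                      baseline = c(-200, 0), n_perm = 200,
                                      alpha = 0.01, seed = 1) {
  type <- match.arg(type)
  if (n_perm < 100) stop("use n_perm >= 100")
  b <- baseline_frames(st, baseline)
  if (length(b) < 2) stop("baseline too short to resample")
  n_tr <- st$n_trials
  n_f <- length(st$freq)
  obs_map <- if (type == "ersp") ersp(st, baseline) else itc(st)
  null <- matrix(0, n_perm, n_f)
  draws <- withr::with_seed(seed, list(
    trial = matrix(sample.int(n_tr, 2 * n_perm * n_tr, replace = TRUE),
                   2 * n_perm, n_tr),
    frame = matrix(sample(b, 2 * n_perm * n_tr, replace = TRUE),
                   2 * n_perm, n_tr)
  ))
  if (type == "ersp") {
    Ptr <- stft_trial_power(st)                    # [trial x freq x time]
    # The observed dB map is a ratio of a post-stimulus trial mean to the
    # estimated baseline, so its null spread includes the baseline
    # estimation error: each null value is the ratio of two independent
    # bootstrap baseline draws.
    boot <- function(p) {
      sel <- vapply(seq_len(n_tr), function(i) {
        Ptr[draws$trial[p, i], , draws$frame[p, i]]
      }, numeric(n_f))                             # [freq x trial]
      rowMeans(sel)
    }
    for (p in seq_len(n_perm)) {
      null[p, ] <- 10 * log10(boot(2 * p - 1) / boot(2 * p))
    }
  } else {
    norm_ph <- function(ch) {
      z <- st$coefs[, , , ch]
      m <- Mod(z)
      m[m == 0] <- 1
      z / m
    }
    z1 <- norm_ph(1)
    z2 <- norm_ph(2)
    for (p in seq_len(n_perm)) {
      s1 <- vapply(seq_len(n_tr), function(i) {
        z1[draws$trial[p, i], , draws$frame[p, i]]
      }, complex(n_f))
      s2 <- vapply(seq_len(n_tr), function(i) {
        z2[draws$trial[p, i], , draws$frame[p, i]]
      }, complex(n_f))
      null[p, ] <- (Mod(rowMeans(s1)) + Mod(rowMeans(s2))) / 2
    }
  }
  pmat <- matrix(1, n_f, length(st$time))
  for (f in seq_len(n_f)) {
    nl <- null[, f]
    ge <- (colSums(outer(nl, obs_map$values[f, ], `>=`)) + 1) / (n_perm + 1)
    if (type == "ersp") {
      le <- (colSums(outer(nl, obs_map$values[f, ], `<=`)) + 1) / (n_perm + 1)
      pmat[f, ] <- pmin(1, 2 * pmin(ge, le))
    } else {
      pmat[f, ] <- ge
    }
  }
  obs_map$mask <- pmat < alpha
  obs_map$p <- pmat
  obs_map
}

#' Trial-by-time map of the epoch set
#'
#' Epochs in presentation order, two-channel mean trace per epoch, with a
#' boxcar moving average over `smooth` consecutive epochs along the trial
#' axis (valid convolution: `n - smooth + 1` rows).
#'
#' @param ep An [epoch_set].
#' @param smooth Moving-window length in epochs.
#' @return Object of class `trial_time_map`: `values`
#'   `[smoothed trial x time]` in microvolts, `time` (ms), `trial_first`
#'   (index of the first epoch entering each row).
#' @export
time_trial_map <- function(ep, smooth = 10) {
  n <- n_epochs(ep)
  if (n < smooth) stop("fewer epochs (", n, ") than smoothing window")
  ord <- order(ep$epoch_event_index)
  tr <- (ep$data[ord, , 1, drop = FALSE] +
           ep$data[ord, , 2, drop = FALSE])[, , 1] / 2  # [trial x time]
  if (smooth > 1) {
    cs <- apply(tr, 2, cumsum)
    v <- (cs[smooth:n, , drop = FALSE] -
            rbind(0, cs[1:(n - smooth), , drop = FALSE])) / smooth
  } else {
    v <- tr
  }
  structure(
    list(values = v, time = epoch_times(ep), smooth = smooth,
         trial_first = seq_len(n - smooth + 1), kind = ep$kind),
    class = "trial_time_map"
  )
}
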