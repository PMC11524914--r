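# Inter-channel connectivity between the two prefrontal channels:
# phase-locking value over time (Hilbert phase of band-passed epochs) and
# magnitude-squared coherence over frequency (Welch average with one
# Hann-tapered segment per epoch).

#' Canonical analysis frequency bands
#'
#' @return Named list: theta 4-8, alpha 8-13, beta 13-30 Hz.
#' @export
analysis_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Phase-locking value waveform between Fp1 and Fp2
#'
#' Both channels of every epoch are band-passed with a zero-phase FIR
#' (applied on a 200 ms mirror-padded copy, pad discarded) and their
#' instantaneous phases extracted with the Hilbert transform.  With
#' `theta(t, n)` the Fp1 - Fp2 phase difference of epoch `n` at time `t`
#' and `N` epochs, the PLV is
#' `PLV(t) = |sum_n exp(j * theta(t, n))| / N`, ranging from 0 (no
#' synchronization) to 1 (perfect synchronization).
#'
#' @param ep An [epoch_set] with at least two epochs (a single epoch gives
#'   PLV identically 1 and is rejected as meaningless).
#' @param band Length-2 numeric band in Hz, inside `(0, fs / 2)`.
#' @param n_taps Odd FIR length for the band filter (default
#'   `2 * floor(0.35 fs) + 1`).
#' @return Object of class `plv_waveform`: list with `values` (PLV per
#'   timepoint), `time` (ms), `band`, `n_epochs`.
#' @export
plv_waveform <- function(ep, band, n_taps = NULL) {
  if (n_epochs(ep) < 2) stop("PLV needs >= 2 epochs")
  if (band[2] <= band[1] || band[1] <= 0 || band[2] >= ep$fs / 2) {
    stop("degenerate band")
  }
  a1 <- band_analytic(chan_mat(ep, 1), band, ep$fs, n_taps = n_taps)
  a2 <- band_analytic(chan_mat(ep, 2), band, ep$fs, n_taps = n_taps)
  z <- a1 * Conj(a2)
  m <- Mod(z)
  m[m == 0] <- 1
  z <- z / m                       # unit phasor of the phase difference
  plv <- Mod(rowMeans(z))
  structure(
    list(values = plv, time = epoch_times(ep), band = band,
         n_epochs = n_epochs(ep), kind = ep$kind),
    class = "plv_waveform"
  )
}

#' Summary features of a PLV waveform
#'
#' Maximum PLV and its time (earliest sample on ties, searched over the
#' positive post-stimulus window), plus mean PLV within the P200, P300 and
#' positive time windows.
#'
#' @param w A `plv_waveform`.
#' @param p200_win,p300_win,pos_win Windows in ms, half-open.
#' @return Named list `PLV_max`, `PLV_time`, `PLV_P200`, `PLV_P300`,
#'   `PLV_P`.
#' @export
plv_features <- function(w, p200_win = c(180, 300), p300_win = c(300, 600),
                         pos_win = c(0, 700)) {
  win_mean <- function(win) {
    idx <- window_idx(w$time, win)
    if (!length(idx)) stop("window ", win[1], "..", win[2],
                           " ms outside the epoch")
    mean(w$values[idx])
  }
  pos_idx <- window_idx(w$time, pos_win)
  imax <- pos_idx[which.max(w$values[pos_idx])]  # which.max: earliest tie
  list(
    PLV_max = w$values[imax], PLV_time = w$time[imax],
    PLV_P200 = win_mean(p200_win), PLV_P300 = win_mean(p300_win),
    PLV_P = win_mean(pos_win)
  )
}

#' Magnitude-squared coherence spectrum between Fp1 and Fp2
#'
#' Welch's averaged periodogram with one segment per epoch: the
#' post-stimulus span of every epoch is Hann-tapered and Fourier
#' transformed; cross- and auto-spectral densities are averaged over
#' epochs and combined as `C(f) = |Wxy(f)|^2 / (Wxx(f) * Wyy(f))`, in
#' `[0, 1]`, where 0 means no linear dependence at `f`.
#'
#' @param ep An [epoch_set] with at least two epochs (a single segment
#'   yields C identically 1 and is rejected).
#' @param nfft FFT length (zero-padded; default 256, about 0.98 Hz bins at
#'   250 Hz).
#' @return Object of class `coherence_spectrum`: list with `values` per
#'   bin (NA where a channel has no power), `freq` (Hz, 0 to fs/2),
#'   `n_segments`.
#' @export
coherence_spectrum <- function(ep, nfft = 256) {
  if (n_epochs(ep) < 2) stop("coherence needs >= 2 epochs")
  times <- epoch_times(ep)
  idx <- which(times >= 0)
  if (!length(idx)) stop("epoch has no post-stimulus samples")
  nseg <- length(idx)
  if (nseg > nfft) stop("post-stimulus span exceeds nfft")
  w <- hann_window(nseg)
  x <- chan_mat(ep, 1)[idx, , drop = FALSE] * w
  y <- chan_mat(ep, 2)[idx, , drop = FALSE] * w
  pad <- matrix(0, nfft - nseg, ncol(x))
  X <- stats::mvfft(rbind(x, pad))
  Y <- stats::mvfft(rbind(y, pad))
  keep <- 1:(nfft / 2 + 1)
  X <- X[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  Wxx <- rowMeans(Mod(X)^2)
  Wyy <- rowMeans(Mod(Y)^2)
  Wxy <- rowMeans(X * Conj(Y))
  denom <- Wxx * Wyy
  C <- ifelse(denom > 0, Mod(Wxy)^2 / denom, NA_real_)
  structure(
    list(values = pmin(C, 1), freq = (keep - 1) * ep$fs / nfft,
         n_segments = n_epochs(ep), kind = ep$kind),
    class = "coherence_spectrum"
  )
}

#' Band summary features of a coherence spectrum
#'
#' Per band and over the union of all bands: maximum coherence and its
#' frequency (earliest bin on ties), mean and SD across bins.  SDs are
#' reported on a 0-100 scale (percentile of the SD of a quantity bounded
#' by 1).
#'
#' @param cs A `coherence_spectrum`.
#' @param bands Named list of `[lo, hi)` bands in Hz (default
#'   [analysis_bands()]).
#' @return Named list with, per band `<name>`: `COH_max`, `COH_freq`,
#'   `COH_mean`, `COH_std`; plus all-band `overall` entries.
#' @export
coh_features <- function(cs, bands = analysis_bands()) {
  one <- function(lo, hi) {
    idx <- which(cs$freq >= lo & cs$freq < hi)
    if (!length(idx)) stop("band ", lo, "-", hi, " Hz contains no bins")
    v <- cs$values[idx]
    imax <- idx[which.max(v)]
    list(
      COH_max = max(v), COH_freq = cs$freq[imax],
      COH_mean = mean(v), COH_std = 100 * stats::sd(v)
    )
  }
  out <- lapply(bands, function(b) one(b[1], b[2]))
  all_lo <- min(vapply(bands, `[`, 0, 1))
  all_hi <- max(vapply(bands, `[`, 0, 2))
  out$overall <- one(all_lo, all_hi)
  out
}
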