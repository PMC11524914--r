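# Internal DSP helpers shared by preprocessing, connectivity and
# time-frequency code.  All operate column-wise on [time x signal] matrices.

next_pow2 <- function(n) 2^ceiling(log2(max(1, n)))

# Linear-phase FIR design (Hamming window via signal::fir1).  n_taps must be
# odd so the group delay (n_taps - 1) / 2 is an integer number of samples.
fir_design <- function(n_taps, lo = NULL, hi = NULL, fs) {
  stopifnot(n_taps %% 2 == 1, n_taps >= 3)
  ny <- fs / 2
  h <- if (!is.null(lo) && !is.null(hi)) {
    signal::fir1(n_taps - 1, c(lo, hi) / ny, type = "pass")
  } else if (is.null(lo)) {
    signal::fir1(n_taps - 1, hi / ny, type = "low")
  } else {
    signal::fir1(n_taps - 1, lo / ny, type = "high")
  }
  as.numeric(h)
}

# Zero-phase application of a symmetric odd-length FIR: FFT overlap-free
# linear convolution, then removal of the integer group delay.
filter_zerophase <- function(x, h) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- length(h)
  L <- next_pow2(n + m - 1)
  H <- stats::fft(c(h, rep(0, L - m)))
  X <- stats::mvfft(rbind(x, matrix(0, L - n, ncol(x))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / L
  d <- (m - 1) / 2
  y[(d + 1):(d + n), , drop = FALSE]
}

# Analytic signal per column (FFT method: zero the negative frequencies).
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  X <- stats::mvfft(x)
  u <- numeric(n)
  u[1] <- 1
  if (n %% 2 == 0) {
    u[n / 2 + 1] <- 1
    if (n > 2) u[2:(n / 2)] <- 2
  } else {
    u[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(X * u, inverse = TRUE) / n
}

# Mirror padding: reflection about the half-sample before the first and
# after the last row, so a cosine at an extremum continues smoothly.
mirror_pad <- function(x, p) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(p >= 1, p <= n)
  rbind(
    x[p:1, , drop = FALSE],
    x,
    x[n:(n - p + 1), , drop = FALSE]
  )
}

# Real (zero-phase) amplitude response of a symmetric FIR sampled at the L
# DFT bin frequencies.
fir_amp_response <- function(h, L) {
  m <- length(h)
  d <- (m - 1) / 2
  H <- stats::fft(c(h, rep(0, L - m)))
  w <- 2 * pi * (seq_len(L) - 1) / L
  Re(H * exp(1i * w * d))
}

# Band-limited analytic signal per column: mirror-pad, apply the zero-phase
# amplitude response of a band-pass FIR in the frequency domain (circular
# convolution on the symmetric extension), take the analytic signal, and
# discard the pad.  Bin-centred tones pass through exactly.
band_analytic <- function(x, band, fs, pad_ms = 200, n_taps = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(n_taps)) n_taps <- 2 * floor(0.35 * fs) + 1
  p <- max(1L, round(pad_ms * fs / 1000))
  xp <- mirror_pad(x, p)
  L <- nrow(xp)
  amp <- fir_amp_response(fir_design(n_taps, band[1], band[2], fs), L)
  u <- numeric(L)
  u[1] <- 1
  if (L %% 2 == 0) {
    u[L / 2 + 1] <- 1
    u[2:(L / 2)] <- 2
  } else {
    u[2:((L + 1) / 2)] <- 2
  }
  X <- stats::mvfft(xp)
  a <- stats::mvfft(X * (amp * u), inverse = TRUE) / L
  a[(p + 1):(p + n), , drop = FALSE]
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# 1/f ("pink") noise of length n, unit variance, zero mean: spectral shaping
# of white Gaussian noise by 1/sqrt(|f|).
pink_noise <- function(n) {
  L <- next_pow2(n)
  W <- stats::fft(stats::rnorm(L))
  k <- pmin(0:(L - 1), L - (0:(L - 1)))
  k[1] <- 1
  x <- Re(stats::fft(W / sqrt(k), inverse = TRUE)) / L
  x <- x[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}

# von Mises(0, kappa) sampler, Best & Fisher (1979) rejection scheme.
rvonmises <- function(n, kappa) {
  stopifnot(kappa >= 0)
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa)) return(rep(0, n))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    m <- n - i
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k2 <- sum(ok)
    if (k2 > 0) {
      out[(i + 1):(i + k2)] <-
        sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      i <- i + k2
    }
  }
  out
}
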