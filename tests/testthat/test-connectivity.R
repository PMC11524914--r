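# Phase-locking value and coherence: analytic identities, estimator
# calibration against independent oracles, feature arithmetic.

test_that("identical channels give PLV = 1 at every sample", {
  x <- sym_tone(15) + 0.7 * sym_tone(20) + 0.5 * sym_tone(25)
  ep <- make_es1(matrix(rep(x, each = 32), 32))
  w <- plv_waveform(ep, c(13, 30))
  expect_lt(max(abs(w$values - 1)), 1e-9)
  expect_true(all(w$values >= 0 & w$values <= 1 + 1e-12))
})

test_that("uniformly spaced phase differences cancel to PLV = 0", {
  # four beta tones whose phase offsets at the probe sample (0-based 112,
  # i.e. 248 ms) are the fourth roots of unity
  x1 <- sym_tone(20)
  ch2 <- rbind(sym_tone(20), sym_tone(15), -sym_tone(20), sym_tone(25))
  ep <- make_es(matrix(rep(x1, each = 4), 4), ch2)
  w <- plv_waveform(ep, c(13, 30))
  expect_lt(w$values[113], 1e-9)
})

test_that("PLV matches the von Mises mean resultant and its closed form", {
  set.seed(21)
  kappa <- 2
  reps <- 15
  pipe <- oracle <- numeric(reps)
  x1 <- sym_tone(20)
  for (r in seq_len(reps)) {
    del <- erp2ch:::rvonmises(256, kappa)
    ch2 <- t(vapply(del, function(d) sym_tone(20, ph = -d), numeric(250)))
    ep <- make_es(matrix(rep(x1, each = 256), 256), ch2)
    pipe[r] <- plv_waveform(ep, c(13, 30))$values[113]
    # independent brute-force oracle from the sampled phases
    oracle[r] <- Mod(mean(exp(1i * del)))
  }
  expect_lt(max(abs(pipe - oracle)), 1e-4)
  expect_lt(abs(mean(pipe) - besselI(kappa, 1) / besselI(kappa, 0)), 0.03)
})

test_that("PLV is invariant to a common phase rotation of both channels", {
  set.seed(22)
  x1 <- sym_tone(20)
  ch2 <- rbind(sym_tone(15), sym_tone(25), -sym_tone(20), sym_tone(20))
  ep <- make_es(matrix(rep(x1, each = 4), 4), ch2)
  w0 <- plv_waveform(ep, c(13, 30))
  # rotate both channels by the same 60 degrees (exact for these tones)
  rot <- function(f, ph) sym_tone(f, ph = ph)
  x1r <- rot(20, pi / 3)
  ch2r <- rbind(rot(15, pi / 3), rot(25, pi / 3), -rot(20, pi / 3),
                rot(20, pi / 3))
  wr <- plv_waveform(make_es(matrix(rep(x1r, each = 4), 4), ch2r), c(13, 30))
  # rotated tones lose the exact-symmetry construction, so allow the
  # small Hilbert edge error of generic finite tones
  expect_equal(wr$values[113], w0$values[113], tolerance = 1e-3)
  # a common rotation by pi (sign flip) preserves the construction exactly
  wpi <- plv_waveform(make_es(-matrix(rep(x1, each = 4), 4), -ch2), c(13, 30))
  expect_equal(wpi$values[113], w0$values[113], tolerance = 1e-9)
})

test_that("PLV rejects degenerate inputs", {
  ep1 <- make_es1(sym_tone(20))
  expect_error(plv_waveform(ep1, c(13, 30)), ">= 2")
  ep <- make_es1(matrix(rep(sym_tone(20), each = 2), 2))
  expect_error(plv_waveform(ep, c(30, 13)), "degenerate")
})

test_that("PLV feature extraction: max, argmax tie rule, window means", {
  tax <- epoch_axis()
  w <- structure(
    list(values = rep(0.5, 250), time = tax, band = c(13, 30),
         n_epochs = 10, kind = "standard"),
    class = "plv_waveform"
  )
  f <- plv_features(w)
  expect_equal(f$PLV_max, 0.5)
  expect_equal(f$PLV_P200, 0.5)
  expect_equal(f$PLV_P300, 0.5)
  expect_equal(f$PLV_P, 0.5)
  # triangular bump peaking at 400 ms
  w$values <- pmax(0, 1 - abs(tax - 400) / 200) * 0.8
  f2 <- plv_features(w)
  expect_equal(f2$PLV_time, 400)
  # two equal maxima at 250 and 500 ms -> earliest wins
  v <- rep(0.2, 250)
  v[tax == 252] <- 0.9
  v[tax == 500] <- 0.9
  w$values <- v
  expect_equal(plv_features(w)$PLV_time, 252)
})

test_that("coherence analytic identities hold", {
  set.seed(23)
  x <- rnorm(250)
  # proportional channels -> C = 1 wherever power is nonzero
  ep <- make_es(matrix(rep(x, each = 8), 8), matrix(rep(0.5 * x, each = 8), 8))
  cs <- coherence_spectrum(ep)
  expect_lt(max(abs(cs$values - 1), na.rm = TRUE), 1e-9)
  # sign-flipped second epoch -> averaged cross-spectrum cancels -> C = 0
  y <- rnorm(250)
  ep2 <- make_es(rbind(x, x), rbind(y, -y))
  cs2 <- coherence_spectrum(ep2)
  expect_lt(max(cs2$values, na.rm = TRUE), 1e-9)
  expect_error(coherence_spectrum(make_es(x, y)), ">= 2")
})

test_that("coherence is invariant to per-channel scaling", {
  set.seed(24)
  x <- matrix(rnorm(6 * 250), 6)
  y <- 0.4 * x + matrix(rnorm(6 * 250), 6)
  a <- coherence_spectrum(make_es(x, y))$values
  b <- coherence_spectrum(make_es(3.7 * x, 0.2 * y))$values
  expect_equal(a, b, tolerance = 1e-9)
  expect_true(all(a >= 0 & a <= 1, na.rm = TRUE))
})

test_that("independent-noise coherence shows the 1/N estimator bias", {
  set.seed(25)
  reps <- 30
  N <- 64
  m <- replicate(reps, {
    d <- array(rnorm(N * 250 * 2), c(N, 250, 2))
    ep <- epoch_set(d, FS, c(-200, 800))
    mean(coherence_spectrum(ep)$values, na.rm = TRUE)
  })
  expect_lt(abs(mean(m) - 1 / N), 0.2 / N)
})

test_that("the Welch estimator matches a direct DFT on 8-sample epochs", {
  set.seed(26)
  n <- 8
  x <- matrix(rnorm(3 * n), 3)
  y <- matrix(rnorm(3 * n), 3)
  d <- array(0, c(3, n, 2))
  d[, , 1] <- x
  d[, , 2] <- y
  ep <- epoch_set(d, fs = 8, window = c(0, 1000), baseline = NULL)
  cs <- coherence_spectrum(ep, nfft = 8)
  # independent direct-DFT implementation
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  dft <- function(v) {
    vapply(0:(n / 2), function(k) {
      sum(v * exp(-2i * pi * k * (0:(n - 1)) / n))
    }, complex(1))
  }
  X <- t(apply(x * rep(w, each = 3), 1, dft))
  Y <- t(apply(y * rep(w, each = 3), 1, dft))
  Wxx <- colMeans(Mod(X)^2)
  Wyy <- colMeans(Mod(Y)^2)
  Wxy <- colMeans(X * Conj(Y))
  ref <- Mod(Wxy)^2 / (Wxx * Wyy)
  expect_equal(cs$values, ref, tolerance = 1e-9)
})

test_that("coherence band features: max, tie rule, mean and SD x 100", {
  cs <- structure(
    list(values = rep(0.6, 129), freq = (0:128) * FS / 256,
         n_segments = 10, kind = "standard"),
    class = "coherence_spectrum"
  )
  f <- coh_features(cs)
  expect_equal(f$beta$COH_mean, 0.6)
  expect_equal(f$beta$COH_std, 0)
  expect_equal(f$overall$COH_mean, 0.6)
  # rising coherence over the beta band peaks at the last beta bin
  v <- rep(0.1, 129)
  bidx <- which(cs$freq >= 13 & cs$freq < 30)
  v[bidx] <- seq(0, 1, length.out = length(bidx))
  cs$values <- v
  f2 <- coh_features(cs)
  expect_equal(f2$beta$COH_freq, max(cs$freq[bidx]))
  # hand-computed 5-bin band: mean 0.6, SD x 100 = 31.62
  vals <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  cs5 <- structure(
    list(values = vals, freq = seq(14, 18, 1), n_segments = 5,
         kind = "standard"),
    class = "coherence_spectrum"
  )
  f5 <- coh_features(cs5, bands = list(beta = c(13, 30)))
  expect_equal(f5$beta$COH_mean, 0.6)
  expect_equal(round(f5$beta$COH_std, 2), 31.62)
  expect_error(coh_features(cs5, bands = list(theta = c(4, 8))), "no bins")
})

test_that("PLV and coherence stay within [0, 1] on fuzzed epochs", {
  set.seed(27)
  for (r in 1:5) {
    n_ep <- sample(2:12, 1)
    d <- array(rnorm(n_ep * 250 * 2, sd = runif(1, 0.1, 50)),
               c(n_ep, 250, 2))
    ep <- epoch_set(d, FS, c(-200, 800))
    w <- plv_waveform(ep, c(13, 30))
    expect_true(all(w$values >= 0 & w$values <= 1 + 1e-9))
    cs <- coherence_spectrum(ep)
    expect_true(all(cs$values >= 0 & cs$values <= 1 + 1e-9, na.rm = TRUE))
  }
})
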