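# Time-frequency maps: STFT, ERSP/ITC, permutation masking, time-trial.

test_that("STFT concentrates a bin-centred tone and satisfies Parseval", {
  # 15.625 Hz is bin k = 4 of a 64-point window at 250 Hz
  x <- cos(2 * pi * 15.625 * (0:249) / FS)
  ep <- make_es1(matrix(rep(x, each = 2), 2))
  st <- stft_epochs(ep, crop = NULL)
  expect_equal(st$freq[2] - st$freq[1], 3.90625)
  P <- erp2ch:::stft_power(st)
  k <- which.min(abs(st$freq - 15.625))
  mid <- ncol(P) %/% 2
  others <- setdiff(seq_along(st$freq), (k - 1):(k + 1))
  expect_gt(10 * log10(P[k, mid] / max(P[others, mid])), 20)
  # Parseval: one-sided power sum equals windowed energy
  w <- erp2ch:::hann_window(64)
  seg <- x[101:164] * w
  X <- fft(seg)
  expect_equal(sum(Mod(X)^2) / 64, sum(seg^2), tolerance = 1e-10)
  one_sided <- (P[1, 101] + P[33, 101] +
                  2 * sum(P[2:32, 101])) / 64
  expect_equal(one_sided, sum(seg^2), tolerance = 1e-6 * sum(seg^2))
  # zero signal -> zero power
  st0 <- stft_epochs(make_es1(matrix(0, 2, 250)))
  expect_equal(max(Mod(st0$coefs)), 0)
  short <- make_es1(matrix(0, 2, 50), window = c(-100, 100),
                    baseline = c(-100, 0))
  expect_error(stft_epochs(short, win = 64), "longer")
})

test_that("ERSP is ~0 dB for stationary noise and +/-3.01 dB for power steps", {
  set.seed(31)
  nn <- 400
  tax <- -800 + (0:(nn - 1)) * 4
  h <- erp2ch:::fir_design(175, 13, 30, FS)
  mk <- function(gain) {
    d <- array(0, c(80, nn, 2))
    for (e in 1:80) for (ch in 1:2) {
      x <- erp2ch:::filter_zerophase(rnorm(nn + 200), h)[101:(100 + nn), 1]
      x[tax >= 0] <- x[tax >= 0] * sqrt(gain)
      d[e, , ch] <- x
    }
    epoch_set(d, FS, c(-800, 800), baseline = c(-800, -200))
  }
  # stationary: gain 1
  m1 <- ersp(stft_epochs(mk(1)), baseline = c(-800, -200))
  expect_lt(abs(mean(m1$values)), 0.5)
  sel <- function(m) {
    mean(m$values[m$freq >= 13 & m$freq <= 30, m$time >= 150 & m$time <= 600])
  }
  m2 <- ersp(stft_epochs(mk(2)), baseline = c(-800, -200))
  expect_lt(abs(sel(m2) - 10 * log10(2)), 0.4)
  mh <- ersp(stft_epochs(mk(0.5)), baseline = c(-800, -200))
  expect_lt(abs(sel(mh) + 10 * log10(2)), 0.4)
})

test_that("ITC is 1 for identical trials, ~Rayleigh level for random phases", {
  x <- cos(2 * pi * 10 * (0:249) / FS) + cos(2 * pi * 20 * (0:249) / FS)
  ep <- make_es1(matrix(rep(x, each = 8), 8))
  m <- itc(stft_epochs(ep))
  expect_lt(max(abs(m$values - 1)), 1e-9)
  set.seed(32)
  vals <- replicate(6, {
    d <- array(rnorm(64 * 250 * 2), c(64, 250, 2))
    mean(itc(stft_epochs(epoch_set(d, FS, c(-200, 800))))$values)
  })
  expect_lt(abs(mean(vals) - sqrt(pi) / 2 / sqrt(64)), 0.015)
  # amplitude scaling of single trials leaves ITC unchanged
  d <- array(rnorm(8 * 250 * 2), c(8, 250, 2))
  a <- itc(stft_epochs(epoch_set(d, FS, c(-200, 800))))$values
  d2 <- d * rep(runif(8, 0.1, 10), 250 * 2)
  b <- itc(stft_epochs(epoch_set(d2, FS, c(-200, 800))))$values
  expect_equal(a, b, tolerance = 1e-9)
  expect_true(all(b <= 1 + 1e-12))
})

test_that("permutation mask is seeded, calibrated and detects real effects", {
  set.seed(33)
  # stationary noise: masked fraction near the nominal 1 percent
  d <- array(rnorm(40 * 250 * 2), c(40, 250, 2))
  ep <- epoch_set(d, FS, c(-200, 800))
  st <- stft_epochs(ep)
  m <- permutation_baseline_test(st, "ersp", n_perm = 200, seed = 4)
  expect_lt(mean(m$mask), 0.03)
  m2 <- permutation_baseline_test(st, "ersp", n_perm = 200, seed = 4)
  expect_identical(m$mask, m2$mask)
  # injected +6 dB post-stimulus band must be flagged
  h <- erp2ch:::fir_design(175, 13, 30, FS)
  tax <- epoch_axis()
  d3 <- array(0, c(40, 250, 2))
  for (e in 1:40) for (ch in 1:2) {
    x <- rnorm(250)
    add <- erp2ch:::filter_zerophase(rnorm(250), h)[, 1] * 2
    add[tax < 200 | tax > 600] <- 0
    d3[e, , ch] <- x + add
  }
  st3 <- stft_epochs(epoch_set(d3, FS, c(-200, 800)))
  m3 <- permutation_baseline_test(st3, "ersp", n_perm = 200, seed = 5)
  reg <- m3$freq >= 13 & m3$freq <= 30
  regt <- m3$time >= 300 & m3$time <= 500
  expect_gt(mean(m3$mask[reg, regt]), 0.5)
  expect_error(permutation_baseline_test(st, "ersp", n_perm = 50), "100")
})

test_that("time-trial map smooths along trials and shows habituation", {
  tax <- epoch_axis()
  tpl <- gauss_bump(tax, 4, 250, 40)
  same <- make_es1(matrix(rep(tpl, each = 20), 20))
  m <- time_trial_map(same, smooth = 10)
  expect_equal(nrow(m$values), 11)
  expect_lt(max(apply(m$values, 2, function(v) diff(range(v)))), 1e-12)
  # smooth = 1 is the identity
  m1 <- time_trial_map(same, smooth = 1)
  expect_equal(m1$values[1, ], tpl, tolerance = 1e-12)
  # 1 percent-per-trial P200 decay -> monotone decline of row maxima
  set.seed(34)
  n <- 60
  x <- t(vapply(seq_len(n), function(i) {
    0.99^(i - 1) * tpl + rnorm(250, sd = 0.3)
  }, numeric(250)))
  md <- time_trial_map(make_es1(x), smooth = 10)
  peaks <- apply(md$values[, tax >= 200 & tax < 300], 1, max)
  rho <- cor(seq_along(peaks), peaks, method = "spearman")
  expect_lt(rho, -0.9)
  expect_error(time_trial_map(make_es1(x[1:5, ]), smooth = 10), "fewer")
})
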