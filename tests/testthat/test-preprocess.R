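# Preprocessing chain: filtering, epoching, baseline, rejection,
# selection, averaging.

test_that("band-pass passes 10 Hz within 1 dB and kills 50 Hz and DC", {
  n <- 30 * FS
  tt <- (0:(n - 1)) / FS
  rms <- function(x) sqrt(mean(x^2))
  mid <- (5 * FS):(25 * FS)      # avoid filter edges
  r10 <- recording(rbind(sin(2 * pi * 10 * tt), sin(2 * pi * 10 * tt)), FS)
  y10 <- bandpass_fir(r10)$samples[1, mid]
  expect_lt(abs(20 * log10(rms(y10) / rms(r10$samples[1, mid]))), 1)
  r50 <- recording(rbind(sin(2 * pi * 50 * tt), sin(2 * pi * 50 * tt)), FS)
  y50 <- bandpass_fir(r50)$samples[1, mid]
  expect_lt(20 * log10(rms(y50) / rms(r50$samples[1, mid])), -40)
  rdc <- recording(matrix(5, 2, n), FS)
  expect_lt(max(abs(bandpass_fir(rdc)$samples)), 1e-6)
  expect_error(bandpass_fir(recording(matrix(0, 2, 100), FS)), "shorter")
  expect_error(bandpass_fir(r10, low = 0, high = 30), "0 < low")
})

test_that("epoching yields one 250-sample epoch per event of the kind", {
  spec <- session_spec()
  sch <- generate_schedule(spec, 1)
  rec <- recording(matrix(rnorm(2 * 321 * FS), 2), FS)
  ep <- make_epochs(rec, sch, "standard")
  expect_equal(n_epochs(ep), 256)
  expect_equal(dim(ep$data)[2], 250)
  expect_equal(epoch_times(ep)[1], -200)
  expect_equal(max(epoch_times(ep)), 796)   # half-open [-200, 800)
  ept <- make_epochs(rec, sch, "target")
  expect_equal(n_epochs(ept), 64)
})

test_that("epochs that do not fit inside the recording are dropped", {
  rec <- recording(matrix(rnorm(2 * 3 * FS), 2), FS)
  ev <- event_log(c(0.1, 1.5), c("standard", "standard"))
  expect_warning(ep <- make_epochs(rec, ev, "standard"), "dropped")
  expect_equal(n_epochs(ep), 1)
  expect_equal(ep$epoch_event_index, 2L)
})

test_that("baseline correction zeroes the baseline mean and is idempotent", {
  set.seed(1)
  ep <- make_es1(matrix(rnorm(20 * 250, mean = 3), 20))
  bc <- baseline_correct(ep)
  idx <- which(epoch_times(bc) >= -200 & epoch_times(bc) < 0)
  for (ch in 1:2) {
    expect_lt(max(abs(rowMeans(bc$data[, idx, ch]))), 1e-9)
  }
  bc2 <- baseline_correct(bc)
  expect_equal(bc2$data, bc$data, tolerance = 1e-12)
  # constant epochs become exactly zero
  cst <- baseline_correct(make_es1(rep(5, 250)))
  expect_equal(max(abs(cst$data)), 0)
  # a linear ramp keeps its shape, shifted so the baseline mean is zero
  tax <- epoch_axis()
  ramp <- 0.01 * (tax + 100)          # crosses zero at -100 ms
  rc <- baseline_correct(make_es1(ramp))
  shift <- mean(ramp[tax >= -200 & tax < 0])
  expect_equal(rc$data[1, , 1], ramp - shift, tolerance = 1e-12)
})

test_that("artifact rejection removes spiked epochs and nothing else", {
  set.seed(2)
  x <- matrix(rnorm(10 * 250, sd = 10), 10)
  x[3, 100] <- 150
  ep <- make_es1(x)
  r <- reject_artifacts(ep, 100)
  expect_equal(n_epochs(r$epochs), 9)
  expect_false(3L %in% r$epochs$epoch_event_index)
  expect_equal(r$report$n_rejected_amplitude, 1)
  expect_equal(r$report$n_epochs_in, 10)
  # surviving samples unaltered
  expect_equal(r$epochs$data[1, , 1], x[1, ], tolerance = 0)
  clean <- reject_artifacts(make_es1(x[-3, , drop = FALSE]), 100)
  expect_equal(clean$report$n_rejected_amplitude, 0)
  allbad <- make_es1(matrix(200, 4, 250))
  expect_error(reject_artifacts(allbad, 100), "excluded")
})

test_that("random selection is deterministic and order-preserving", {
  set.seed(3)
  ep <- make_es1(matrix(rnorm(256 * 250), 256))
  s1 <- random_select(ep, 64, seed = 9)
  s2 <- random_select(ep, 64, seed = 9)
  expect_equal(n_epochs(s1), 64)
  expect_identical(s1$epoch_event_index, s2$epoch_event_index)
  expect_false(is.unsorted(s1$epoch_event_index))
  idn <- random_select(ep, 256, seed = 9)
  expect_equal(idn$data, ep$data)
  expect_error(random_select(ep, 300, seed = 1), "cannot select")
})

test_that("averaging is the pointwise mean and noise shrinks as 1/sqrt(N)", {
  one <- make_es1(sym_tone(10))
  expect_equal(average_epochs(one)$channel_mean, sym_tone(10),
               tolerance = 1e-12)
  two <- make_es1(rbind(rep(2, 250), rep(-2, 250)))
  expect_equal(max(abs(average_epochs(two)$channel_mean)), 0)
  # residual RMS of an averaged template ~ sigma / sqrt(N)
  set.seed(4)
  template <- gauss_bump(epoch_axis(), 5, 300, 60)
  sigma <- 8
  N <- 64
  resid <- replicate(20, {
    x <- matrix(rep(template, each = N), N) + matrix(rnorm(N * 250, sd = sigma), N)
    avg <- average_epochs(make_es1(x))$channel_mean
    sqrt(mean((avg - template)^2))
  })
  expect_equal(mean(resid), sigma / sqrt(N), tolerance = 0.15)
})

test_that("filtering and epoch averaging are invariant to epoch order", {
  set.seed(5)
  x <- matrix(rnorm(12 * 250), 12)
  perm <- sample(12)
  a <- average_epochs(make_es1(x))$channel_mean
  b <- average_epochs(make_es1(x[perm, ]))$channel_mean
  expect_equal(a, b, tolerance = 1e-12)
})
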