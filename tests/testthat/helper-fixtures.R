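# Shared fixtures: all built in code at test time.

FS <- 250

# Sampled cosine symmetric about the half-sample before/after the epoch
# ends: cos(2*pi*f*(k + 0.5)/fs - ph).  For f a multiple of fs/(2 n) the
# mirror-padded extension continues the tone exactly, so band filtering
# and the Hilbert transform are exact for it.
sym_tone <- function(f, n = 250, fs = FS, ph = 0) {
  cos(pi * (2 * f / fs) * ((0:(n - 1)) + 0.5) - ph)
}

# Assemble an epoch_set from two lists/matrices of per-epoch channel
# traces ([epochs x time] or a single vector recycled).
make_es <- function(x1, x2, fs = FS, window = c(-200, 800),
                    baseline = c(-200, 0), kind = "standard") {
  x1 <- if (is.matrix(x1)) x1 else matrix(x1, 1)
  x2 <- if (is.matrix(x2)) x2 else matrix(x2, 1)
  stopifnot(nrow(x1) == nrow(x2))
  d <- array(0, c(nrow(x1), ncol(x1), 2))
  d[, , 1] <- x1
  d[, , 2] <- x2
  epoch_set(d, fs, window, baseline = baseline, kind = kind)
}

# Epoch set where both channels carry identical per-epoch traces.
make_es1 <- function(x, ...) make_es(x, x, ...)

# Gaussian bump in ms units on an epoch time axis.
gauss_bump <- function(times, amp, lat, sd_ms) {
  amp * exp(-(times - lat)^2 / (2 * sd_ms^2))
}

epoch_axis <- function(n = 250, window = c(-200, 800), fs = FS) {
  window[1] + (0:(n - 1)) * 1000 / fs
}

# Small deterministic session for fast end-to-end tests.
quick_session <- function() session_spec()

quick_profile <- function() default_group_profiles()$CN
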