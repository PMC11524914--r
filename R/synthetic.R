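# Synthetic oddball-session generator.  Emulates the statistical structure
# the analysis assumes -- evoked N100/P200/P300 components with
# controllable latency jitter, a shared beta-band oscillation with von
# Mises inter-channel phase coupling, 1/f background noise partially common
# to the two channels, post-stimulus beta desynchronization, P200
# habituation over standard trials, the portable device's acquisition
# filters, and button-press behavior -- so that every pipeline stage can be
# validated against known ground truth.

#' Oddball session specification
#'
#' Defaults reproduce the recorded paradigm: 256 frequent standard tones
#' and 64 rare target tones (4:1) at a 1000 ms onset-to-onset asynchrony,
#' 50 ms tone duration, 250 Hz sampling and a 1 s lead-in, i.e. a session
#' of 5 min 21 s.
#'
#' @param n_standard,n_target Stimulus counts.
#' @param soa Stimulus onset asynchrony in ms.
#' @param stim_duration Tone duration in ms.
#' @param fs Sampling rate in Hz.
#' @param lead_in Pre-task recording in ms.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(n_standard = 256, n_target = 64, soa = 1000,
                         stim_duration = 50, fs = 250, lead_in = 1000) {
  stopifnot(n_standard >= 0, n_target >= 1, soa >= stim_duration, fs > 0)
  structure(
    list(
      n_standard = as.integer(n_standard), n_target = as.integer(n_target),
      soa = soa, stim_duration = stim_duration, fs = fs, lead_in = lead_in
    ),
    class = "session_spec"
  )
}

evoked_component <- function(amp, lat, jitter) {
  c(amp = amp, lat = lat, jitter = jitter)
}

#' Group effect profile for the generator
#'
#' Bundles every group-dependent generator parameter: evoked component
#' amplitude/latency/jitter per stimulus kind, inter-channel beta phase
#' coupling, beta event-related desynchronization, background noise,
#' habituation and behavior.
#'
#' @param components Nested list `components$standard$N100 = c(amp, lat,
#'   jitter)` etc., amplitudes in microvolts, latencies and jitter SDs in
#'   ms.  See [default_group_profiles()] for the expected shape.
#' @param beta_coupling_kappa von Mises concentration of the Fp1-Fp2 phase
#'   difference of the shared beta-band (13-30 Hz) activity; larger means
#'   tighter coupling.
#' @param beta_erd_gain Multiplicative post-stimulus beta power factor over
#'   300-500 ms; values below 1 produce event-related desynchronization.
#' @param noise_scale RMS of the 1/f background per channel, microvolts.
#' @param noise_coupling Fraction of background power common to the two
#'   channels (sets the broadband coherence ceiling).
#' @param beta_amp RMS of the shared beta oscillation, microvolts.
#' @param rt_mean,rt_sd Response time mean and SD in ms (truncated to the
#'   interval (100, soa)).
#' @param miss_rate,false_alarm_rate Probability of missing a target / of
#'   pressing after a standard.
#' @param p200_habituation Per-trial multiplicative decay of the
#'   standard-epoch P200 amplitude.
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(components,
                          beta_coupling_kappa = 6,
                          beta_erd_gain = 0.55,
                          noise_scale = 6,
                          noise_coupling = 0.85,
                          beta_amp = 4,
                          rt_mean = 340, rt_sd = 75,
                          miss_rate = 0.02, false_alarm_rate = 0.003,
                          p200_habituation = 0.9975) {
  stopifnot(
    beta_coupling_kappa >= 0, beta_erd_gain > 0,
    noise_scale >= 0, noise_coupling >= 0, noise_coupling <= 1,
    miss_rate >= 0, miss_rate <= 1,
    false_alarm_rate >= 0, false_alarm_rate <= 1,
    p200_habituation > 0, p200_habituation <= 1
  )
  for (k in c("standard", "target")) {
    stopifnot(all(c("N100", "P200", "P300") %in% names(components[[k]])))
    for (cmp in components[[k]]) stopifnot(cmp[["jitter"]] >= 0)
  }
  structure(
    list(
      components = components,
      beta_coupling_kappa = beta_coupling_kappa,
      beta_erd_gain = beta_erd_gain,
      noise_scale = noise_scale,
      noise_coupling = noise_coupling,
      beta_amp = beta_amp,
      rt_mean = rt_mean, rt_sd = rt_sd,
      miss_rate = miss_rate, false_alarm_rate = false_alarm_rate,
      p200_habituation = p200_habituation
    ),
    class = "group_profile"
  )
}

base_components <- function(p300_target_jitter) {
  list(
    standard = list(
      N100 = evoked_component(-4.0, 145, 12),
      P200 = evoked_component(3.5, 245, 18),
      P300 = evoked_component(1.2, 430, 70)
    ),
    target = list(
      N100 = evoked_component(-4.5, 145, 15),
      P200 = evoked_component(6.0, 250, 18),
      P300 = evoked_component(7.0, 430, p300_target_jitter)
    )
  )
}

#' Default synthetic group profiles
#'
#' One profile per diagnostic subgroup encoding, qualitatively, the group
#' structure the analysis is designed to resolve: beta coupling ordered
#' CN > SCD > naMCI > aMCI; higher target-P300 latency jitter and response
#' time variability in the MCI subgroups; post-stimulus beta
#' desynchronization present in the HC subgroups and absent (gain 1) in
#' the MCI subgroups; identical N100/P200 parameters everywhere.  The
#' numerical values are synthetic choices, not estimates from any cohort.
#'
#' @return Named list of [group_profile] objects
#'   (`CN`, `SCD`, `aMCI`, `naMCI`).
#' @export
default_group_profiles <- function() {
  list(
    CN = group_profile(
      base_components(40), beta_coupling_kappa = 8, beta_erd_gain = 0.55,
      rt_mean = 335, rt_sd = 65, miss_rate = 0.015,
      false_alarm_rate = 0.002, p200_habituation = 0.9975
    ),
    SCD = group_profile(
      base_components(43), beta_coupling_kappa = 6, beta_erd_gain = 0.55,
      rt_mean = 340, rt_sd = 75, miss_rate = 0.02,
      false_alarm_rate = 0.003, p200_habituation = 0.9975
    ),
    aMCI = group_profile(
      base_components(55), beta_coupling_kappa = 2, beta_erd_gain = 1,
      rt_mean = 345, rt_sd = 95, miss_rate = 0.04,
      false_alarm_rate = 0.006, p200_habituation = 0.996
    ),
    naMCI = group_profile(
      base_components(50), beta_coupling_kappa = 3, beta_erd_gain = 1,
      rt_mean = 350, rt_sd = 105, miss_rate = 0.05,
      false_alarm_rate = 0.008, p200_habituation = 0.996
    )
  )
}

#' Generate a stimulus schedule
#'
#' Onsets are `lead_in + i * soa`; target positions are drawn uniformly
#' among arrangements with at least one standard between consecutive
#' targets (preventing target runs that would confound habituation
#' analyses).
#'
#' @param spec A [session_spec].
#' @param seed Integer seed; identical seeds give identical schedules.
#' @return An [event_log].
#' @export
generate_schedule <- function(spec, seed) {
  n <- spec$n_standard + spec$n_target
  if (spec$n_target > ceiling(n / 2)) {
    stop("cannot place ", spec$n_target, " non-adjacent targets in ",
         n, " positions")
  }
  pos <- withr::with_seed(seed, {
    # classic gap construction: choose k from n - k + 1, then spread
    sort(sample.int(n - spec$n_target + 1, spec$n_target)) +
      0:(spec$n_target - 1)
  })
  kinds <- rep("standard", n)
  kinds[pos] <- "target"
  onsets <- (spec$lead_in + (0:(n - 1)) * spec$soa) / 1000
  event_log(onsets, kinds, stimulus_duration = spec$stim_duration)
}

# Piecewise-constant per-epoch value expanded to a full-length sample
# vector, with a short linear cross-fade after each boundary (applied on
# the unit circle for phases).
segment_phasor <- function(delta, onset_idx, n, fs, ramp_ms = 80) {
  z <- complex(argument = delta)
  seg <- findInterval(seq_len(n) - 1, onset_idx)  # 0 = lead-in
  zt <- z[seg + 1]
  r <- max(1L, round(ramp_ms * fs / 1000))
  w <- rep(1 / (2 * r + 1), 2 * r + 1)
  sm_re <- as.numeric(stats::filter(Re(zt), w, sides = 2))
  sm_im <- as.numeric(stats::filter(Im(zt), w, sides = 2))
  na <- is.na(sm_re)
  sm_re[na] <- Re(zt)[na]
  sm_im[na] <- Im(zt)[na]
  zt <- complex(real = sm_re, imaginary = sm_im)
  m <- Mod(zt)
  zt[m > 0] <- zt[m > 0] / m[m > 0]
  zt[m == 0] <- 1 + 0i
  zt
}

#' Synthesize a two-channel oddball recording
#'
#' Builds `Fp1`/`Fp2` as 1/f background noise (a `noise_coupling` fraction
#' of its power shared between channels) plus a shared beta-band
#' oscillation, per-event evoked components and post-stimulus beta gain.
#' Within each inter-stimulus segment the beta-band content of channel 2 is
#' phase-rotated against channel 1 by a von Mises(0, kappa) draw, so
#' `beta_coupling_kappa` directly controls beta-band PLV and coherence
#' while theta/alpha coupling is group-independent.  The ongoing activity
#' is passed through the emulated acquisition filters of the portable
#' device (55-65 Hz 2nd-order band-stop, 2.6 Hz 1st-order high-pass, 43 Hz
#' 8th-order low-pass Butterworth); the evoked templates are then added,
#' i.e. the profile's component amplitudes and latencies describe the
#' deflections as they appear in the recorded signal.
#'
#' @param schedule An [event_log] from [generate_schedule()].
#' @param profile A [group_profile].
#' @param spec The [session_spec] used for the schedule.
#' @param seed Integer seed.
#' @param device_filters Apply the emulated device filters (default); the
#'   raw construction is available for closed-form validation.
#' @return A [recording].
#' @export
synthesize_recording <- function(schedule, profile, spec, seed,
                                 device_filters = TRUE) {
  fs <- spec$fs
  n_ev <- nrow(schedule)
  total_ms <- spec$lead_in + n_ev * spec$soa
  n <- round(total_ms * fs / 1000)
  onset_idx <- round(schedule$onset_s * fs)  # 0-based sample of each onset
  if (max(onset_idx) + 0.8 * fs > n) stop("schedule exceeds recording length")
  withr::with_seed(seed, {
    common <- pink_noise(n)
    ind1 <- pink_noise(n)
    ind2 <- pink_noise(n)
    # Shared/decoupled oscillatory band: middle and high beta (16-30 Hz),
    # split with a sharp FIR so the group-dependent decoupling cannot
    # leak into the measured alpha band.
    h_beta <- fir_design(2 * floor(1 * fs) + 1, 16, 30, fs)
    cb <- filter_zerophase(common, h_beta)[, 1]
    rest <- common - cb
    acb <- analytic_signal(cb)[, 1]
    osc <- filter_zerophase(stats::rnorm(n), h_beta)[, 1]
    osc <- osc / stats::sd(osc) * profile$beta_amp
    aosc <- analytic_signal(osc)[, 1]
    # inter-channel beta phase offset, one draw per inter-stimulus segment
    delta <- rvonmises(n_ev + 1, profile$beta_coupling_kappa)
    rot <- segment_phasor(delta, onset_idx, n, fs)
    # post-stimulus beta power gain over 300-500 ms (amplitude sqrt(gain))
    g <- rep(1, n)
    if (profile$beta_erd_gain != 1) {
      ga <- sqrt(profile$beta_erd_gain)
      for (i in onset_idx) {
        lo <- i + round(0.300 * fs) + 1
        hi <- min(n, i + round(0.500 * fs))
        if (lo <= hi) g[lo:hi] <- ga
      }
      g <- stats::filter(g, rep(1 / 11, 11), sides = 2)
      g[is.na(g)] <- 1
      g <- as.numeric(g)
    }
    # evoked components, identical on both channels
    ev <- numeric(n)
    # P300 width 50 ms: wide enough to fill its detection window under
    # jitter, narrow enough that the jitter-smeared average does not
    # bleed into the P200 window.
    sigma_ms <- c(N100 = 25, P200 = 35, P300 = 50)
    std_count <- 0
    for (i in seq_len(n_ev)) {
      kind <- schedule$kind[i]
      if (kind == "standard") std_count <- std_count + 1
      comps <- profile$components[[kind]]
      for (nm in names(comps)) {
        cmp <- comps[[nm]]
        amp <- cmp[["amp"]]
        if (nm == "P200" && kind == "standard") {
          amp <- amp * profile$p200_habituation^(std_count - 1)
        }
        lat <- cmp[["lat"]] + stats::rnorm(1, 0, cmp[["jitter"]])
        sd_smp <- sigma_ms[[nm]] * fs / 1000
        ctr <- onset_idx[i] + lat * fs / 1000
        k <- max(0, floor(ctr - 4 * sd_smp)):min(n - 1, ceiling(ctr + 4 * sd_smp))
        ev[k + 1] <- ev[k + 1] + amp * exp(-(k - ctr)^2 / (2 * sd_smp^2))
      }
    }
    w_c <- sqrt(profile$noise_coupling)
    w_i <- sqrt(1 - profile$noise_coupling)
    ns <- profile$noise_scale
    ch1 <- ns * (w_c * (rest + g * cb) + w_i * ind1) + g * osc
    ch2 <- ns * (w_c * (rest + g * Re(acb * rot)) + w_i * ind2) +
      g * Re(aosc * rot)
    x <- rbind(ch1, ch2)
    # The device chain shapes the ongoing activity; the evoked templates
    # describe the deflections as they appear in the recorded signal (a
    # 1st-order 2.6 Hz high-pass would otherwise remove most of a 60 ms
    # wide P300, making the profile amplitudes uninterpretable).
    if (device_filters) x <- apply_device_filters(x, fs)
    x <- x + rbind(ev, ev)
    if (max(abs(x)) > DEVICE_RANGE_UV) {
      stop("profile produces clipping beyond the +/-", DEVICE_RANGE_UV,
           " uV input range")
    }
    recording(x, fs = fs)
  })
}

# Emulation of the acquisition device's digital IIR chain: 2nd-order
# 55-65 Hz band-stop, 1st-order 2.6 Hz high-pass, 8th-order 43 Hz low-pass
# Butterworth filters, applied causally as in the device.
apply_device_filters <- function(x, fs) {
  ny <- fs / 2
  bs <- signal::butter(2, c(55, 65) / ny, type = "stop")
  hp <- signal::butter(1, 2.6 / ny, type = "high")
  lp <- signal::butter(8, 43 / ny, type = "low")
  t(apply(x, 1, function(ch) {
    ch <- signal::filter(bs, ch)
    ch <- signal::filter(hp, ch)
    as.numeric(signal::filter(lp, ch))
  }))
}

#' Simulate button-press behavior for a schedule
#'
#' Each target elicits, with probability `1 - miss_rate`, a press at onset
#' plus a response time drawn from Normal(`rt_mean`, `rt_sd`) truncated to
#' (100, soa) ms; each standard elicits a false-alarm press with
#' probability `false_alarm_rate`.
#'
#' @param schedule An [event_log].
#' @param profile A [group_profile].
#' @param spec The [session_spec] (for the truncation bound).
#' @param seed Integer seed.
#' @return A [response_log].
#' @export
simulate_behavior <- function(schedule, profile, spec, seed) {
  if (profile$rt_mean <= 100 || profile$rt_mean >= spec$soa) {
    stop("rt_mean must lie inside (100, ", spec$soa, ") ms")
  }
  withr::with_seed(seed, {
    rtrunc <- function(m) {
      out <- numeric(m)
      left <- seq_len(m)
      while (length(left)) {
        r <- stats::rnorm(length(left), profile$rt_mean, profile$rt_sd)
        ok <- r > 100 & r < spec$soa
        out[left[ok]] <- r[ok]
        left <- left[!ok]
      }
      out
    }
    press <- numeric(0)
    tgt <- schedule$onset_s[schedule$kind == "target"]
    hit <- stats::runif(length(tgt)) >= profile$miss_rate
    if (any(hit)) press <- c(press, tgt[hit] + rtrunc(sum(hit)) / 1000)
    std <- schedule$onset_s[schedule$kind == "standard"]
    fa <- stats::runif(length(std)) < profile$false_alarm_rate
    if (any(fa)) press <- c(press, std[fa] + rtrunc(sum(fa)) / 1000)
    response_log(sort(press))
  })
}

#' Cohort specification
#'
#' @param n_per_subgroup Named integer vector (`CN`, `SCD`, `aMCI`,
#'   `naMCI`) or a single count applied to all four subgroups.
#' @param profiles Named list of [group_profile] objects, one per subgroup.
#' @param session A [session_spec].
#' @param seed Master seed; per-participant seeds are derived
#'   deterministically from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_subgroup, profiles = default_group_profiles(),
                        session = session_spec(), seed = 1) {
  subgroups <- c("CN", "SCD", "aMCI", "naMCI")
  if (length(n_per_subgroup) == 1 && is.null(names(n_per_subgroup))) {
    n_per_subgroup <- stats::setNames(rep(n_per_subgroup, 4), subgroups)
  }
  stopifnot(all(subgroups %in% names(n_per_subgroup)),
            all(subgroups %in% names(profiles)))
  structure(
    list(
      n_per_subgroup = n_per_subgroup[subgroups], profiles = profiles,
      session = session, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Plausible covariate distributions per subgroup (ages/education in years;
# male fraction).  Purely synthetic population settings.
covariate_settings <- function() {
  list(
    CN = list(age = c(72.3, 6.2), male = 0.57, edu = c(11.8, 4.6)),
    SCD = list(age = c(71.3, 6.2), male = 0.45, edu = c(12.1, 4.5)),
    aMCI = list(age = c(74.3, 6.8), male = 0.65, edu = c(12.2, 4.7)),
    naMCI = list(age = c(73.1, 6.4), male = 0.52, edu = c(12.7, 4.7))
  )
}

# One participant: covariates plus a recording/event/response triple.
# Age mildly shifts response time and target P300 latency so that
# covariate adjustment has something real to adjust for.
synth_participant <- function(id, subgroup, profiles, session, seed) {
  cs <- covariate_settings()[[subgroup]]
  prof <- profiles[[subgroup]]
  withr::with_seed(seed, {
    age <- max(54, min(90, stats::rnorm(1, cs$age[1], cs$age[2])))
    sex <- if (stats::runif(1) < cs$male) "M" else "F"
    edu <- max(0, stats::rnorm(1, cs$edu[1], cs$edu[2]))
    seeds <- sample.int(2147483646L, 3)
  })
  prof$rt_mean <- prof$rt_mean + 1.0 * (age - 72)
  prof$components$target$P300[["lat"]] <-
    prof$components$target$P300[["lat"]] + 1.0 * (age - 72)
  cov <- covariate_record(id, age, sex, edu, subgroup)
  schedule <- generate_schedule(session, seeds[1])
  rec <- synthesize_recording(schedule, prof, session, seeds[2])
  resp <- simulate_behavior(schedule, prof, session, seeds[3])
  list(covariates = cov, recording = rec, events = schedule,
       responses = resp)
}

#' Generate a synthetic cohort
#'
#' Deterministic under the master seed: per-participant seeds are drawn
#' once from it, so regenerating the cohort reproduces it exactly.
#'
#' @param cohort A [cohort_spec].
#' @return List of participants, each a list with elements `covariates`,
#'   `recording`, `events`, `responses`.
#' @export
generate_cohort <- function(cohort) {
  plan <- cohort_plan(cohort)
  lapply(seq_len(nrow(plan)), function(i) {
    synth_participant(plan$participant_id[i], plan$subgroup[i],
                      cohort$profiles, cohort$session, plan$seed[i])
  })
}

cohort_plan <- function(cohort) {
  subgroup <- rep(names(cohort$n_per_subgroup), cohort$n_per_subgroup)
  n <- length(subgroup)
  seeds <- withr::with_seed(cohort$seed, sample.int(2147483646L, n))
  data.frame(
    participant_id = sprintf("S%03d", seq_len(n)),
    subgroup = subgroup, seed = seeds, stringsAsFactors = FALSE
  )
}
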