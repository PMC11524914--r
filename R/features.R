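# Per-participant feature extraction: runs the full preprocessing,
# component, behavioral and connectivity chain for one session and
# assembles the feature-table rows (one per epoch kind).

#' Analysis parameter set
#'
#' Collects every tunable of the single-participant pipeline with its
#' default: 0.1-30 Hz FIR band-pass, -200..800 ms epochs with -200..0 ms
#' baseline, +/-100 uV artifact threshold, random selection of 64
#' standard epochs (matching the target count), 2 uV component threshold,
#' (100, 1000] ms response window, and the theta/alpha/beta bands.
#'
#' @param bp_low,bp_high Band-pass edges, Hz.
#' @param bp_taps FIR length for the band-pass (NULL = `8 * fs + 1`).
#' @param window,baseline Epoch and baseline windows, ms.
#' @param reject_uv Artifact rejection threshold, microvolts.
#' @param select_standard Number of standard epochs kept by random
#'   selection (NA to keep all).
#' @param min_amp Component detection threshold, microvolts.
#' @param resp_window Behavioral response window, ms.
#' @param bands Frequency bands for connectivity features.
#' @return List of class `analysis_params`.
#' @export
analysis_params <- function(bp_low = 0.1, bp_high = 30, bp_taps = NULL,
                            window = c(-200, 800), baseline = c(-200, 0),
                            reject_uv = 100, select_standard = 64,
                            min_amp = 2, resp_window = c(100, 1000),
                            bands = analysis_bands()) {
  if (baseline[1] < window[1] || baseline[2] > window[2]) {
    stop("baseline must lie inside the epoch window")
  }
  structure(
    list(
      bp_low = bp_low, bp_high = bp_high, bp_taps = bp_taps,
      window = window, baseline = baseline, reject_uv = reject_uv,
      select_standard = select_standard, min_amp = min_amp,
      resp_window = resp_window, bands = bands
    ),
    class = "analysis_params"
  )
}

band_suffix <- c(beta = "B", alpha = "A", theta = "T")

#' Extract all feature-table variables for one participant
#'
#' Runs band-pass filtering, epoching, baseline correction, artifact
#' rejection, random selection of standard epochs, averaging, component
#' detection on the two-channel mean trace (per-channel values retained
#' with `_Fp1`/`_Fp2` suffixes), single-trial P300 variability,
#' behavioral measures, and PLV/coherence band features, separately for
#' standard and target epochs.
#'
#' @param rec A [recording].
#' @param events An [event_log].
#' @param responses A [response_log].
#' @param params An [analysis_params] set.
#' @param participant_id Identifier copied into the rows.
#' @param seed Seed for the random selection of standard epochs.
#' @param keep_curves Also return PLV waveforms and coherence spectra for
#'   grand averaging.
#' @return List with `features` (two-row data frame) and, if requested,
#'   `curves` (nested list by kind/band) and `reports`.
#' @export
participant_features <- function(rec, events, responses,
                                 params = analysis_params(),
                                 participant_id = "P1", seed = 1,
                                 keep_curves = FALSE) {
  filt <- bandpass_fir(rec, params$bp_low, params$bp_high, params$bp_taps)
  rows <- list()
  curves <- list()
  reports <- list()
  for (kind in c("standard", "target")) {
    ep <- make_epochs(filt, events, kind, params$window, params$baseline)
    ep <- baseline_correct(ep, params$baseline)
    rj <- reject_artifacts(ep, params$reject_uv)
    ep <- rj$epochs
    if (kind == "standard" && is.finite(params$select_standard) &&
        n_epochs(ep) > params$select_standard) {
      ep <- random_select(ep, params$select_standard, seed)
    }
    erp <- average_epochs(ep)
    comp <- detect_components(erp, min_amp = params$min_amp)
    st <- single_trial_p300(ep)
    beh <- behavioral_measures(events, responses, kind, params$resp_window)
    row <- data.frame(
      participant_id = participant_id, kind = kind,
      n_epochs = n_epochs(ep),
      Cor_no = beh$Cor_no, Err_rate = beh$Err_rate,
      RT_mean = beh$RT_mean, RT_std = beh$RT_std,
      stringsAsFactors = FALSE
    )
    for (nm in c("N100", "P200", "P300")) {
      row[[paste0(nm, "_lat")]] <- comp[[nm]]$latency
      row[[paste0(nm, "_amp")]] <- comp[[nm]]$amplitude
      for (ch in c("Fp1", "Fp2")) {
        row[[paste0(nm, "_lat_", ch)]] <- comp$per_channel[[ch]][[nm]]$latency
        row[[paste0(nm, "_amp_", ch)]] <- comp$per_channel[[ch]][[nm]]$amplitude
      }
    }
    row$P300_lat_std <- st$lat_std
    row$P300_amp_std <- st$amp_std
    row$P300_amp_mean <- st$amp_mean
    cs <- coherence_spectrum(ep)
    cf <- coh_features(cs, params$bands)
    kcurves <- list(coherence = cs)
    for (bn in names(params$bands)) {
      sfx <- band_suffix[[bn]]
      w <- plv_waveform(ep, params$bands[[bn]])
      pf <- plv_features(w)
      row[[paste0("PLV_max_", sfx)]] <- pf$PLV_max
      row[[paste0("PLV_time_", sfx)]] <- pf$PLV_time
      row[[paste0("PLV_P200_", sfx)]] <- pf$PLV_P200
      row[[paste0("PLV_P300_", sfx)]] <- pf$PLV_P300
      row[[paste0("PLV_P_", sfx)]] <- pf$PLV_P
      row[[paste0("COH_max_", sfx)]] <- cf[[bn]]$COH_max
      row[[paste0("COH_freq_", sfx)]] <- cf[[bn]]$COH_freq
      row[[paste0("COH_mean_", sfx)]] <- cf[[bn]]$COH_mean
      row[[paste0("COH_std_", sfx)]] <- cf[[bn]]$COH_std
      kcurves[[paste0("plv_", bn)]] <- w
    }
    row$COH_mean <- cf$overall$COH_mean
    row$COH_std <- cf$overall$COH_std
    rows[[kind]] <- row
    reports[[kind]] <- rj$report
    if (keep_curves) curves[[kind]] <- kcurves
  }
  out <- list(features = do.call(rbind, rows), reports = reports)
  if (keep_curves) out$curves <- curves
  rownames(out$features) <- NULL
  out
}

#' Feature table for a whole synthetic cohort
#'
#' Generates each participant in turn (recordings are discarded after
#' feature extraction, so memory stays flat), merges the covariates, and
#' returns the combined feature table.
#'
#' @param cohort A [cohort_spec].
#' @param params An [analysis_params] set.
#' @return Data frame: covariates plus features, two rows (standard /
#'   target) per participant.
#' @export
cohort_feature_table <- function(cohort, params = analysis_params()) {
  plan <- cohort_plan(cohort)
  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    p <- synth_participant(plan$participant_id[i], plan$subgroup[i],
                           cohort$profiles, cohort$session, plan$seed[i])
    f <- participant_features(
      p$recording, p$events, p$responses, params,
      participant_id = plan$participant_id[i], seed = plan$seed[i]
    )$features
    out[[i]] <- merge(p$covariates, f, by = "participant_id")
  }
  do.call(rbind, out)
}
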