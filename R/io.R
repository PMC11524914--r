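# File interchange: EDF for recordings, TSV for events/responses,
# covariates and the participant feature table.  TSV dialect everywhere:
# UTF-8, tab-separated, "." decimal, mandatory header row.

#' Read a two-channel recording from EDF or TSV
#'
#' EDF files must contain signals labelled `Fp1` and `Fp2` (any extra
#' signals are ignored); TSV files must have columns `time`, `Fp1`, `Fp2`
#' with a uniform time step.  Channels are returned in Fp1, Fp2 order and
#' EDF physical dimensions of mV are converted to microvolts.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"edf"` or `"tsv"`.
#' @return A [recording].
#' @export
read_recording <- function(path, format = c("auto", "edf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv"
  }
  if (format == "edf") read_recording_edf(path) else read_recording_tsv(path)
}

read_recording_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  need <- c("time", "Fp1", "Fp2")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("TSV recording lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(d) < 2) stop("TSV recording too short")
  dt <- diff(d$time)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1])) {
    stop("non-uniform sampling in TSV recording")
  }
  recording(rbind(d$Fp1, d$Fp2), fs = 1 / dt[1], start_time = d$time[1])
}

# --- EDF (European Data Format) -------------------------------------------
# Minimal EDF support written for this package: fixed-layout ASCII header
# plus 16-bit little-endian samples.  No installed R package reads EDF, so
# the format's published byte layout is implemented directly.

edf_pad <- function(x, n) {
  x <- substr(as.character(x), 1, n)
  sprintf("%-*s", n, x)
}

#' Write a recording to an EDF file
#'
#' Samples are quantised to the 16-bit digital range mapped onto the
#' device's physical input range of +/- 393 microvolts, one data record per
#' second.  Recordings whose length is not a whole number of records are
#' zero-padded to the next record boundary.
#'
#' @param rec A [recording].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  ns <- 2L
  spr <- as.integer(round(rec$fs))          # samples per 1 s record
  if (abs(spr - rec$fs) > 1e-9) stop("EDF writer requires an integer Hz rate")
  n <- n_samples(rec)
  n_rec <- as.integer(ceiling(n / spr))
  pad <- n_rec * spr - n
  pmin <- -DEVICE_RANGE_UV; pmax <- DEVICE_RANGE_UV
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("X", 80),
    edf_pad("01.01.85", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + ns * 256, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4)
  )
  field <- function(vals, w) paste(vapply(vals, edf_pad, "", n = w),
                                   collapse = "")
  hdr <- paste0(
    hdr,
    field(rec$channel_labels, 16), field(rep("", ns), 80),
    field(rep("uV", ns), 8),
    field(rep(format(pmin), ns), 8), field(rep(format(pmax), ns), 8),
    field(rep(format(dmin), ns), 8), field(rep(format(dmax), ns), 8),
    field(rep("", ns), 80), field(rep(spr, ns), 8), field(rep("", ns), 32)
  )
  writeBin(charToRaw(hdr), con)
  scale <- (dmax - dmin) / (pmax - pmin)
  x <- cbind(rec$samples, matrix(0, 2, pad))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in 1:2) {
      dig <- as.integer(round((x[ch, idx] - pmin) * scale + dmin))
      writeBin(pmin(pmax(dig, dmin), dmax), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  num <- function(s) as.numeric(trimws(s))
  version <- rd(8); patient <- rd(80); recinfo <- rd(80)
  date <- rd(8); time <- rd(8)
  hdr_bytes <- num(rd(8)); reserved <- rd(44)
  n_rec <- num(rd(8)); rec_dur <- num(rd(8)); ns <- as.integer(num(rd(4)))
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fld(16); transducer <- fld(80); dim <- fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  prefilt <- fld(80); spr <- as.integer(fld(8)); fld(32)
  list(
    n_rec = n_rec, rec_dur = rec_dur, ns = ns, labels = labels, dim = dim,
    pmin = pmin, pmax = pmax, dmin = dmin, dmax = dmax, spr = spr
  )
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  want <- c("Fp1", "Fp2")
  ix <- match(want, h$labels)
  if (anyNA(ix)) {
    stop("EDF file lacks channel(s): ", paste(want[is.na(ix)], collapse = ", "))
  }
  sig <- vector("list", h$ns)
  for (i in seq_len(h$ns)) sig[[i]] <- numeric(h$n_rec * h$spr[i])
  for (r in seq_len(h$n_rec)) {
    for (i in seq_len(h$ns)) {
      dig <- readBin(con, "integer", h$spr[i], size = 2, endian = "little")
      sig[[i]][((r - 1) * h$spr[i] + 1):(r * h$spr[i])] <- dig
    }
  }
  out <- lapply(ix, function(i) {
    x <- h$pmin[i] + (sig[[i]] - h$dmin[i]) *
      (h$pmax[i] - h$pmin[i]) / (h$dmax[i] - h$dmin[i])
    if (grepl("^mV$", h$dim[i])) x <- x * 1000
    x
  })
  if (h$spr[ix[1]] != h$spr[ix[2]]) stop("Fp1/Fp2 sampling rates differ")
  fs <- h$spr[ix[1]] / h$rec_dur
  recording(rbind(out[[1]], out[[2]]), fs = fs)
}

# --- events / responses ----------------------------------------------------

#' Read stimulus events and responses from TSV
#'
#' The file must have columns `onset_s` and `kind`, with `kind` one of
#' `standard`, `target` (stimuli) or `response` (button presses).
#'
#' @param path File path.
#' @param .sort Sort rows by onset before validation (row order within the
#'   file is then irrelevant).
#' @return List with elements `events` ([event_log]) and `responses`
#'   ([response_log]).
#' @export
read_events <- function(path, .sort = FALSE) {
  d <- utils::read.delim(path)
  if (!all(c("onset_s", "kind") %in% names(d))) {
    stop("event TSV needs columns onset_s, kind")
  }
  bad <- setdiff(unique(d$kind), c("standard", "target", "response"))
  if (length(bad)) stop("unknown kind token: ", paste(bad, collapse = ", "))
  if (.sort) d <- d[order(d$onset_s), ]
  stim <- d[d$kind != "response", ]
  resp <- d[d$kind == "response", ]
  if (nrow(stim) == 0) stop("event file contains no stimulus rows")
  list(
    events = event_log(stim$onset_s, stim$kind),
    responses = response_log(sort(resp$onset_s))
  )
}

#' Write stimulus events and responses to TSV
#'
#' @param events An [event_log].
#' @param responses A [response_log] (optional).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_events <- function(events, responses = response_log(), path) {
  d <- rbind(
    data.frame(onset_s = events$onset_s, kind = events$kind),
    if (length(responses$press_times)) {
      data.frame(onset_s = responses$press_times, kind = "response")
    }
  )
  d <- d[order(d$onset_s), ]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- feature table / covariates -------------------------------------------

#' Write the participant feature table to TSV
#'
#' One row per participant per epoch kind.  Values round-trip through
#' [read_feature_table()] to at least 1e-9 relative precision.
#'
#' @param rows Data frame with at least `participant_id` and `kind` columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(rows, path) {
  key <- paste(rows$participant_id, rows$kind)
  if (anyDuplicated(key)) {
    stop("duplicate participant/kind rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  num <- vapply(rows, is.numeric, TRUE)
  rows[num] <- lapply(rows[num], function(x) {
    ifelse(is.na(x), NA, sprintf("%.15g", x))
  })
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a participant feature table written by [write_feature_table()]
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_feature_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a participant covariate table from TSV
#'
#' Expects columns `participant_id`, `age`, `sex`, `education`, `subgroup`;
#' the HC/MCI main group is derived from the subgroup.
#'
#' @param path File path.
#' @return Data frame with an added `main_group` column.
#' @export
read_covariates <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "age", "sex", "education", "subgroup")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("covariate TSV lacks: ", paste(miss, collapse = ", "))
  d$main_group <- main_group(d$subgroup)
  d
}
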