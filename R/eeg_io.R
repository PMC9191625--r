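#' Construct a single-channel EEG recording
#'
#' A `Recording` is a uniformly sampled single-channel trace in microvolts.
#' Time is 0-based seconds from the first sample; all event onsets downstream
#' are interpreted on this clock with half-open intervals.
#'
#' @param samples Numeric vector of samples in microvolts.
#' @param fs Sampling rate in Hz.
#' @param participant_id Participant identifier.
#' @param channel_label Channel label, e.g. `"Fp1-Fp2"`.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(samples, fs, participant_id = "anon",
                      channel_label = "Fp1-Fp2") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("no samples")
  if (!all(is.finite(samples))) stop("samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  structure(list(samples = samples, fs = fs,
                 participant_id = as.character(participant_id),
                 channel_label = channel_label, start_time = 0),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s], %d samples @ %g Hz (%.1f s)\n",
              x$participant_id, x$channel_label, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) length(rec$samples) / rec$fs

#' Read a recording from EDF or CSV
#'
#' CSV files hold one column of samples in microvolts (header `value`, or a
#' single unnamed column); the sampling rate must then be supplied. EDF files
#' carry the rate in their header; exactly one signal must be present or
#' selected by `channel`.
#'
#' @param path File path.
#' @param format `"EDF"` or `"CSV"` (default: guessed from the extension).
#' @param fs Sampling rate in Hz, required for CSV.
#' @param channel Channel index for multi-signal EDF files.
#' @param participant_id Participant identifier attached to the result.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = NULL, fs = NULL, channel = NULL,
                           participant_id = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "EDF" else "CSV"
  }
  format <- match.arg(toupper(format), c("EDF", "CSV"))
  pid <- participant_id %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "CSV") {
    if (is.null(fs)) stop("fs must be supplied for CSV recordings")
    if (file.info(path)$size == 0) stop("no samples")
    df <- utils::read.csv(path)
    col <- if ("value" %in% names(df)) df$value else df[[1L]]
    if (length(col) < 1L) stop("no samples")
    recording(col, fs = fs, participant_id = pid)
  } else {
    read_edf(path, channel = channel, participant_id = pid)
  }
}

# ---- minimal single-channel EDF ------------------------------------------
# 16-bit little-endian integers, fixed physical range, one data record per
# second. Only the subset of the format the pipeline needs.

edf_pad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits over the physical range (default
#' +/- 25 mV, i.e. +/- 25000 microvolts). One data record per second.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @param phys_range Physical range in microvolts (symmetric).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_range = 25000) {
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- as.integer(fs)
  n_rec <- ceiling(length(rec$samples) / ns)
  x <- rec$samples
  length(x) <- n_rec * ns           # zero-pad the last record
  x[is.na(x)] <- 0
  # same affine map the reader inverts: pmin<->dmin, pmax<->dmax
  dig <- round((x + phys_range) / (2 * phys_range) * 65535) - 32768
  dig <- pmin(pmax(dig, -32768), 32767)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                       # version
    edf_pad(substr(rec$participant_id, 1, 80), 80),
    edf_pad("synthetic recording", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256, 8),                 # header bytes (1 signal)
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),                       # record duration (s)
    edf_pad("1", 4))                       # number of signals
  sig <- paste0(
    edf_pad(substr(rec$channel_label, 1, 16), 16),
    edf_pad("EEG electrode", 80),
    edf_pad("uV", 8),
    edf_pad(-phys_range, 8), edf_pad(phys_range, 8),
    edf_pad(-32768, 8), edf_pad(32767, 8),
    edf_pad("", 80),
    edf_pad(ns, 8),
    edf_pad("", 32))
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  writeBin(as.integer(dig), con, size = 2, endian = "little")
  invisible(path)
}

read_edf <- function(path, channel = NULL, participant_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256, useBytes = TRUE)
  if (nchar(fixed) < 256) stop("no samples")
  fld <- function(s, a, b) trimws(substr(s, a, b))
  pid <- fld(fixed, 9, 88)
  n_rec <- as.integer(fld(fixed, 237, 244))
  rec_dur <- as.numeric(fld(fixed, 245, 252))
  n_sig <- as.integer(fld(fixed, 253, 256))
  if (is.na(n_sig) || n_sig < 1) stop("no samples")
  if (n_sig > 1 && is.null(channel))
    stop("multi-channel EDF requires a channel selector")
  ch <- channel %||% 1L
  sh <- readChar(con, 256 * n_sig, useBytes = TRUE)
  seg <- function(a, w) vapply(seq_len(n_sig), function(i)
    trimws(substr(sh, a + (i - 1) * w, a + i * w - 1)), "")
  labels <- seg(1, 16)
  off <- 16 * n_sig
  off <- off + 80 * n_sig   # transducer
  off <- off + 8 * n_sig    # unit
  pmin_ <- as.numeric(vapply(seq_len(n_sig), function(i)
    trimws(substr(sh, off + (i - 1) * 8 + 1, off + i * 8)), ""))
  off <- off + 8 * n_sig
  pmax_ <- as.numeric(vapply(seq_len(n_sig), function(i)
    trimws(substr(sh, off + (i - 1) * 8 + 1, off + i * 8)), ""))
  off <- off + 8 * n_sig
  dmin_ <- as.numeric(vapply(seq_len(n_sig), function(i)
    trimws(substr(sh, off + (i - 1) * 8 + 1, off + i * 8)), ""))
  off <- off + 8 * n_sig
  dmax_ <- as.numeric(vapply(seq_len(n_sig), function(i)
    trimws(substr(sh, off + (i - 1) * 8 + 1, off + i * 8)), ""))
  off <- off + 8 * n_sig + 80 * n_sig
  nsamp <- as.integer(vapply(seq_len(n_sig), function(i)
    trimws(substr(sh, off + (i - 1) * 8 + 1, off + i * 8)), ""))
  total_per_rec <- sum(nsamp)
  raw <- readBin(con, "integer", n = n_rec * total_per_rec, size = 2,
                 endian = "little")
  if (length(raw) < n_rec * total_per_rec) stop("truncated EDF data")
  mat <- matrix(raw, nrow = total_per_rec)
  sel0 <- c(0L, cumsum(nsamp))[ch] + seq_len(nsamp[ch])
  dig <- as.vector(mat[sel0, , drop = FALSE])
  scale <- (pmax_[ch] - pmin_[ch]) / (dmax_[ch] - dmin_[ch])
  phys <- pmin_[ch] + (dig - dmin_[ch]) * scale
  recording(phys, fs = nsamp[ch] / rec_dur,
            participant_id = participant_id %||% pid,
            channel_label = labels[ch])
}

# ---- event tables ---------------------------------------------------------

.event_cols <- c("onset_s", "duration_s", "kind", "instrument", "is_target",
                 "task_level")

#' Construct / validate an event list
#'
#' Events are kept sorted by onset; click records must have zero duration.
#' Kinds: `melody`, `instruction`, `click`, `block_start`.
#'
#' @param df Data frame with columns `onset_s`, `duration_s`, `kind`,
#'   `instrument`, `is_target`, `task_level`.
#' @return The sorted, validated data frame with class `event_list`.
#' @export
event_list <- function(df) {
  missing <- setdiff(.event_cols, names(df))
  if (length(missing)) stop("missing column: ", paste(missing, collapse = ", "))
  if (nrow(df) && any(df$onset_s < 0)) stop("negative onset")
  if (nrow(df) && any(df$duration_s < 0)) stop("negative duration")
  bad <- df$kind == "click" & df$duration_s != 0
  if (any(bad)) stop("click duration must be 0")
  df <- df[order(df$onset_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_list", "data.frame")
  df
}

#' Read an event/click table from CSV
#' @param path CSV path with the event-list columns.
#' @return An `event_list`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  event_list(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write any tabular result to CSV
#'
#' Values are written at full double precision (>= 10 significant digits) so
#' a read-back reproduces the table.
#'
#' @param table Non-empty data frame or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  if (is.matrix(table)) table <- as.data.frame(table)
  if (!is.data.frame(table) || nrow(table) == 0L || ncol(table) == 0L)
    stop("empty table")
  df <- table
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct / validate a participant table
#'
#' Checks that each participant's group is consistent with the MMSE cutoffs
#' 24 and 27 (`MMSE<24`, `MMSE24-27`, `MMSE>=28`), with young controls
#' (`YOUNG`) carrying no MMSE score.
#'
#' @param df Data frame with columns `participant_id`, `age`, `sex`, `mmse`,
#'   `group`.
#' @return Validated data frame with class `participant_table`.
#' @export
participant_table <- function(df) {
  need <- c("participant_id", "age", "sex", "mmse", "group")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing column: ", paste(missing, collapse = ", "))
  grp <- mmse_group(df$mmse)
  senior <- !is.na(df$mmse)
  if (any(senior & df$group != grp))
    stop("group inconsistent with MMSE cutoffs 24/27")
  if (any(senior & (df$mmse < 10 | df$mmse > 30)))
    stop("mmse out of [10, 30]")
  if (any(!senior & df$group != "YOUNG"))
    stop("participants without MMSE must be in group YOUNG")
  class(df) <- c("participant_table", "data.frame")
  df
}

#' Map MMSE scores to study groups (cutoffs 24 and 27)
#' @param mmse Integer MMSE scores; `NA` maps to `"YOUNG"`.
#' @return Character vector of group labels.
#' @export
mmse_group <- function(mmse) {
  ifelse(is.na(mmse), "YOUNG",
         ifelse(mmse < 24, "MMSE<24",
                ifelse(mmse <= 27, "MMSE24-27", "MMSE>=28")))
}

#' Read a participant metadata table from CSV
#' @param path CSV path.
#' @return A `participant_table`.
#' @export
read_participants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("mmse" %in% names(df)) df$mmse <- suppressWarnings(as.integer(df$mmse))
  participant_table(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
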