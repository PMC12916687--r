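# Minimal EDF (European Data Format) support: continuous recordings with a
# common sampling rate across channels, stored as a single data record so the
# write -> read roundtrip is exact up to 16-bit quantisation.

fixed_field <- function(x, width) {
  s <- substr(format(x, trim = TRUE, scientific = FALSE), 1L, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Signals are scaled per channel to the signed 16-bit digital range; the
#' amplitude resolution is `(max - min) / 65534` of each channel's range.
#'
#' @param rec A [raw_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  data <- rec$data
  ns <- nrow(data)
  L <- ncol(data)
  pmin <- apply(data, 1L, min)
  pmax <- apply(data, 1L, max)
  flat <- pmax - pmin < 1e-9
  pmax[flat] <- pmin[flat] + 1
  # physical limits must survive the 8-char ASCII fields exactly
  pmin <- as.numeric(fixed_field(signif(pmin, 6), 8L))
  pmax <- as.numeric(fixed_field(signif(pmax + abs(pmax) * 1e-5 + 1e-6, 6), 8L))
  dmin <- -32767; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, width) writeChar(fixed_field(x, width), con, nchars = width, eos = NULL)
  put("0", 8L)
  put(sprintf("subject %s", rec$subject_id), 80L)
  put(sprintf("trial %s label %s", rec$trial_id, rec$label), 80L)
  put("01.01.00", 8L); put("00.00.00", 8L)
  put(256L * (1L + ns), 8L)
  put("", 44L)
  put(1L, 8L)                               # one data record
  put(L / rec$fs, 8L)                       # record duration in seconds
  put(ns, 4L)
  for (lab in rec$channel_labels) put(lab, 16L)
  for (i in seq_len(ns)) put("", 80L)       # transducer
  for (i in seq_len(ns)) put("uV", 8L)
  for (i in seq_len(ns)) put(pmin[i], 8L)
  for (i in seq_len(ns)) put(pmax[i], 8L)
  for (i in seq_len(ns)) put(dmin, 8L)
  for (i in seq_len(ns)) put(dmax, 8L)
  for (i in seq_len(ns)) put("", 80L)       # prefiltering
  for (i in seq_len(ns)) put(L, 8L)
  for (i in seq_len(ns)) put("", 32L)
  for (i in seq_len(ns)) {
    dig <- round((data[i, ] - pmin[i]) / (pmax[i] - pmin[i]) * (dmax - dmin) + dmin)
    writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Supports the subset written by [write_edf()] plus any EDF whose signals
#' share one sampling rate; multiple data records are concatenated.
#'
#' @param path EDF file path.
#' @return A [raw_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  take <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- take(8L)
  if (version != "0") stop("malformed EDF header: bad version field", call. = FALSE)
  patient <- take(80L); recording <- take(80L)
  take(8L); take(8L)
  header_bytes <- as.integer(take(8L))
  take(44L)
  n_records <- as.integer(take(8L))
  rec_dur <- as.numeric(take(8L))
  ns <- as.integer(take(4L))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header: bad signal count", call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) take(16L), character(1))
  for (i in seq_len(ns)) take(80L)
  units <- vapply(seq_len(ns), function(i) take(8L), character(1))
  pmin <- vapply(seq_len(ns), function(i) as.numeric(take(8L)), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(take(8L)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(take(8L)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(take(8L)), numeric(1))
  for (i in seq_len(ns)) take(80L)
  spr <- vapply(seq_len(ns), function(i) as.integer(take(8L)), integer(1))
  for (i in seq_len(ns)) take(32L)
  if (length(unique(spr / rec_dur)) != 1L) {
    stop("EDF signals have differing sampling rates; not supported", call. = FALSE)
  }
  fs <- spr[1L] / rec_dur
  if (is.na(fs) || fs <= 0) stop("malformed EDF header: sampling rate missing", call. = FALSE)
  out <- matrix(0, ns, spr[1L] * n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, endian = "little")
      phys <- (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
      out[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- phys
    }
  }
  if (!all(is.finite(out))) stop("EDF data contains non-finite values", call. = FALSE)
  meta <- parse_edf_meta(patient, recording)
  raw_recording(out, fs, labels, subject_id = meta$subject_id,
                trial_id = meta$trial_id, label = meta$label)
}

parse_edf_meta <- function(patient, recording) {
  sid <- sub("^subject\\s+", "", patient)
  m <- regmatches(recording, regexec("^trial\\s+(\\S+)\\s+label\\s+(\\S+)", recording))[[1]]
  list(
    subject_id = if (nzchar(sid)) sid else NA,
    trial_id = if (length(m) == 3L) m[2L] else NA,
    label = if (length(m) == 3L) m[3L] else NA
  )
}
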