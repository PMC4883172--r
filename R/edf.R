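# Minimal European Data Format (EDF, 16-bit) reader and writer.
# Covers the plain-EDF subset used for clinical exchange: one fixed-rate
# int16 stream per signal with linear physical scaling. No EDF+ events.

edf_field <- function(con, n) trimws(readChar(con, n, useBytes = TRUE))

pad_field <- function(x, n) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > n) abort("EDF header field overflow")
  formatC(x, width = -n)
}

# physical-dimension string -> multiplier into uV
edf_unit_scale <- function(dim) {
  d <- tolower(trimws(dim))
  if (d %in% c("uv", "µv", "microvolt", "")) return(1)
  if (d == "mv") return(1e3)
  if (d == "v") return(1e6)
  warn(paste0("unrecognized EDF physical dimension '", dim, "'; assuming uV"))
  1
}

#' Read an EDF file into an [eeg_recording()]
#'
#' Plain EDF only (16-bit samples, linear scaling); all signals must share
#' one sampling rate. Physical units are converted to uV.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ver <- edf_field(con, 8)
  if (!identical(ver, "0")) abort(paste0("not an EDF file (version '", ver, "')"))
  readChar(con, 80 + 80 + 8 + 8, useBytes = TRUE)        # patient, rec, date, time
  header_bytes <- as.integer(edf_field(con, 8))
  edf_field(con, 44)                                      # reserved
  n_records <- as.integer(edf_field(con, 8))
  record_dur <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(ns) || ns < 1) abort("EDF header: bad signal count")

  sig_field <- function(width) vapply(seq_len(ns), function(i) edf_field(con, width), "")
  labels <- sig_field(16)
  sig_field(80)                                           # transducer
  dims <- sig_field(8)
  phys_min <- as.numeric(sig_field(8))
  phys_max <- as.numeric(sig_field(8))
  dig_min <- as.numeric(sig_field(8))
  dig_max <- as.numeric(sig_field(8))
  sig_field(80)                                           # prefilter
  spr <- as.integer(sig_field(8))                         # samples per record
  sig_field(32)                                           # reserved
  if (length(unique(spr)) != 1) {
    abort("EDF signals have differing sampling rates; not supported")
  }
  if (is.na(record_dur) || record_dur <= 0) abort("EDF header: bad record duration")
  rate <- spr[1] / record_dur

  seek(con, header_bytes)
  raw <- readBin(con, "integer", n = n_records * sum(spr), size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_records * sum(spr)) abort("EDF file truncated")
  # records are interleaved: per record, spr samples of each signal in turn
  out <- matrix(0, nrow = n_records * spr[1], ncol = ns)
  dim(raw) <- c(spr[1], ns, n_records)
  for (j in seq_len(ns)) out[, j] <- as.vector(raw[, j, ])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (j in seq_len(ns)) {
    out[, j] <- (phys_min[j] + (out[, j] - dig_min[j]) * gain[j]) *
      edf_unit_scale(dims[j])
  }
  eeg_recording(out, labels = labels, rate = rate)
}

#' Write an [eeg_recording()] as plain EDF
#'
#' Samples are quantized to 16 bits over an integer physical range just
#' covering each channel, so a read-back agrees with the original within
#' one quantization step.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  x <- rec$samples
  ns <- ncol(x)
  n <- nrow(x)
  phys_min <- floor(apply(x, 2, min)) - 1
  phys_max <- ceiling(apply(x, 2, max)) + 1
  dig_min <- -32768; dig_max <- 32767
  record_dur <- n / rec$rate

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)                                       # patient id
  wr("Startdate X X X X", 80)                             # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)
  header_bytes <- 256 + 256 * ns
  wr(header_bytes, 8)
  wr("", 44)
  wr(1, 8)                                                # one data record
  wr(format(record_dur, digits = 7), 8)
  wr(ns, 4)
  for (lab in rec$labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in phys_min) wr(format(v, scientific = FALSE), 8)
  for (v in phys_max) wr(format(v, scientific = FALSE), 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(n, 8)
  for (i in seq_len(ns)) wr("", 32)

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (j in seq_len(ns)) {
    dig <- round((x[, j] - phys_min[j]) / gain[j] + dig_min)
    writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}
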