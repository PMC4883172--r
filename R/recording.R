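#' EEG recording objects
#'
#' An `eeg_recording` holds a multi-channel EEG time series at a single
#' sampling rate. Amplitudes are microvolts (uV) throughout the package:
#' the stage-1 half-wave thresholds are stated in uV, so every reader
#' converts into that unit on input.
#'
#' @param samples numeric matrix, one column per channel (rows are samples),
#'   or a data frame of numeric columns.
#' @param labels character channel names (10-20 convention strings such as
#'   `"F8"`); defaults to the column names of `samples`.
#' @param rate sampling frequency in Hz (> 0).
#' @param start_time time of the first sample in seconds (default 0).
#'
#' @return An object of class `eeg_recording`: a list with elements
#'   `samples` (numeric matrix, samples x channels), `labels`, `rate`,
#'   `start_time`.
#' @examples
#' rec <- eeg_recording(cbind(T4 = sin(1:100), F8 = cos(1:100)), rate = 100)
#' rec_duration(rec)
#' @export
eeg_recording <- function(samples, labels = NULL, rate, start_time = 0) {
  if (is.data.frame(samples)) samples <- as.matrix(samples)
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.numeric(samples)) abort("`samples` must be numeric")
  if (is.null(labels)) labels <- colnames(samples)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(samples)))
  if (length(labels) != ncol(samples)) {
    abort("one label per channel is required")
  }
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    abort("`rate` must be a single positive number (Hz)")
  }
  if (anyNA(samples)) abort("recording contains missing values")
  colnames(samples) <- labels
  structure(
    list(samples = samples, labels = labels, rate = rate,
         start_time = start_time),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
    ncol(x$samples), nrow(x$samples), x$rate, rec_duration(x)
  ))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname eeg_recording
#' @param rec an `eeg_recording`.
#' @export
rec_duration <- function(rec) nrow(rec$samples) / rec$rate

#' @export
as_tibble.eeg_recording <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$samples)) |>
    dplyr::mutate(
      time = x$start_time + (dplyr::row_number() - 1) / x$rate,
      .before = 1
    )
}

#' Read an EEG recording
#'
#' Reads either European Data Format (EDF, 16-bit) or the package's
#' delimited-text exchange format: one column per channel, a header row of
#' channel labels, optionally preceded by a comment line `# rate: <Hz>`.
#' Amplitudes are converted to uV using the EDF physical-dimension field
#' (`mV` values are scaled by 1000, `V` by 1e6).
#'
#' @param path file path.
#' @param fmt `"edf"` or `"delimited"`; default guesses from the extension.
#' @param rate_hint sampling rate in Hz for delimited files whose header
#'   carries no rate line. A missing rate is an error, never a default.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, fmt = c("auto", "edf", "delimited"),
                           rate_hint = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (fmt == "auto") {
    fmt <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  }
  if (fmt == "edf") {
    return(read_edf(path))
  }
  lines <- readLines(path, n = 2L)
  if (length(lines) == 0 || !nzchar(lines[1])) abort("empty recording file")
  rate <- rate_hint
  skip <- 0L
  m <- regmatches(lines[1], regexec("^#\\s*rate:\\s*([0-9.eE+-]+)", lines[1]))[[1]]
  if (length(m) == 2) {
    rate <- as.numeric(m[2])
    skip <- 1L
  }
  if (is.null(rate) || is.na(rate)) {
    abort("sampling rate not found: give `rate_hint` or a '# rate: <Hz>' header line")
  }
  dat <- readr::read_csv(path, skip = skip, show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(dat) == 0) abort("recording file has no samples")
  if (!all(vapply(dat, is.numeric, logical(1)))) {
    abort("non-numeric values in recording file")
  }
  eeg_recording(as.matrix(dat), labels = names(dat), rate = rate)
}

#' Write a recording in the delimited-text format
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  writeLines(sprintf("# rate: %.10g", rec$rate), path)
  readr::write_csv(tibble::as_tibble(as.data.frame(rec$samples)), path,
                   append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read expert spike annotations
#'
#' One marker per line, `time_seconds[,channel]`, with an optional header
#' line. Times are seconds from recording start; output is sorted ascending
#' and markers closer than 1 ms are collapsed to the first.
#'
#' @param path annotation CSV path.
#' @return A tibble with columns `time` (s) and `channel` (character, `NA`
#'   when absent).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^\\s*(time|#)", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  if (!length(lines)) {
    return(tibble::tibble(time = numeric(), channel = character()))
  }
  parts <- strsplit(lines, ",")
  times <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  bad <- which(is.na(times))
  if (length(bad)) {
    abort(sprintf("non-numeric marker time on line %d: '%s'", bad[1], lines[bad[1]]))
  }
  if (any(times < 0)) {
    abort(sprintf("negative marker time on line %d", which(times < 0)[1]))
  }
  chan <- vapply(parts, function(p) if (length(p) > 1) trimws(p[2]) else NA_character_, "")
  ord <- order(times)
  times <- times[ord]; chan <- chan[ord]
  keep <- c(TRUE, diff(times) > 1e-3)
  tibble::tibble(time = times[keep], channel = chan[keep])
}

#' Write annotations in the package's CSV convention
#'
#' @param ann tibble with columns `time` and optionally `channel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  df <- tibble::tibble(
    time = ann$time,
    channel = if ("channel" %in% names(ann)) ann$channel else NA_character_
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Average selected channels into the single analysis trace
#'
#' The two-stage analysis operates on one time series, obtained as the
#' pointwise arithmetic mean of the informative channels (the ones the
#' expert read when marking spikes). One wanted channel returns that
#' channel unchanged.
#'
#' @param rec an [eeg_recording()].
#' @param wanted character vector of channel labels to average; default all.
#' @return Numeric vector (uV) at the recording's rate.
#' @export
select_average <- function(rec, wanted = rec$labels) {
  missing_lab <- setdiff(wanted, rec$labels)
  if (length(missing_lab)) {
    abort(paste0("unknown channel label(s): ", paste(missing_lab, collapse = ", ")))
  }
  if (!length(wanted)) abort("at least one channel must be selected")
  sub <- rec$samples[, wanted, drop = FALSE]
  rowMeans(sub)
}
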