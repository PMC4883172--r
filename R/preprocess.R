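#' Preprocessing configuration
#'
#' Parameters of the cleaning stage that turns a raw multi-channel
#' recording into the single analysis trace: mains notch, anti-aliased
#' downsampling, and stepwise baseline correction.
#'
#' @param target_rate analysis sampling rate in Hz (default 100).
#' @param notch_freq mains frequency to reject, Hz (default 50; set to
#'   `NULL` to skip).
#' @param notch_q notch quality factor (centre frequency / bandwidth).
#' @param baseline_segment baseline-estimation segment length in seconds.
#' @param baseline_overlap fractional overlap of consecutive segments,
#'   in `[0, 1)`.
#' @param smooth_window moving-average width (number of segment means,
#'   odd).
#' @param baseline whether to apply baseline correction at all.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate = 100, notch_freq = 50,
                              notch_q = 30, baseline_segment = 1.0,
                              baseline_overlap = 0.5, smooth_window = 5,
                              baseline = TRUE) {
  stopifnot(target_rate > 0, baseline_segment > 0,
            baseline_overlap >= 0, baseline_overlap < 1,
            smooth_window >= 1)
  structure(
    list(target_rate = target_rate, notch_freq = notch_freq,
         notch_q = notch_q, baseline_segment = baseline_segment,
         baseline_overlap = baseline_overlap,
         smooth_window = smooth_window, baseline = baseline),
    class = "preprocess_config"
  )
}

#' Zero-phase notch filter
#'
#' Second-order Butterworth band-reject applied forward-backward
#' ([signal::filtfilt()]), so mains interference is removed without
#' shifting peak latencies — the downstream scoring is latency-based.
#'
#' @param x numeric signal (uV).
#' @param rate sampling rate, Hz.
#' @param freq centre frequency to reject, Hz; must be below Nyquist.
#' @param q quality factor; the rejected band is `freq/q` wide.
#' @return Filtered signal, same length.
#' @export
notch_filter <- function(x, rate, freq = 50, q = 30) {
  if (freq <= 0 || freq >= rate / 2) {
    abort(sprintf("notch frequency %g Hz is not inside (0, Nyquist=%g) Hz",
                  freq, rate / 2))
  }
  bw <- freq / q
  lo <- max(freq - bw / 2, 1e-6)
  hi <- min(freq + bw / 2, rate / 2 * (1 - 1e-9))
  filt <- signal::butter(2, c(lo, hi) / (rate / 2), type = "stop")
  filtfilt_padded(filt, x, npad = ceiling(3 * rate / max(bw, 1e-6)))
}

# forward-backward filtering with edge-reflection padding, so boundary
# transients do not corrupt the ends of the trace
filtfilt_padded <- function(filt, x, npad) {
  n <- length(x)
  npad <- min(n - 1L, as.integer(npad))
  if (npad < 1L) return(as.numeric(signal::filtfilt(filt, x)))
  head_pad <- 2 * x[1] - x[(npad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- as.numeric(signal::filtfilt(filt, c(head_pad, x, tail_pad)))
  y[(npad + 1L):(npad + n)]
}

#' Anti-aliased downsampling
#'
#' Zero-phase low-pass at 90 % of the target Nyquist, then decimation
#' (for integer ratios) or resampling onto the target time grid.
#'
#' @param x numeric signal.
#' @param rate original rate, Hz.
#' @param target target rate, Hz (must not exceed `rate`).
#' @return Signal at `target` Hz.
#' @export
downsample_signal <- function(x, rate, target) {
  if (target > rate) abort("target rate exceeds the original rate")
  if (target == rate) return(x)
  filt <- signal::butter(4, 0.9 * target / rate)
  y <- filtfilt_padded(filt, x, npad = ceiling(10 * rate / target))
  ratio <- rate / target
  if (abs(ratio - round(ratio)) < 1e-9) {
    y[seq(1, length(y), by = round(ratio))]
  } else {
    t_old <- (seq_along(y) - 1) / rate
    t_new <- seq(0, t_old[length(t_old)], by = 1 / target)
    approx(t_old, y, xout = t_new, rule = 2)$y
  }
}

#' Stepwise baseline correction
#'
#' Estimates the slow baseline as the mean of overlapping segments
#' (value at each segment centre), smooths that stepwise series with a
#' centred moving average, interpolates linearly between centres and
#' subtracts. Zero-centres the local EEG average so that the stage-1
#' amplitude thresholds can be absolute.
#'
#' @param x numeric signal (uV).
#' @param rate sampling rate, Hz.
#' @param cfg a [preprocess_config()].
#' @return Baseline-corrected signal, same length.
#' @export
correct_baseline <- function(x, rate, cfg = preprocess_config()) {
  n <- length(x)
  seg <- round(cfg$baseline_segment * rate)
  if (seg < 2 || n < seg) return(x - mean(x))
  hop <- max(1L, round(seg * (1 - cfg$baseline_overlap)))
  starts <- seq(1L, max(1L, n - seg + 1L), by = hop)
  centers <- starts + (seg - 1) / 2
  means <- vapply(starts, function(s) mean(x[s:(s + seg - 1L)]), 0)
  w <- min(cfg$smooth_window, length(means))
  if (w %% 2 == 0) w <- w - 1L
  if (w >= 3) {
    sm <- means
    half <- (w - 1L) %/% 2L
    for (i in seq_along(means)) {
      lo <- max(1L, i - half); hi <- min(length(means), i + half)
      sm[i] <- mean(means[lo:hi])
    }
    means <- sm
  }
  base <- if (length(means) == 1) {
    rep(means, n)
  } else {
    approx(centers, means, xout = seq_len(n), rule = 2)$y
  }
  x - base
}

#' Full preprocessing pipeline
#'
#' Channel averaging, mains notch at the original rate, anti-aliased
#' downsampling to the analysis rate, then baseline correction. The
#' notch runs before decimation because a 50 Hz reject is degenerate at
#' the 100 Hz analysis rate (50 Hz is its Nyquist frequency).
#'
#' @param rec an [eeg_recording()].
#' @param channels channels to average into the analysis trace
#'   (default: all).
#' @param cfg a [preprocess_config()].
#' @return An [eeg_recording()] with the single channel `"avg"` at
#'   `cfg$target_rate`.
#' @export
preprocess <- function(rec, channels = rec$labels, cfg = preprocess_config()) {
  x <- select_average(rec, channels)
  if (!is.null(cfg$notch_freq) && cfg$notch_freq < rec$rate / 2) {
    x <- notch_filter(x, rec$rate, cfg$notch_freq, cfg$notch_q)
  }
  x <- downsample_signal(x, rec$rate, cfg$target_rate)
  if (isTRUE(cfg$baseline)) {
    x <- correct_baseline(x, cfg$target_rate, cfg)
  }
  eeg_recording(matrix(x, ncol = 1), labels = "avg", rate = cfg$target_rate,
                start_time = rec$start_time)
}
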