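#' Half-wave threshold set
#'
#' Stage-1 acceptance bounds on the two half-waves around the primary
#' vertex (the spike's negative extremum). Defaults are the clinical
#' working values: the amplitude differences A1 (preceding maximum minus
#' vertex) and A2 (following maximum minus vertex) must lie in
#' `[20, 500]` and `[50, 500]` uV, the half-wave durations D1 and D2 must
#' not exceed 200 and 150 ms. The upper amplitude bounds discard movement
#' artifacts; durations have no lower bound. All comparisons are
#' inclusive.
#'
#' @param a1_min,a1_max bounds on A1 in uV.
#' @param a2_min,a2_max bounds on A2 in uV.
#' @param d1_max,d2_max upper bounds on D1, D2 in ms.
#' @return A list of class `spike_thresholds`.
#' @export
spike_thresholds <- function(a1_min = 20, a1_max = 500,
                             a2_min = 50, a2_max = 500,
                             d1_max = 200, d2_max = 150) {
  stopifnot(a1_min < a1_max, a2_min < a2_max, d1_max > 0, d2_max > 0)
  structure(
    list(a1_min = a1_min, a1_max = a1_max, a2_min = a2_min,
         a2_max = a2_max, d1_max = d1_max, d2_max = d2_max),
    class = "spike_thresholds"
  )
}

# topographic prominence of local minima: depth below the lower of the two
# "saddle" maxima separating the minimum from deeper minima on each side
minima_prominence <- function(x, idx) {
  n <- length(x)
  vapply(idx, function(i) {
    v <- x[i]
    left_bar <- -Inf
    j <- i - 1L
    run_max <- -Inf
    while (j >= 1L) {
      if (x[j] > run_max) run_max <- x[j]
      if (x[j] < v) break
      j <- j - 1L
    }
    left_bar <- if (j >= 1L) run_max else max(x[seq_len(i)])
    j <- i + 1L
    run_max <- -Inf
    while (j <= n) {
      if (x[j] > run_max) run_max <- x[j]
      if (x[j] < v) break
      j <- j + 1L
    }
    right_bar <- if (j <= n) run_max else max(x[i:n])
    min(left_bar, right_bar) - v
  }, 0)
}

#' Detect candidate primary vertices
#'
#' Local minima of the analysis trace (spikes present with a pointed
#' negative phase), filtered two ways: minima must have topographic
#' prominence of at least `min_prominence`, and any two retained minima
#' must be separated by at least `min_separation`; when two conflict the
#' deeper one is kept (ties: the earlier).
#'
#' @param x numeric analysis signal (uV).
#' @param rate sampling rate, Hz.
#' @param min_separation minimum distance between retained peaks, ms.
#' @param min_prominence minimum topographic prominence, uV.
#' @return Integer vector of 1-based sample indices, ascending.
#' @export
detect_peaks <- function(x, rate, min_separation = 100, min_prominence = 10) {
  n <- length(x)
  if (n < 3) return(integer())
  is_min <- which(diff(sign(diff(x))) > 0) + 1L
  # plateau minima: keep the first sample of a flat bottom
  if (!length(is_min)) {
    d <- diff(x)
    is_min <- which(head(d, -1) < 0 & tail(d, -1) >= 0) + 1L
  }
  if (!length(is_min)) return(integer())
  prom <- minima_prominence(x, is_min)
  is_min <- is_min[prom >= min_prominence]
  if (!length(is_min)) return(integer())
  sep <- round(min_separation / 1000 * rate)
  # deepest-first greedy suppression; ties resolved toward the earlier index
  ord <- order(x[is_min], is_min)
  keep <- logical(length(is_min))
  taken <- integer()
  for (i in ord) {
    if (!length(taken) || all(abs(is_min[taken] - is_min[i]) >= sep)) {
      keep[i] <- TRUE
      taken <- c(taken, i)
    }
  }
  sort(is_min[keep])
}

#' Extract the spike waveform around a vertex
#'
#' Inclusive slice from `pre` ms before to `post` ms after the vertex.
#' At the 100 Hz analysis rate and default window this is
#' 10 + 1 + 20 = 31 samples. A vertex without full context on both sides
#' yields `NULL` (the candidate is discarded, not an error).
#'
#' @param x numeric signal.
#' @param rate sampling rate, Hz.
#' @param peak_index 1-based vertex sample index.
#' @param pre,post window extent before/after the vertex, ms.
#' @return Numeric waveform, or `NULL` when context is insufficient.
#' @export
extract_waveform <- function(x, rate, peak_index, pre = 100, post = 200) {
  npre <- round(pre / 1000 * rate)
  npost <- round(post / 1000 * rate)
  lo <- peak_index - npre
  hi <- peak_index + npost
  if (lo < 1 || hi > length(x)) return(NULL)
  x[lo:hi]
}

#' Half-wave features of a waveform
#'
#' The two half-waves run from the primary vertex (the waveform minimum)
#' to the closest local maximum on each side. Amplitudes are the maximum
#' minus the vertex value (uV); durations are the index distance over the
#' rate (ms). The same small-peaks-are-ignored rule that governs vertex
#' detection applies to the flanking maxima: a local maximum only counts
#' if its topographic prominence within the half-segment reaches
#' `min_prominence`, so a microvolt-scale noise wiggle beside the vertex
#' cannot pose as the half-wave peak. If no qualifying maximum exists
#' inside a half-window, the extreme sample of that segment stands in
#' for it — discarding such candidates would cost stage-1 sensitivity.
#'
#' @param w numeric waveform.
#' @param rate sampling rate, Hz.
#' @param vertex_offset 0-based offset of the vertex inside `w`.
#' @param min_prominence minimum prominence for a flanking maximum, uV.
#' @return One-row tibble with columns `A1`, `A2` (uV) and `D1`, `D2` (ms).
#' @export
halfwave_features <- function(w, rate, vertex_offset, min_prominence = 10) {
  n <- length(w)
  vi <- vertex_offset + 1L
  if (vi <= 1L || vi >= n) abort("vertex lies on the waveform edge")
  v <- w[vi]

  prominent_max <- function(seg) {
    if (length(seg) < 3) return(integer())
    lm <- which(diff(sign(diff(seg))) < 0) + 1L
    if (!length(lm)) return(integer())
    lm[minima_prominence(-seg, lm) >= min_prominence]
  }
  pre <- w[1:vi]
  lm_pre <- prominent_max(pre)
  ip <- if (length(lm_pre)) max(lm_pre) else which.max(pre)
  post <- w[vi:n]
  lm_post <- prominent_max(post)
  ia <- if (length(lm_post)) min(lm_post) else which.max(post)
  ia <- vi + ia - 1L

  tibble::tibble(
    A1 = w[ip] - v,
    A2 = w[ia] - v,
    D1 = (vi - ip) / rate * 1000,
    D2 = (ia - vi) / rate * 1000
  )
}

#' Apply the half-wave thresholds
#'
#' @param features data frame with columns `A1`, `A2`, `D1`, `D2` (one
#'   candidate per row).
#' @param thresholds a [spike_thresholds()].
#' @return The input with a logical `passed` column appended (inclusive
#'   comparisons).
#' @export
apply_thresholds <- function(features, thresholds = spike_thresholds()) {
  t <- thresholds
  dplyr::mutate(
    tibble::as_tibble(features),
    passed = .data$A1 >= t$a1_min & .data$A1 <= t$a1_max &
      .data$A2 >= t$a2_min & .data$A2 <= t$a2_max &
      .data$D1 <= t$d1_max & .data$D2 <= t$d2_max
  )
}

#' Stage 1: detect candidate spikes by half-wave shape analysis
#'
#' Composes peak detection, waveform extraction, half-wave measurement
#' and thresholding. The thresholds are deliberately loose (high
#' stage-1 sensitivity, poor specificity); stage 2 refines.
#'
#' @param x numeric analysis signal (uV), or a single-channel
#'   [eeg_recording()].
#' @param rate sampling rate, Hz (ignored when `x` is a recording).
#' @param thresholds a [spike_thresholds()].
#' @param min_separation,min_prominence see [detect_peaks()].
#' @param pre,post extraction window, ms (see [extract_waveform()]).
#' @return A tibble of class `spike_candidates`, one row per candidate
#'   with full window context: `peak_index`, `peak_time` (s), `A1`, `A2`,
#'   `D1`, `D2`, `passed`, `label` (factor, initialised `"unknown"`), and
#'   the list-column `waveform`. Attributes `rate`, `pre`, `post`,
#'   `duration` carry the extraction geometry.
#' @export
detect_candidates <- function(x, rate = NULL,
                              thresholds = spike_thresholds(),
                              min_separation = 100, min_prominence = 10,
                              pre = 100, post = 200) {
  if (inherits(x, "eeg_recording")) {
    if (ncol(x$samples) != 1) {
      abort("detect_candidates() needs a single-channel recording; preprocess() first")
    }
    rate <- x$rate
    x <- as.numeric(x$samples[, 1])
  }
  if (is.null(rate)) abort("`rate` is required for a bare signal")
  peaks <- detect_peaks(x, rate, min_separation, min_prominence)
  npre <- round(pre / 1000 * rate)
  waves <- lapply(peaks, function(p) extract_waveform(x, rate, p, pre, post))
  ok <- !vapply(waves, is.null, TRUE)
  peaks <- peaks[ok]; waves <- waves[ok]
  if (!length(peaks)) {
    out <- tibble::tibble(
      peak_index = integer(), peak_time = numeric(),
      A1 = numeric(), A2 = numeric(), D1 = numeric(), D2 = numeric(),
      passed = logical(),
      label = factor(character(), levels = c("spike", "non_spike", "unknown")),
      waveform = list()
    )
  } else {
    feats <- purrr::map(waves, halfwave_features, rate = rate,
                        vertex_offset = npre,
                        min_prominence = min_prominence) |>
      purrr::list_rbind()
    out <- tibble::tibble(
      peak_index = peaks,
      peak_time = (peaks - 1) / rate,
      feats,
      label = factor("unknown", levels = c("spike", "non_spike", "unknown")),
      waveform = waves
    ) |>
      apply_thresholds(thresholds) |>
      dplyr::relocate("passed", .after = "D2")
  }
  structure(out,
            class = c("spike_candidates", class(out)),
            rate = rate, pre = pre, post = post,
            duration = length(x) / rate)
}

#' Collect candidate waveforms into the ambient data matrix
#'
#' @param candidates a `spike_candidates` tibble.
#' @return Numeric matrix, one column per candidate (d x m).
#' @export
candidate_matrix <- function(candidates) {
  if (!nrow(candidates)) return(matrix(numeric(), nrow = 0, ncol = 0))
  lens <- lengths(candidates$waveform)
  if (length(unique(lens)) != 1) abort("candidate waveforms have unequal length")
  do.call(cbind, candidates$waveform)
}
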