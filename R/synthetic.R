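#' Synthetic recording configuration
#'
#' Defines a seeded EEG-like recording: stationary coloured-noise
#' background, planted negative-going triphasic spikes whose half-wave
#' parameters are drawn from configurable ranges inside the stage-1 pass
#' region, and spike-like distractor transients each violating exactly
#' one threshold bound. Defaults emulate a 30-minute 500 Hz clinical
#' trace: the background is a stationary AR(2) process (coefficients
#' 0.5, -0.2) with innovation SD 5 uV (about 5.6 uV RMS), and spikes
#' have typical clinical morphology (amplitudes tens-to-low-hundreds of
#' uV, half-wave durations 30-80 ms). Power-law (`one_over_f`)
#' background is available for heavier slow activity.
#'
#' @param duration seconds (default 1800).
#' @param rate Hz (default 500).
#' @param noise_sd AR innovation SD, uV.
#' @param ar_coeffs AR coefficients of the background (use
#'   `one_over_f` instead for power-law noise).
#' @param one_over_f optional list `list(exponent=, scale=)`: power-law
#'   background with spectrum `1/f^exponent` scaled to SD `scale` uV;
#'   overrides the AR model when non-`NULL`.
#' @param n_spikes,n_distractors event counts.
#' @param n_confounders number of nonspecific sharp transients
#'   (default 0): high-amplitude slower waves in the style of vertex
#'   waves / K-complexes that satisfy every stage-1 bound but are not
#'   spikes — the negative class stage 2 must learn to reject.
#' @param spike_ranges list of `c(min, max)` for `A1`, `A2` (uV) and
#'   `D1`, `D2` (ms); must sit inside the threshold pass region.
#' @param confounder_ranges like `spike_ranges`, for the nonspecific
#'   transients; the default regime (A ~ 150-400 uV, D ~ 85-140 ms) is
#'   inside the pass region but morphologically distinct from spikes.
#' @param distractor_rules character vector of bounds to violate, one
#'   recycled per distractor, from `"a1_min"`, `"a1_max"`, `"a2_min"`,
#'   `"a2_max"`, `"d2_max"`. (The D1 bound cannot bind inside the
#'   default 100 ms pre-vertex window, so it is not a useful distractor
#'   target.)
#' @param min_event_gap minimum separation between planted vertices, ms.
#' @param mains_amp amplitude of optional 50 Hz contamination, uV.
#' @param drift optional peak amplitude of a slow baseline ramp, uV.
#' @param seed RNG seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(duration = 1800, rate = 500, noise_sd = 5,
                             ar_coeffs = c(0.5, -0.2), one_over_f = NULL,
                             n_spikes = 20, n_distractors = 20,
                             n_confounders = 0,
                             spike_ranges = list(A1 = c(40, 120),
                                                 A2 = c(60, 150),
                                                 D1 = c(30, 80),
                                                 D2 = c(30, 80)),
                             confounder_ranges = list(A1 = c(150, 350),
                                                      A2 = c(180, 400),
                                                      D1 = c(85, 95),
                                                      D2 = c(100, 140)),
                             distractor_rules = c("a1_min", "a2_min",
                                                  "a1_max", "a2_max",
                                                  "d2_max"),
                             min_event_gap = 1000, mains_amp = 0,
                             drift = 0, seed = 1) {
  stopifnot(duration > 0, rate > 0, noise_sd >= 0,
            n_spikes >= 0, n_distractors >= 0, n_confounders >= 0,
            min_event_gap > 0)
  bad <- setdiff(distractor_rules,
                 c("a1_min", "a1_max", "a2_min", "a2_max", "d2_max"))
  if (length(bad)) abort(paste0("unknown distractor rule(s): ",
                                paste(bad, collapse = ", ")))
  structure(
    list(duration = duration, rate = rate, noise_sd = noise_sd,
         ar_coeffs = ar_coeffs, one_over_f = one_over_f,
         n_spikes = n_spikes, n_distractors = n_distractors,
         n_confounders = n_confounders,
         spike_ranges = spike_ranges,
         confounder_ranges = confounder_ranges,
         distractor_rules = distractor_rules,
         min_event_gap = min_event_gap, mains_amp = mains_amp,
         drift = drift, seed = seed),
    class = "synthetic_config"
  )
}

#' Triphasic spike template
#'
#' Piecewise raised-cosine waveform: rise to the pre-vertex positive
#' peak, descent to the negative primary vertex, rise to the post-vertex
#' positive peak, decay back to zero, with compact support and zero
#' endpoints. Durations snap to the sample grid so the measured
#' half-wave features reproduce the requested `A1`/`A2` exactly and
#' `D1`/`D2` within one sample period. The vertex depth is
#' `-min(A1, A2)/2`, keeping both flanking maxima positive.
#'
#' @param A1,A2 half-wave amplitude differences, uV.
#' @param D1,D2 half-wave durations, ms.
#' @param rate sampling rate, Hz.
#' @return List with `wave` (numeric) and `vertex_offset` (0-based index
#'   of the vertex within `wave`).
#' @export
spike_template <- function(A1, A2, D1, D2, rate) {
  n1 <- round(D1 / 1000 * rate)
  n2 <- round(D2 / 1000 * rate)
  if (n1 < 2 || n2 < 2) abort("half-wave durations must span at least 2 sample periods")
  v <- -min(A1, A2) / 2
  p1 <- A1 + v
  p2 <- A2 + v
  seg <- function(from, to, len) {
    u <- seq_len(len) / len
    from + (to - from) * (1 - cos(pi * u)) / 2
  }
  wave <- c(
    0,
    seg(0, p1, n1),      # onset ramp up to the leading positive peak
    seg(p1, v, n1),      # leading half-wave down to the vertex
    seg(v, p2, n2),      # trailing half-wave up to the second peak
    seg(p2, 0, n2)       # decay back to baseline
  )
  list(wave = wave, vertex_offset = 2L * n1)
}

#' Seeded coloured-noise background
#'
#' Either a stationary AR process driven by Gaussian innovations or
#' power-law (`1/f^a`) noise synthesized in the frequency domain.
#' Optional mains sinusoid and linear drift are added on top. Identical
#' seeds give bit-identical output.
#'
#' @param cfg a [synthetic_config()].
#' @param n number of samples (default from `cfg` duration).
#' @return Numeric signal, uV.
#' @export
generate_background <- function(cfg, n = round(cfg$duration * cfg$rate)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  if (!is.null(cfg$one_over_f)) {
    expo <- cfg$one_over_f$exponent
    scale <- cfg$one_over_f$scale
    white <- rnorm(n)
    sp <- fft(white)
    f <- c(1, seq_len(n - 1))
    f <- pmin(f, n - f + 1)                 # symmetric frequency index
    sp <- sp / f^(expo / 2)
    x <- Re(fft(sp, inverse = TRUE)) / n
    x <- x / sd(x) * scale
  } else if (cfg$noise_sd > 0) {
    p <- cfg$ar_coeffs
    if (length(p)) {
      roots <- polyroot(c(1, -p))
      if (any(Mod(roots) <= 1)) abort("AR coefficients are not stationary")
    }
    innov <- rnorm(n + 200, sd = cfg$noise_sd)
    x <- as.numeric(stats::filter(innov, p, method = "recursive"))
    x <- x[(length(x) - n + 1):length(x)]   # drop burn-in
  } else {
    x <- numeric(n)
  }
  t <- (seq_len(n) - 1) / cfg$rate
  if (cfg$mains_amp > 0) x <- x + cfg$mains_amp * sin(2 * pi * 50 * t)
  if (cfg$drift != 0) x <- x + cfg$drift * t / max(t[n], 1e-12)
  x
}

#' Simulate a labeled stage-2 candidate set
#'
#' Builds extraction-window waveforms directly (no continuous
#' recording): true spikes are conforming templates, non-spikes are
#' threshold-passing nonspecific sharp transients (the confounder
#' regime of [synthetic_config()] — the only negatives that survive
#' stage 1 in the full pipeline), both with additive AR background
#' noise at the analysis rate. Useful for exercising the embedding +
#' classification stage at scale.
#'
#' @param n_spikes,n_nonspikes class sizes.
#' @param rate analysis rate, Hz (default 100).
#' @param noise_sd additive AR(2) noise innovation SD, uV.
#' @param seed RNG seed.
#' @param cfg a [synthetic_config()] supplying the parameter ranges and
#'   distractor rules.
#' @param pre,post extraction window, ms.
#' @return A labeled `spike_candidates` tibble (all rows `passed`),
#'   ready for [crossval_stage2()].
#' @export
simulate_candidates <- function(n_spikes = 200, n_nonspikes = 1800,
                                rate = 100, noise_sd = 3, seed = 1,
                                cfg = synthetic_config(rate = rate, seed = seed),
                                pre = 100, post = 200) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  npre <- round(pre / 1000 * rate)
  npost <- round(post / 1000 * rate)
  len <- npre + npost + 1L
  make_wave <- function(kind) {
    p <- draw_event_params(cfg, kind)
    tpl <- spike_template(p$A1, p$A2, p$D1, p$D2, rate)
    w <- numeric(len)
    vi <- npre + 1L
    src <- seq_along(tpl$wave) - (tpl$vertex_offset + 1L)   # offsets from vertex
    keep <- src >= -npre & src <= npost
    w[vi + src[keep]] <- tpl$wave[keep]
    if (noise_sd > 0) {
      innov <- rnorm(len + 50, sd = noise_sd)
      nz <- as.numeric(stats::filter(innov, c(0.5, -0.2), method = "recursive"))
      w <- w + nz[(length(nz) - len + 1):length(nz)]
    }
    w
  }
  kinds <- c(rep("spike", n_spikes), rep("non_spike", n_nonspikes))
  waves <- lapply(kinds, function(k) {
    make_wave(if (k == "spike") "spike" else "confounder")
  })
  feats <- purrr::map(waves, halfwave_features, rate = rate,
                      vertex_offset = npre) |>
    purrr::list_rbind()
  out <- tibble::tibble(
    peak_index = seq_along(kinds) * round(0.4 * rate),
    peak_time = (seq_along(kinds) * round(0.4 * rate) - 1) / rate,
    feats,
    passed = TRUE,
    label = factor(kinds, levels = c("spike", "non_spike", "unknown")),
    waveform = waves
  )
  structure(out, class = c("spike_candidates", class(out)),
            rate = rate, pre = pre, post = post,
            duration = length(kinds) * 0.4)
}

# draw event parameters: conforming spikes, threshold-passing
# confounders, or a single-bound violation
draw_event_params <- function(cfg, kind, rule = NULL) {
  rg <- if (identical(kind, "confounder")) cfg$confounder_ranges else cfg$spike_ranges
  p <- list(
    A1 = runif(1, rg$A1[1], rg$A1[2]),
    A2 = runif(1, rg$A2[1], rg$A2[2]),
    D1 = runif(1, rg$D1[1], rg$D1[2]),
    D2 = runif(1, rg$D2[1], rg$D2[2])
  )
  if (kind == "distractor") {
    # violate the configured bound by a wide margin so measurement noise
    # cannot carry the transient back across the threshold
    switch(rule,
      a1_min = { p$A1 <- runif(1, 4, 8) },
      a1_max = { p$A1 <- runif(1, 600, 800) },
      a2_min = { p$A2 <- runif(1, 15, 25) },
      a2_max = { p$A2 <- runif(1, 600, 800) },
      d2_max = { p$D2 <- runif(1, 280, 320); p$A2 <- runif(1, 50, 60) }
    )
  }
  p
}

#' Generate a synthetic recording with ground truth
#'
#' Background noise plus planted spikes and distractors at uniformly
#' drawn times respecting the minimum event gap. Markers are placed
#' exactly at the planted vertices of the true spikes.
#'
#' @param cfg a [synthetic_config()].
#' @return List: `recording` (single-channel [eeg_recording()]),
#'   `annotations` (tibble `time`, `channel`) at the planted spike
#'   vertices, and `truth` — a tibble of every planted event
#'   (`time`, `kind`, `rule`, `A1`, `A2`, `D1`, `D2`).
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  n <- round(cfg$duration * cfg$rate)
  x <- generate_background(cfg, n)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)

  n_events <- cfg$n_spikes + cfg$n_distractors + cfg$n_confounders
  gap <- cfg$min_event_gap / 1000 * cfg$rate
  margin <- round(0.75 * cfg$rate)          # keep full waveform context
  placed <- numeric(0)
  tries <- 0
  while (length(placed) < n_events) {
    cand <- runif(1, margin, n - margin)
    if (!length(placed) || all(abs(placed - cand) >= gap)) {
      placed <- c(placed, cand)
    }
    tries <- tries + 1
    if (tries > 1000 * n_events) {
      abort("cannot place events with the requested minimum gap")
    }
  }
  placed <- round(placed)
  kinds <- sample(c(rep("spike", cfg$n_spikes),
                    rep("distractor", cfg$n_distractors),
                    rep("confounder", cfg$n_confounders)))
  rules <- rep_len(cfg$distractor_rules, max(1, cfg$n_distractors))
  ri <- 0
  rows <- vector("list", n_events)
  for (e in seq_len(n_events)) {
    kind <- kinds[e]
    rule <- NA_character_
    if (kind == "distractor") {
      ri <- ri + 1
      rule <- rules[ri]
    }
    p <- draw_event_params(cfg, kind, rule)
    tpl <- spike_template(p$A1, p$A2, p$D1, p$D2, cfg$rate)
    start <- placed[e] - tpl$vertex_offset
    idx <- start:(start + length(tpl$wave) - 1L)
    x[idx] <- x[idx] + tpl$wave
    rows[[e]] <- tibble::tibble(
      time = (placed[e] - 1) / cfg$rate, kind = kind, rule = rule,
      A1 = p$A1, A2 = p$A2, D1 = p$D1, D2 = p$D2
    )
  }
  truth <- purrr::list_rbind(rows) |> dplyr::arrange(.data$time)
  ann <- truth |>
    dplyr::filter(.data$kind == "spike") |>
    dplyr::transmute(time = .data$time, channel = "avg")
  list(
    recording = eeg_recording(matrix(x, ncol = 1), labels = "avg",
                              rate = cfg$rate),
    annotations = ann,
    truth = truth
  )
}
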