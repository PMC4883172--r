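test_that("detect_peaks keeps the deeper of two close minima", {
  rate <- 100
  x <- numeric(400)
  # two V-shaped dips 50 ms apart (5 samples), depths 80 and 30
  x[195:205] <- -c(seq(0, 80, length.out = 6), seq(64, 0, length.out = 5))
  x[200 + 5] <- -30    # shallower dip right next to the deep one
  peaks <- detect_peaks(x, rate, min_separation = 100, min_prominence = 10)
  expect_equal(peaks, 200)
})

test_that("detect_peaks handles degenerate and planted inputs", {
  expect_identical(detect_peaks(rep(1, 100), 100), integer())
  fix <- fixture_planted_trace()
  peaks <- detect_peaks(fix$x, fix$rate, min_separation = 100,
                        min_prominence = 10)
  # every planted vertex recovered within one sample
  for (v in fix$vertices) {
    expect_true(min(abs(peaks - v)) <= 1)
  }
})

test_that("candidate peak times respect the separation invariant", {
  fix <- fixture_planted_trace(noise_sd = 4, seed = 7)
  for (sep in c(100, 200)) {
    peaks <- detect_peaks(fix$x, fix$rate, min_separation = sep)
    if (length(peaks) > 1) {
      expect_true(all(diff(peaks) >= round(sep / 1000 * fix$rate)))
    }
  }
})

test_that("extract_waveform is an inclusive, aligned slice", {
  x <- sin(1:1000)
  w <- extract_waveform(x, 100, 500)
  expect_length(w, 31)
  expect_identical(w[11], x[500])
  expect_null(extract_waveform(x, 100, 3))
  expect_null(extract_waveform(x, 100, 995))
})

test_that("halfwave features match hand-constructed arithmetic", {
  rate <- 100
  # max 40 at -30 ms, vertex -20, max 30 at +50 ms
  w <- c(seq(0, 40, length.out = 4),            # rises to 40 at index 4
         seq(40, -20, length.out = 4)[-1],      # vertex -20 at index 7
         seq(-20, 30, length.out = 6)[-1],      # max 30 at index 12
         seq(30, 0, length.out = 4)[-1])
  f <- halfwave_features(w, rate, vertex_offset = 6)
  expect_equal(f$A1, 60)
  expect_equal(f$D1, 30)
  expect_equal(f$A2, 50)
  expect_equal(f$D2, 50)
})

test_that("halfwave features are symmetric for symmetric waves", {
  tpl <- spike_template(80, 80, 60, 60, 100)
  f <- halfwave_features(tpl$wave, 100, tpl$vertex_offset)
  expect_equal(f$A1, f$A2)
  expect_equal(f$D1, f$D2)
})

test_that("monotone half-segments fall back to the segment extreme", {
  w <- c(seq(10, -20, length.out = 11), seq(-20, 25, length.out = 21)[-1])
  f <- halfwave_features(w, 100, vertex_offset = 10)
  expect_equal(f$A1, 30)      # first sample of the window
  expect_equal(f$D1, 100)
  expect_equal(f$A2, 45)      # last sample of the window
  expect_equal(f$D2, 200)
  expect_error(halfwave_features(w, 100, vertex_offset = 0), "edge")
})

test_that("threshold comparisons are inclusive and bound-specific", {
  thr <- spike_thresholds()
  f <- function(A1, A2, D1, D2) tibble::tibble(A1 = A1, A2 = A2, D1 = D1, D2 = D2)
  expect_true(apply_thresholds(f(30, 60, 100, 80), thr)$passed)
  expect_false(apply_thresholds(f(30, 40, 100, 80), thr)$passed)   # A2 < 50
  expect_false(apply_thresholds(f(600, 60, 100, 80), thr)$passed)  # A1 > 500
  # inclusive bounds pass exactly at the limits
  expect_true(apply_thresholds(f(20, 50, 200, 150), thr)$passed)
  expect_true(apply_thresholds(f(500, 500, 200, 150), thr)$passed)
  expect_false(apply_thresholds(f(30, 60, 100, 151), thr)$passed)  # D2 > 150
})

test_that("stage 1 recovers planted spikes and rejects distractors", {
  cfg <- synthetic_config(duration = 600, n_spikes = 10, n_distractors = 10,
                          seed = 3)
  ds <- generate_dataset(cfg)
  cand <- run_detect(ds$recording)
  pass <- cand[cand$passed, ]
  spikes <- ds$truth$time[ds$truth$kind == "spike"]
  distr <- ds$truth$time[ds$truth$kind == "distractor"]
  hits <- vapply(spikes, function(tt) any(abs(pass$peak_time - tt) <= 0.05), TRUE)
  expect_gte(sum(hits), 9)
  d_hits <- vapply(distr, function(tt) any(abs(pass$peak_time - tt) <= 0.05), TRUE)
  expect_equal(sum(d_hits), 0)
})

test_that("pure low-amplitude noise yields no passing candidates", {
  withr::with_seed(11, x <- rnorm(6000, sd = 2))
  cand <- detect_candidates(x, 100)
  expect_equal(sum(cand$passed), 0)
})

test_that("vacuous thresholds pass every full-context peak", {
  fix <- fixture_planted_trace(noise_sd = 3, seed = 5)
  wide <- spike_thresholds(a1_min = -Inf, a1_max = Inf, a2_min = -Inf,
                           a2_max = Inf, d1_max = Inf, d2_max = Inf)
  cand <- detect_candidates(fix$x, fix$rate, thresholds = wide)
  peaks <- detect_peaks(fix$x, fix$rate)
  full <- sum(peaks - 10 >= 1 & peaks + 20 <= length(fix$x))
  expect_equal(sum(cand$passed), full)
})

test_that("relaxing any threshold never reduces the passing count", {
  fix <- fixture_planted_trace(noise_sd = 6, seed = 13)
  base <- spike_thresholds()
  n0 <- sum(detect_candidates(fix$x, fix$rate, thresholds = base)$passed)
  relaxed <- list(
    spike_thresholds(a1_min = 5),
    spike_thresholds(a2_min = 20),
    spike_thresholds(a1_max = 1000, a2_max = 1000),
    spike_thresholds(d2_max = 200)
  )
  for (thr in relaxed) {
    expect_gte(sum(detect_candidates(fix$x, fix$rate, thresholds = thr)$passed), n0)
  }
})

test_that("stored waveforms re-measure to the tabulated features", {
  cfg <- synthetic_config(duration = 300, n_spikes = 6, n_distractors = 4,
                          seed = 8)
  ds <- generate_dataset(cfg)
  cand <- run_detect(ds$recording)
  for (i in seq_len(nrow(cand))) {
    f <- halfwave_features(cand$waveform[[i]], attr(cand, "rate"), 10)
    expect_equal(unlist(f), unlist(cand[i, c("A1", "A2", "D1", "D2")]),
                 ignore_attr = TRUE)
  }
})
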