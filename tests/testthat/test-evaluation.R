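test_that("markers realign onto the nearest negative peak", {
  fix <- fixture_planted_trace()
  v <- fix$vertices[1]
  vertex_time <- (v - 1) / fix$rate
  ann <- tibble::tibble(time = vertex_time - 0.02)    # 20 ms early
  out <- realign_markers(ann, fix$x, fix$rate, radius = 50)
  expect_equal(out$time, vertex_time)
  # already-aligned marker is unchanged
  out2 <- realign_markers(tibble::tibble(time = vertex_time), fix$x, fix$rate)
  expect_equal(out2$time, vertex_time)
  # flat neighbourhood: earliest sample wins
  flat <- numeric(200)
  out3 <- realign_markers(tibble::tibble(time = 1.0), flat, 100, radius = 50)
  expect_equal(out3$time, 0.95)   # left edge of the +/-50 ms window
  expect_error(realign_markers(tibble::tibble(time = 99), flat, 100), "outside")
})

test_that("latency-windowed matching classifies detections", {
  m <- match_events(0.530, 0.5, latency = 50)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  m <- match_events(0.560, 0.5, latency = 50)
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 1, 1))
  m <- match_events(numeric(), c(1, 2, 3, 4, 5))
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 0, 5))
  # one detection cannot match two markers
  m <- match_events(1.0, c(0.98, 1.02))
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 1))
})

test_that("matching is invariant to global time translation", {
  withr::with_seed(10, {
    det <- sort(runif(6, 0, 10))
    mk <- sort(runif(5, 0, 10))
  })
  m1 <- match_events(det, mk)
  m2 <- match_events(det + 123.4, mk + 123.4)
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(m2$tp, m2$fp, m2$fn))
})

test_that("matching satisfies the counting identities and maximality", {
  greedy_optimal_agree <- 0
  for (s in 1:200) {
    withr::with_seed(1000 + s, {
      nd <- sample(0:10, 1); nm <- sample(0:10, 1)
      det <- sort(runif(nd, 0, 3))
      mk <- sort(runif(nm, 0, 3))
    })
    m <- match_events(det, mk, latency = 50)
    expect_equal(m$tp + m$fn, length(mk))
    expect_equal(m$tp + m$fp, length(det))
    expect_equal(m$tp, nrow(m$pairs))
    if (nrow(m$pairs)) {
      expect_true(all(abs(m$pairs$delta) <= 0.05 + 1e-12))
      expect_false(any(duplicated(m$pairs$detection)))
      expect_false(any(duplicated(m$pairs$marker)))
    }
    # maximality: no unmatched detection/marker pair is still compatible
    if (length(m$fp_times) && length(m$fn_times)) {
      expect_true(min(abs(outer(m$fp_times, m$fn_times, "-"))) > 0.05)
    }
    # greedy never exceeds the optimal assignment
    opt <- brute_force_match(det, mk, latency = 50)
    expect_lte(m$tp, opt)
    if (m$tp == opt) greedy_optimal_agree <- greedy_optimal_agree + 1
  }
  # closest-first greedy attains the optimum in nearly every random draw
  expect_gte(greedy_optimal_agree, 195)
})

test_that("metrics reproduce their defining arithmetic", {
  met <- detection_metrics(98, 58, 3, duration_min = 540)
  expect_equal(met$sensitivity, 98 / 101)
  expect_equal(met$selectivity, 98 / 156)
  expect_equal(met$fp_per_min, 58 / 540)
  expect_equal(met$fscore, 196 / 257)
  zero <- detection_metrics(0, 0, 0, duration_min = 10)
  expect_equal(unlist(zero[, c("sensitivity", "selectivity", "fscore")]),
               c(sensitivity = 0, selectivity = 0, fscore = 0))
  perfect <- detection_metrics(7, 0, 0, duration_min = 10)
  expect_equal(perfect$fscore, 1)
})

test_that("candidate labeling follows the latency rule", {
  cand <- tibble::tibble(
    peak_time = c(1.0, 2.0, 3.0), passed = TRUE,
    label = factor("unknown", levels = c("spike", "non_spike", "unknown"))
  )
  out <- label_candidates(cand, markers = c(1.04, 2.2), latency = 50)
  expect_equal(as.character(out$label), c("spike", "non_spike", "non_spike"))
})

test_that("cross-validation pools counts consistently and is seeded", {
  cand <- simulate_candidates(n_spikes = 40, n_nonspikes = 160, seed = 3)
  cv1 <- crossval_stage2(cand, l = 4, folds = 10, seed = 5)
  cv2 <- crossval_stage2(cand, l = 4, folds = 10, seed = 5)
  expect_equal(cv1$metrics, cv2$metrics)
  expect_equal(cv1$fold_metrics, cv2$fold_metrics)
  # partition identity: pooled tp + fn equals the positive count
  expect_equal(cv1$metrics$tp + cv1$metrics$fn, 40)
  expect_equal(sum(cv1$fold_metrics$tp + cv1$fold_metrics$fp +
                     cv1$fold_metrics$fn + cv1$fold_metrics$tn), 200)
  expect_error(crossval_stage2(cand, l = 4, folds = 50), "at least")
})

test_that("cross-validation separates planted spikes from sharp transients", {
  cand <- simulate_candidates(n_spikes = 60, n_nonspikes = 300, seed = 4)
  cv <- crossval_stage2(cand, l = "mle", folds = 10, seed = 6)
  expect_gte(cv$metrics$fscore, 0.9)
})
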