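test_that("class penalties follow the inverse size ratio", {
  p <- class_penalties(99, 4609)
  expect_equal(unname(p["pos"] / p["neg"]), 4609 / 99)
  expect_equal(unname(class_penalties(10, 10)["pos"] /
                        class_penalties(10, 10)["neg"]), 1)
  p2 <- class_penalties(99, 4609, c_base = 2)
  expect_equal(unname(p2), unname(2 * p))
  expect_equal(unname(p2["pos"] / p2["neg"]), 4609 / 99)
  # scaling both class sizes leaves the ratio unchanged
  p3 <- class_penalties(99 * 7, 4609 * 7)
  expect_equal(unname(p3["pos"] / p3["neg"]), 4609 / 99)
  expect_error(class_penalties(0, 10), "non-empty")
})

test_that("gamma formula evaluates in closed form with natural log", {
  # k = 1, l = 10: gamma = 1 / (10 ln 10)^2
  k <- 1; l <- 10
  expect_equal(1 / (k * l * log(l))^2, 0.001886117, tolerance = 1e-6)
  withr::with_seed(1, Y <- matrix(rnorm(10 * 60), 10, 60))
  cal <- calibrate_gamma(Y, l = 10)
  expect_equal(cal$gamma, 1 / (cal$k_const * 10 * log(10))^2)
})

test_that("calibrated gamma hits the target pair fraction", {
  withr::with_seed(2, Y <- matrix(rnorm(5 * 200), 5, 200))
  cal <- calibrate_gamma(Y, l = 5, kernel_fraction = 0.20)
  d <- as.numeric(dist(t(Y)))
  achieved <- mean(d <= 1 / sqrt(cal$gamma))
  expect_lt(abs(achieved - 0.20), 0.01)
  expect_equal(cal$fraction, achieved)
})

test_that("larger kernel fractions give larger radii", {
  withr::with_seed(3, Y <- matrix(rnorm(4 * 150), 4, 150))
  radii <- vapply(c(0.1, 0.2, 0.4, 0.6), function(f) {
    calibrate_gamma(Y, l = 4, kernel_fraction = f)$radius
  }, 0)
  expect_true(all(diff(radii) >= 0))
})

test_that("degenerate calibration inputs error out", {
  expect_error(calibrate_gamma(matrix(rnorm(20), 1, 20)), "l < 2")
  expect_error(calibrate_gamma(matrix(1, 3, 20), l = 3), "coincide")
  expect_error(calibrate_gamma(matrix(rnorm(12), 2, 6), l = 2), "at least 10")
})

test_that("the weighted classifier separates seeded blobs", {
  withr::with_seed(4, {
    Y <- cbind(matrix(rnorm(2 * 40, mean = 0, sd = 0.4), 2, 40),
               matrix(rnorm(2 * 40, mean = 3, sd = 0.4), 2, 40))
  })
  labs <- rep(c("spike", "non_spike"), each = 40)
  mod <- train_classifier(Y, labs)
  pr <- predict(mod, Y)
  expect_equal(as.character(pr$label), labs)
  # score sign agrees with the label everywhere
  expect_true(all((pr$score > 0) == (pr$label == "spike")))
  expect_error(train_classifier(Y, rep("spike", 80)), "both classes")
})

test_that("label flips flip the predictions", {
  withr::with_seed(5, {
    Y <- cbind(matrix(rnorm(2 * 30, 0, 0.5), 2, 30),
               matrix(rnorm(2 * 30, 3, 0.5), 2, 30))
  })
  labs <- rep(c("spike", "non_spike"), each = 30)
  flip <- rep(c("non_spike", "spike"), each = 30)
  m1 <- train_classifier(Y, labs)
  m2 <- train_classifier(Y, flip)
  p1 <- predict(m1, Y)$label
  p2 <- predict(m2, Y)$label
  expect_true(all(p1 != p2))
})

test_that("duplicating the training set leaves the decision intact", {
  withr::with_seed(6, {
    Y <- cbind(matrix(rnorm(2 * 25, 0, 0.5), 2, 25),
               matrix(rnorm(2 * 25, 3, 0.5), 2, 25))
    grid <- rbind(runif(50, -1, 4), runif(50, -1, 4))
  })
  labs <- rep(c("spike", "non_spike"), each = 25)
  m1 <- train_classifier(Y, labs, gamma = 0.5)
  m2 <- train_classifier(cbind(Y, Y), c(labs, labs), gamma = 0.5)
  expect_equal(as.character(predict(m1, grid)$label),
               as.character(predict(m2, grid)$label))
})

test_that("prediction validates dimensionality and handles empty input", {
  withr::with_seed(7, {
    Y <- cbind(matrix(rnorm(3 * 20, 0, 0.5), 3, 20),
               matrix(rnorm(3 * 20, 3, 0.5), 3, 20))
  })
  mod <- train_classifier(Y, rep(c("spike", "non_spike"), each = 20))
  expect_error(predict(mod, matrix(0, 2, 4)), "mismatch")
  empty <- predict(mod, matrix(numeric(), 3, 0))
  expect_equal(nrow(empty), 0)
})

test_that("stage-2 CV on separated Gaussian embeddings is near-perfect", {
  win31 <- function(A1, A2, D1, D2) {
    tpl <- spike_template(A1, A2, D1, D2, 100)
    w <- numeric(31)
    src <- seq_along(tpl$wave) - (tpl$vertex_offset + 1L)
    keep <- src >= -10 & src <= 20
    w[11 + src[keep]] <- tpl$wave[keep]
    w
  }
  withr::with_seed(8, {
    waves <- c(
      lapply(1:60, function(i) win31(80, 90, 50, 50) + rnorm(31)),
      lapply(1:240, function(i) win31(250, 300, 90, 120) + rnorm(31))
    )
  })
  labs <- c(rep("spike", 60), rep("non_spike", 240))
  cand <- tibble::tibble(
    peak_index = seq_along(waves) * 40,
    peak_time = seq_along(waves) * 0.4,
    A1 = 0, A2 = 0, D1 = 0, D2 = 0, passed = TRUE,
    label = factor(labs, levels = c("spike", "non_spike", "unknown")),
    waveform = waves
  )
  cand <- structure(cand, class = c("spike_candidates", class(cand)),
                    rate = 100, pre = 100, post = 200, duration = 120)
  cv <- crossval_stage2(cand, l = 3, folds = 10, seed = 2)
  expect_gte(cv$metrics$sensitivity, 0.95)
  spec <- sum(cv$fold_metrics$tn) /
    (sum(cv$fold_metrics$tn) + sum(cv$fold_metrics$fp))
  expect_gte(spec, 0.95)
})
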