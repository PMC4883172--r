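test_that("MLE recovers known manifold dimensionalities", {
  est3 <- vapply(1:5, function(s) {
    withr::with_seed(s, {
      P <- matrix(rnorm(1000 * 3), 1000, 3)
      P <- P * runif(1000)^(1 / 3) / sqrt(rowSums(P^2))   # uniform 3-ball
      Q <- P %*% matrix(rnorm(3 * 20), 3, 20) +
        matrix(rnorm(1000 * 20, sd = 1e-3), 1000, 20)
      estimate_intrinsic_dim(t(Q))
    })
  }, 0L)
  expect_true(all(abs(est3 - 3) <= 1))

  withr::with_seed(1, {
    line <- rbind(seq(0, 1, length.out = 500)) %x% rnorm(10)
    dim(line) <- c(10, 500)
  })
  expect_equal(estimate_intrinsic_dim(line), 1L)

  expect_error(estimate_intrinsic_dim(matrix(rnorm(50), 5, 10)), "k_max")
})

test_that("graph construction satisfies the Laplacian identities", {
  withr::with_seed(2, X <- matrix(rnorm(4 * 25), 4, 25))
  g <- build_graph(X, graph_params(n_neighbors = 5))
  expect_true(isSymmetric(g$W))
  expect_true(all(diag(g$W) == 0))
  expect_equal(max(abs(rowSums(g$L))), 0, tolerance = 1e-12)
  expect_equal(diag(g$D), colSums(g$W), ignore_attr = TRUE)

  # two points, k = 1: closed form
  X2 <- cbind(c(0, 0), c(3, 4))
  g2 <- build_graph(X2, graph_params(n_neighbors = 1, heat_t = 10))
  expect_equal(g2$W[1, 2], exp(-25 / 10))
  expect_equal(diag(g2$D), rep(exp(-25 / 10), 2), ignore_attr = TRUE)
})

test_that("fit_lpp solves the generalized eigenproblem", {
  withr::with_seed(3, X <- matrix(rnorm(5 * 20), 5, 20))
  m <- fit_lpp(X, 3)
  g <- build_graph(X, graph_params())
  G <- X %*% g$L %*% t(X)
  B <- X %*% g$D %*% t(X)
  for (k in 1:3) {
    a <- m$A[, k]
    resid <- sqrt(sum((G %*% a - m$eigenvalues[k] * B %*% a)^2)) /
      sqrt(sum((B %*% a)^2))
    expect_lt(resid, 1e-6)
    expect_equal(as.numeric(t(a) %*% B %*% a), 1, tolerance = 1e-8)
  }
  expect_true(all(diff(m$eigenvalues) >= -1e-12))
  expect_true(all(m$eigenvalues >= -1e-10))
})

test_that("eigenpairs match a dense brute-force solver after sign alignment", {
  for (s in 1:3) {
    withr::with_seed(s, X <- matrix(rnorm(8 * 30), 8, 30))
    l <- 4
    m <- fit_lpp(X, l)
    g <- build_graph(X, graph_params())
    orc <- dense_gev_oracle(X %*% g$L %*% t(X), X %*% g$D %*% t(X))
    expect_equal(m$eigenvalues, orc$values[seq_len(l)], tolerance = 1e-8)
    B <- X %*% g$D %*% t(X)
    for (k in seq_len(l)) {
      v <- orc$vectors[, k]
      v <- v / sqrt(as.numeric(t(v) %*% B %*% v))    # same normalization
      if (sum(v * m$A[, k]) < 0) v <- -v             # sign alignment
      expect_equal(m$A[, k], v, tolerance = 1e-8)
    }
  }
})

test_that("a 1-D LPP separates well-separated clusters", {
  withr::with_seed(4, {
    X <- cbind(matrix(rnorm(10 * 30, mean = 0, sd = 0.3), 10, 30),
               matrix(rnorm(10 * 30, mean = 4, sd = 0.3), 10, 30))
  })
  m <- fit_lpp(X, 1)
  y <- as.numeric(lpp_transform(m, X))
  a <- y[1:30]; b <- y[31:60]
  expect_true(max(a) < min(b) || max(b) < min(a))
})

test_that("the embedding map is linear and exact out-of-sample", {
  withr::with_seed(5, X <- matrix(rnorm(6 * 25), 6, 25))
  m <- fit_lpp(X, 2)
  Y <- lpp_transform(m, X)
  expect_equal(lpp_transform(m, X[, 3]), Y[, 3, drop = FALSE])
  expect_equal(lpp_transform(m, matrix(0, 6, 1)),
               matrix(0, 2, 1), ignore_attr = TRUE)
  x <- X[, 1]
  expect_equal(lpp_transform(m, 2 * x), 2 * lpp_transform(m, x),
               tolerance = 1e-12)
  expect_error(lpp_transform(m, matrix(0, 5, 1)), "mismatch")
})

test_that("fit_lpp is column-permutation invariant up to sign", {
  withr::with_seed(6, X <- matrix(rnorm(5 * 24), 5, 24))
  m1 <- fit_lpp(X, 2)
  m2 <- fit_lpp(X[, sample(24)], 2)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-8)
  expect_equal(abs(m1$A), abs(m2$A), tolerance = 1e-6)
})

test_that("locality is preserved better than by a random projection", {
  # data on a smooth 1-D closed curve lifted into 20 dimensions: rank-2
  # LPP should keep curve neighbourhoods together where a rank-2 random
  # projection folds the curve onto itself
  knn_overlap <- function(Y, X, k = 5) {
    da <- as.matrix(dist(t(X))); diag(da) <- Inf
    de <- as.matrix(dist(t(Y))); diag(de) <- Inf
    mean(vapply(seq_len(ncol(X)), function(i) {
      length(intersect(order(da[i, ])[1:k], order(de[i, ])[1:k])) / k
    }, 0))
  }
  for (s in c(1, 2, 4)) {
    withr::with_seed(s, {
      tt <- sort(runif(120))
      B <- matrix(rnorm(20 * 4), 20, 4)
      feat <- rbind(sin(2 * pi * tt), cos(2 * pi * tt),
                    sin(4 * pi * tt), cos(4 * pi * tt))
      X <- B %*% feat + matrix(rnorm(20 * 120, sd = 0.05), 20, 120)
    })
    m <- fit_lpp(X, 2)
    lpp_o <- knn_overlap(lpp_transform(m, X), X)
    withr::with_seed(100 + s, R <- matrix(rnorm(2 * 20), 2, 20))
    rnd_o <- knn_overlap(R %*% X, X)
    expect_gte(lpp_o, rnd_o)
  }
})

test_that("embedding models serialize to JSON and back", {
  withr::with_seed(9, X <- matrix(rnorm(6 * 20), 6, 20))
  m <- fit_lpp(X, 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_lpp(m, path)
  back <- read_lpp(path)
  expect_equal(back$A, m$A)
  expect_equal(back$eigenvalues, m$eigenvalues)
  expect_equal(back$graph$n_neighbors, m$graph$n_neighbors)
  expect_equal(lpp_transform(back, X), lpp_transform(m, X))
})
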