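#' Neighbourhood-graph parameters for the embedding
#'
#' The candidates form the nodes of a k-nearest-neighbour graph whose
#' edge weights decay with distance. Defaults follow the usual locality
#' preserving projection practice: symmetric 7-NN adjacency and heat
#' kernel weights `exp(-d^2 / t)` with `t` set to the mean squared
#' k-NN distance of the data.
#'
#' @param n_neighbors k of the adjacency graph.
#' @param weight_mode `"heat"` or `"binary"` edge weights.
#' @param heat_t heat-kernel width; `NULL` (default) uses the mean
#'   squared k-NN distance.
#' @return A list of class `graph_params`.
#' @export
graph_params <- function(n_neighbors = 7, weight_mode = c("heat", "binary"),
                         heat_t = NULL) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(n_neighbors >= 1)
  structure(list(n_neighbors = n_neighbors, weight_mode = weight_mode,
                 heat_t = heat_t),
            class = "graph_params")
}

# pairwise Euclidean distance matrix between the columns of X
col_dist <- function(X) as.matrix(dist(t(X)))

#' Maximum-likelihood intrinsic dimensionality
#'
#' Levina-Bickel nearest-neighbour estimator in its corrected form: for
#' each point and neighbourhood size k,
#' `1/m_k(x) = (1/(k-1)) * sum_{j<k} log(T_k(x)/T_j(x))` with `T_j` the
#' distance to the j-th nearest neighbour; the inverse estimates are
#' averaged over points and then over `k` in `[k_min, k_max]`, and the
#' reciprocal of that mean is rounded to the nearest integer (at least 1).
#'
#' @param X d x m matrix, one observation per column.
#' @param k_min,k_max neighbourhood range (defaults 6-12, the
#'   estimator authors' recommendation).
#' @return Integer dimensionality estimate.
#' @export
estimate_intrinsic_dim <- function(X, k_min = 6, k_max = 12) {
  m <- ncol(X)
  if (m <= k_max) {
    abort(sprintf("need more than k_max = %d observations (got %d)", k_max, m))
  }
  dm <- col_dist(X)
  diag(dm) <- Inf
  Tk <- t(apply(dm, 1, function(r) sort(r)[seq_len(k_max)]))
  if (any(Tk <= 0)) {
    warn("duplicate points give zero neighbour distances; perturbing by machine epsilon")
    Tk[Tk <= 0] <- .Machine$double.eps
  }
  inv_per_k <- vapply(k_min:k_max, function(k) {
    inv_point <- rowSums(log(Tk[, k] / Tk[, seq_len(k - 1), drop = FALSE])) / (k - 1)
    mean(inv_point)
  }, 0)
  est <- 1 / mean(inv_per_k)
  max(1L, as.integer(round(est)))
}

#' Build the candidate neighbourhood graph
#'
#' Symmetric k-NN adjacency (an edge exists if either endpoint lists the
#' other among its k nearest neighbours) with heat-kernel or binary
#' weights; returns the weight matrix `W`, the diagonal degree matrix
#' `D` (column sums of `W`) and the graph Laplacian `L = D - W`.
#'
#' @param X d x m matrix of column observations.
#' @param params a [graph_params()].
#' @return List with elements `W`, `D`, `L` (m x m matrices) and the
#'   resolved `heat_t`.
#' @export
build_graph <- function(X, params = graph_params()) {
  m <- ncol(X)
  if (m < 2) abort("graph needs at least two observations")
  k <- min(params$n_neighbors, m - 1)
  dm <- col_dist(X)
  diag(dm) <- Inf
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    nb <- order(dm[i, ])[seq_len(k)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  d2 <- dm^2
  heat_t <- params$heat_t
  if (params$weight_mode == "heat") {
    if (is.null(heat_t)) {
      knn_d2 <- apply(dm, 1, function(r) sort(r)[seq_len(k)])^2
      heat_t <- mean(knn_d2)
    }
    W <- ifelse(adj, exp(-d2 / heat_t), 0)
  } else {
    W <- ifelse(adj, 1, 0)
    heat_t <- NA_real_
  }
  diag(W) <- 0
  deg <- colSums(W)
  D <- diag(deg, m)
  list(W = W, D = D, L = D - W, heat_t = heat_t)
}

#' Fit a locality preserving projection
#'
#' Learns the linear map `y = A' x` that best preserves the
#' neighbourhood graph of the data, by solving the generalized
#' eigenproblem `X L X' a = lambda X D X' a` and keeping the `l`
#' eigenvectors of smallest eigenvalue. Each eigenvector is normalized
#' to `a' (X D X') a = 1` with its first nonzero component positive, so
#' fits are reproducible bit for bit. A singular `X D X'` is ridged by
#' `1e-9 * trace/d` on the diagonal (with a warning).
#'
#' @param X d x m matrix of column waveforms.
#' @param l embedding dimensionality, `1 <= l <= d`.
#' @param params a [graph_params()].
#' @return An object of class `lpp` with elements `A` (d x l),
#'   `eigenvalues` (ascending), `l`, `d`, `graph` (the parameters,
#'   with resolved `heat_t`).
#' @export
fit_lpp <- function(X, l, params = graph_params()) {
  d <- nrow(X); m <- ncol(X)
  if (l < 1 || l > d) abort("embedding dimension must satisfy 1 <= l <= d")
  g <- build_graph(X, params)
  G <- X %*% g$L %*% t(X)
  B <- X %*% g$D %*% t(X)
  G <- (G + t(G)) / 2
  B <- (B + t(B)) / 2
  R <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(R)) {
    warn("X D X' is singular; adding a 1e-9 * trace/d ridge")
    B <- B + diag(1e-9 * sum(diag(B)) / d, d)
    R <- chol(B)
  }
  Rinv <- backsolve(R, diag(d))
  M <- t(Rinv) %*% G %*% Rinv
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  idx <- rev(seq_len(d))[seq_len(l)]          # smallest first
  vals <- eig$values[idx]
  A <- Rinv %*% eig$vectors[, idx, drop = FALSE]
  for (j in seq_len(l)) {
    nz <- which(abs(A[, j]) > 1e-12)
    if (length(nz) && A[nz[1], j] < 0) A[, j] <- -A[, j]
  }
  params$heat_t <- g$heat_t
  structure(
    list(A = A, eigenvalues = vals, l = l, d = d, m = m, graph = params),
    class = "lpp"
  )
}

#' Embed data with a fitted projection
#'
#' The out-of-sample map is exact and linear: `Y = A' X`. Training
#' columns reproduce their training embedding.
#'
#' @param model an [fit_lpp()] object.
#' @param X d x m' matrix (same ambient dimensionality as the fit).
#' @return l x m' matrix of embedded coordinates.
#' @export
lpp_transform <- function(model, X) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (nrow(X) != model$d) {
    abort(sprintf("ambient dimensionality mismatch: model d = %d, data d = %d",
                  model$d, nrow(X)))
  }
  t(model$A) %*% X
}

#' @export
predict.lpp <- function(object, newdata, ...) lpp_transform(object, newdata)

#' @export
print.lpp <- function(x, ...) {
  cat(sprintf("<lpp> %d -> %d locality preserving projection (m = %d)\n",
              x$d, x$l, x$m))
  cat("  eigenvalues:", format(head(x$eigenvalues, 5), digits = 4),
      if (x$l > 5) "..." else "", "\n")
  invisible(x)
}

#' Serialize / restore an embedding model as JSON
#'
#' @param model an `lpp` object.
#' @param path file path for the JSON container.
#' @return `path` invisibly; `read_lpp()` returns the restored model.
#' @export
write_lpp <- function(model, path) {
  obj <- list(
    A = model$A, eigenvalues = model$eigenvalues, l = model$l, d = model$d,
    m = model$m,
    graph = list(n_neighbors = model$graph$n_neighbors,
                 weight_mode = model$graph$weight_mode,
                 heat_t = model$graph$heat_t)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lpp
#' @export
read_lpp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(A = matrix(obj$A, nrow = obj$d), eigenvalues = obj$eigenvalues,
         l = obj$l, d = obj$d, m = obj$m,
         graph = graph_params(obj$graph$n_neighbors, obj$graph$weight_mode,
                              obj$graph$heat_t)),
    class = "lpp"
  )
}
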