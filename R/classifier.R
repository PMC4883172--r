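#' Class-weighted misclassification penalties
#'
#' The candidate set is heavily unbalanced (a handful of true spikes
#' against thousands of sharp transients) and too small to balance by
#' subsampling, so each class gets its own penalty with
#' `C_pos / C_neg = n_neg / n_pos` (the inverse ratio of the training
#' class sizes). The returned pair is normalized so that the average
#' penalty per training sample equals `c_base`.
#'
#' @param n_pos,n_neg training class sizes (>= 1).
#' @param c_base overall penalty scale (default 1).
#' @return Named numeric vector `c(pos = C1, neg = C2)`.
#' @export
class_penalties <- function(n_pos, n_neg, c_base = 1) {
  if (n_pos < 1 || n_neg < 1) abort("both classes must be non-empty")
  n <- n_pos + n_neg
  c(pos = c_base * n / (2 * n_pos), neg = c_base * n / (2 * n_neg))
}

# within-radius fraction over all training pairs
pair_fraction <- function(dvec, radius) mean(dvec <= radius)

#' Calibrate the RBF kernel width to the embedding dimensionality
#'
#' The kernel width follows `gamma = 1 / (k * l * log(l))^2` with natural
#' log, where the constant `k` is solved (by bisection, the fraction is
#' monotone in `k`) so that the fraction of training pairs whose distance
#' falls within one kernel radius `1/sqrt(gamma)` is approximately
#' `kernel_fraction`. Requires `l >= 2`: the formula degenerates at
#' `l = 1` (`log 1 = 0`).
#'
#' @param Y l x m matrix of embedded training data.
#' @param l embedding dimensionality (defaults to `nrow(Y)`).
#' @param kernel_fraction target within-radius pair fraction
#'   (default 0.20).
#' @param log_base base of the log in the width formula; `exp(1)`
#'   (default) or 10.
#' @param tol acceptable deviation of the achieved fraction.
#' @return List with `gamma`, `k_const`, `fraction` (achieved), `radius`.
#' @export
calibrate_gamma <- function(Y, l = nrow(Y), kernel_fraction = 0.20,
                            log_base = exp(1), tol = 0.01) {
  if (l < 2) abort("gamma formula is undefined for l < 2 (log(l) vanishes)")
  m <- ncol(Y)
  if (m < 10) abort("need at least 10 training points to calibrate gamma")
  dvec <- as.numeric(dist(t(Y)))
  if (all(dvec == 0)) abort("all embedded points coincide; kernel fraction is degenerate")
  denom <- l * log(l, base = log_base)
  # radius = k * l * log(l); bracket k so the fraction straddles the target
  lo <- .Machine$double.eps
  hi <- max(dvec) / denom * 2
  f <- function(k) pair_fraction(dvec, k * denom)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    fr <- f(mid)
    if (abs(fr - kernel_fraction) <= tol / 10) break
    if (fr < kernel_fraction) lo <- mid else hi <- mid
  }
  # discrete pair counts can make the target unattainable exactly;
  # return whichever bracket endpoint comes closer
  cand <- c(lo, mid, hi)
  k_const <- cand[which.min(abs(vapply(cand, f, 0) - kernel_fraction))]
  fraction <- f(k_const)
  if (abs(fraction - kernel_fraction) > max(tol, 1 / length(dvec))) {
    warn(sprintf("achieved kernel fraction %.3f misses target %.2f",
                 fraction, kernel_fraction))
  }
  gamma <- 1 / (k_const * denom)^2
  list(gamma = gamma, k_const = k_const, fraction = fraction,
       radius = k_const * denom)
}

#' Train the stage-2 spike classifier
#'
#' Class-weighted support vector machine with Gaussian radial basis
#' kernel on the embedded candidates. The penalty ratio follows
#' [class_penalties()]; the kernel width, unless given, follows
#' [calibrate_gamma()]. Inputs are used unscaled — the embedding already
#' fixes the geometry the kernel width was calibrated on.
#'
#' @param Y l x m matrix of embedded training points.
#' @param labels factor or character, `"spike"` / `"non_spike"`, one per
#'   column of `Y`.
#' @param gamma kernel width; `NULL` to calibrate from `Y`.
#' @param c_base penalty scale.
#' @param kernel_fraction,log_base passed to [calibrate_gamma()] when
#'   `gamma` is `NULL`.
#' @return Object of class `spike_svm`: the fitted svm plus the
#'   calibration metadata (`gamma`, `k_const`, `penalties`, `l`).
#' @export
train_classifier <- function(Y, labels, gamma = NULL, c_base = 1,
                             kernel_fraction = 0.20, log_base = exp(1)) {
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1)
  labels <- factor(as.character(labels), levels = c("spike", "non_spike"))
  if (anyNA(labels)) abort("labels must be 'spike' or 'non_spike'")
  if (length(labels) != ncol(Y)) abort("one label per column of Y is required")
  n_pos <- sum(labels == "spike")
  n_neg <- sum(labels == "non_spike")
  if (n_pos == 0 || n_neg == 0) abort("training needs both classes present")
  cal <- NULL
  if (is.null(gamma)) {
    cal <- calibrate_gamma(Y, l = nrow(Y), kernel_fraction = kernel_fraction,
                           log_base = log_base)
    gamma <- cal$gamma
  }
  pen <- class_penalties(n_pos, n_neg, c_base)
  fit <- e1071::svm(
    x = t(Y), y = labels, scale = FALSE, kernel = "radial",
    gamma = gamma, cost = 1,
    class.weights = c(spike = unname(pen["pos"]), non_spike = unname(pen["neg"]))
  )
  structure(
    list(fit = fit, gamma = gamma, k_const = if (is.null(cal)) NA_real_ else cal$k_const,
         kernel_fraction = if (is.null(cal)) NA_real_ else cal$fraction,
         penalties = pen, l = nrow(Y), n_pos = n_pos, n_neg = n_neg),
    class = "spike_svm"
  )
}

#' Classify embedded candidates
#'
#' @param object a `spike_svm` model.
#' @param newdata l x m' matrix of embedded points (or an `lpp`-shaped
#'   output of [lpp_transform()]).
#' @param ... unused.
#' @return Tibble with columns `label` (factor spike/non_spike) and
#'   `score` (real margin, positive for spike).
#' @export
predict.spike_svm <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = object$l)
  if (nrow(newdata) != object$l) {
    abort(sprintf("dimensionality mismatch: model l = %d, data l = %d",
                  object$l, nrow(newdata)))
  }
  if (ncol(newdata) == 0) {
    return(tibble::tibble(
      label = factor(character(), levels = c("spike", "non_spike")),
      score = numeric()
    ))
  }
  pr <- predict(object$fit, t(newdata), decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  score <- as.numeric(dv[, 1])
  # libsvm signs the margin toward the first class named in the column
  if (!grepl("^spike/", colnames(dv)[1])) score <- -score
  tibble::tibble(
    label = factor(as.character(pr), levels = c("spike", "non_spike")),
    score = score
  )
}

#' @export
print.spike_svm <- function(x, ...) {
  cat(sprintf(
    "<spike_svm> RBF weighted SVM: l = %d, gamma = %.4g, C(pos)/C(neg) = %.3g (n = %d/%d)\n",
    x$l, x$gamma, x$penalties["pos"] / x$penalties["neg"], x$n_pos, x$n_neg))
  invisible(x)
}
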