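#' Tidiers for fitted eegspike objects
#'
#' Broom-style `tidy()`/`glance()` methods: `tidy()` returns one row per
#' component/fold/pair, `glance()` a one-row model summary.
#'
#' @param x a fitted object.
#' @param ... unused.
#' @name eegspike-tidiers
NULL

#' @rdname eegspike-tidiers
#' @export
tidy.lpp <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$l),
    eigenvalue = x$eigenvalues,
    vector_norm = sqrt(colSums(x$A^2))
  )
}

#' @rdname eegspike-tidiers
#' @export
glance.lpp <- function(x, ...) {
  tibble::tibble(
    d = x$d, l = x$l, m = x$m,
    n_neighbors = x$graph$n_neighbors,
    weight_mode = x$graph$weight_mode,
    heat_t = x$graph$heat_t %||% NA_real_
  )
}

#' @rdname eegspike-tidiers
#' @export
glance.spike_svm <- function(x, ...) {
  tibble::tibble(
    l = x$l, gamma = x$gamma, k_const = x$k_const,
    kernel_fraction = x$kernel_fraction,
    c_pos = unname(x$penalties["pos"]), c_neg = unname(x$penalties["neg"]),
    n_pos = x$n_pos, n_neg = x$n_neg,
    n_support = x$fit$tot.nSV
  )
}

#' @rdname eegspike-tidiers
#' @export
tidy.spike_cv <- function(x, ...) x$fold_metrics

#' @rdname eegspike-tidiers
#' @export
glance.spike_cv <- function(x, ...) x$metrics

#' @rdname eegspike-tidiers
#' @export
tidy.match_result <- function(x, ...) x$pairs

#' @rdname eegspike-tidiers
#' @export
glance.match_result <- function(x, ...) {
  detection_metrics(x)
}

#' @rdname eegspike-tidiers
#' @export
glance.spike_model <- function(x, ...) {
  md <- x$metadata
  tibble::tibble(
    d = md$d, l = md$l, gamma = md$gamma, k_const = md$k_const,
    n_pos = md$n_pos, n_neg = md$n_neg, mode = md$mode, seed = md$seed
  )
}
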