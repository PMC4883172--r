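#' Realign markers onto the nearest negative peak
#'
#' Manual markers are imprecise; each marker is shifted to the largest
#' negative deflection (signal minimum) within `radius` ms of its
#' original position, matching how expert markings are corrected before
#' scoring. Ties take the earliest sample.
#'
#' @param ann annotation tibble (columns `time`, optional `channel`).
#' @param x numeric analysis signal, or single-channel
#'   [eeg_recording()].
#' @param rate sampling rate, Hz (taken from the recording if given).
#' @param radius search neighbourhood, ms (default 50, the detection
#'   latency).
#' @return The annotation tibble with `time` replaced by the realigned
#'   times (sorted).
#' @export
realign_markers <- function(ann, x, rate = NULL, radius = 50) {
  if (inherits(x, "eeg_recording")) {
    rate <- x$rate
    x <- as.numeric(x$samples[, 1])
  }
  if (is.null(rate)) abort("`rate` is required for a bare signal")
  n <- length(x)
  r <- round(radius / 1000 * rate)
  new_time <- vapply(ann$time, function(t) {
    i <- round(t * rate) + 1L
    if (i < 1 || i > n) abort(sprintf("marker at %.3f s lies outside the signal", t))
    lo <- max(1L, i - r); hi <- min(n, i + r)
    seg <- x[lo:hi]
    (lo + which.min(seg) - 2L) / rate      # which.min takes the first tie
  }, 0)
  out <- ann
  out$time <- new_time
  dplyr::arrange(out, .data$time)
}

#' Match detections to expert markers within a latency window
#'
#' Greedy one-to-one matching: all detection-marker pairs within
#' `latency` ms are considered in order of increasing |time difference|
#' (ties: earlier detection, then earlier marker), and each event is
#' used at most once. Unmatched detections are false positives,
#' unmatched markers false negatives.
#'
#' @param detections numeric detection times, seconds, sorted.
#' @param markers numeric marker times, seconds, sorted.
#' @param latency matching window, ms (default 50).
#' @return A list of class `match_result`: counts `tp`, `fp`, `fn`, the
#'   `pairs` tibble (`detection`, `marker`, `delta`), and the unmatched
#'   `fp_times` / `fn_times`.
#' @export
match_events <- function(detections, markers, latency = 50) {
  lat_s <- latency / 1000
  nd <- length(detections); nm <- length(markers)
  pairs <- NULL
  if (nd && nm) {
    dd <- abs(outer(detections, markers, "-"))
    ok <- which(dd <= lat_s + 1e-12, arr.ind = TRUE)
    if (nrow(ok)) {
      ord <- order(dd[ok], detections[ok[, 1]], markers[ok[, 2]])
      ok <- ok[ord, , drop = FALSE]
      used_d <- logical(nd); used_m <- logical(nm)
      keep <- logical(nrow(ok))
      for (r in seq_len(nrow(ok))) {
        i <- ok[r, 1]; j <- ok[r, 2]
        if (!used_d[i] && !used_m[j]) {
          used_d[i] <- TRUE; used_m[j] <- TRUE; keep[r] <- TRUE
        }
      }
      ok <- ok[keep, , drop = FALSE]
      pairs <- tibble::tibble(
        detection = detections[ok[, 1]],
        marker = markers[ok[, 2]],
        delta = detections[ok[, 1]] - markers[ok[, 2]]
      )
    }
  }
  if (is.null(pairs)) {
    pairs <- tibble::tibble(detection = numeric(), marker = numeric(),
                            delta = numeric())
  }
  structure(
    list(
      tp = nrow(pairs),
      fp = nd - nrow(pairs),
      fn = nm - nrow(pairs),
      pairs = pairs,
      fp_times = setdiff(detections, pairs$detection),
      fn_times = setdiff(markers, pairs$marker),
      latency = latency
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FP %d, FN %d (latency %g ms)\n",
              x$tp, x$fp, x$fn, x$latency))
  invisible(x)
}

#' Detection performance metrics
#'
#' Sensitivity `TP/(TP+FN)`, selectivity (precision) `TP/(TP+FP)`,
#' false positives per minute, and the F-score
#' `2*TP / (2*TP + FP + FN)` — the harmonic mean of sensitivity and
#' precision. Empty ratios (0/0) are reported as 0 by convention.
#'
#' @param tp,fp,fn confusion counts, or a `match_result` as `tp`.
#' @param duration_min recording length in minutes (for FP/min; `NA`
#'   allowed).
#' @return One-row tibble: `tp`, `fp`, `fn`, `sensitivity`,
#'   `selectivity`, `fp_per_min`, `fscore`, `duration_min`.
#' @export
detection_metrics <- function(tp, fp = NULL, fn = NULL, duration_min = NA) {
  if (inherits(tp, "match_result")) {
    m <- tp
    tp <- m$tp; fp <- m$fp; fn <- m$fn
  }
  rat <- function(num, den) if (den > 0) num / den else 0
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    sensitivity = rat(tp, tp + fn),
    selectivity = rat(tp, tp + fp),
    fp_per_min = if (is.na(duration_min)) NA_real_ else rat(fp, duration_min),
    fscore = rat(2 * tp, 2 * tp + fp + fn),
    duration_min = duration_min
  )
}

#' Label stage-1 candidates against expert markers
#'
#' A candidate is a true spike iff its vertex lies within the detection
#' latency of a (realigned) marker; every other detected transient is a
#' nonspecific sharp transient and forms the negative class.
#'
#' @param candidates a `spike_candidates` tibble.
#' @param markers numeric marker times (s), or an annotation tibble.
#' @param latency ms (default 50).
#' @return `candidates` with `label` filled in (`spike` / `non_spike`).
#' @export
label_candidates <- function(candidates, markers, latency = 50) {
  if (is.data.frame(markers)) markers <- markers$time
  lab <- rep("non_spike", nrow(candidates))
  if (length(markers) && nrow(candidates)) {
    dd <- abs(outer(candidates$peak_time, markers, "-"))
    lab[apply(dd, 1, min) <= latency / 1000 + 1e-12] <- "spike"
  }
  candidates$label <- factor(lab, levels = c("spike", "non_spike", "unknown"))
  candidates
}

# stratified fold ids, deterministic given the RNG state
stratified_folds <- function(labels, folds) {
  id <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    id[ix] <- sample(rep_len(seq_len(folds), length(ix)))
  }
  id
}

#' Ten-fold cross-validation of the refinement stage
#'
#' The rule-based stage 1 needs no fitting, so cross-validation covers
#' stage 2 only: in each fold the embedding and the classifier are fit
#' on the training folds alone (inductive mode) and applied to the
#' held-out candidates; confusion counts are pooled over folds.
#' Stratified folds keep the rare positive class represented everywhere.
#'
#' @param candidates labeled `spike_candidates` (only `passed` rows are
#'   used; labels must be spike/non_spike).
#' @param l embedding dimensionality, or `"mle"` to estimate per fold.
#' @param graph a [graph_params()].
#' @param folds number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param c_base,kernel_fraction,log_base classifier settings.
#' @param duration_min recording length for FP/min (optional).
#' @param transductive if `TRUE`, the embedding is learnt from training
#'   and held-out waveforms jointly (labels of the held-out fold are
#'   still never used).
#' @return List of class `spike_cv`: `metrics` (pooled, one row),
#'   `fold_metrics` (per fold), `mean_metrics` (per-fold averages),
#'   `predictions` tibble, and the per-fold chosen `l`.
#' @export
crossval_stage2 <- function(candidates, l = "mle", graph = graph_params(),
                            folds = 10, seed = 1, c_base = 1,
                            kernel_fraction = 0.20, log_base = exp(1),
                            duration_min = NA, transductive = FALSE) {
  cand <- candidates[candidates$passed & candidates$label != "unknown", ]
  labs <- droplevels(factor(cand$label, levels = c("spike", "non_spike")))
  if (nlevels(labs) < 2) abort("cross-validation needs both classes among passing candidates")
  if (min(table(labs)) < folds) {
    abort(sprintf("need at least %d candidates of each class for %d folds",
                  folds, folds))
  }
  X <- candidate_matrix(cand)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_id <- stratified_folds(as.character(labs), folds)

  preds <- vector("list", folds)
  fold_rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    X_tr <- X[, tr, drop = FALSE]
    X_te <- X[, !tr, drop = FALSE]
    l_f <- if (identical(l, "mle")) estimate_intrinsic_dim(X_tr) else as.integer(l)
    l_f <- max(2L, min(l_f, nrow(X)))
    emb <- if (transductive) fit_lpp(cbind(X_tr, X_te), l_f, graph) else fit_lpp(X_tr, l_f, graph)
    Y_tr <- lpp_transform(emb, X_tr)
    Y_te <- lpp_transform(emb, X_te)
    mod <- train_classifier(Y_tr, labs[tr], c_base = c_base,
                            kernel_fraction = kernel_fraction,
                            log_base = log_base)
    pr <- predict(mod, Y_te)
    truth <- labs[!tr]
    preds[[f]] <- tibble::tibble(
      fold = f, peak_time = cand$peak_time[!tr],
      truth = truth, label = pr$label, score = pr$score
    )
    fold_rows[[f]] <- tibble::tibble(
      fold = f, l = l_f, gamma = mod$gamma,
      tp = sum(pr$label == "spike" & truth == "spike"),
      fp = sum(pr$label == "spike" & truth == "non_spike"),
      fn = sum(pr$label == "non_spike" & truth == "spike"),
      tn = sum(pr$label == "non_spike" & truth == "non_spike")
    )
  }
  fold_tab <- purrr::list_rbind(fold_rows)
  pooled <- detection_metrics(sum(fold_tab$tp), sum(fold_tab$fp),
                              sum(fold_tab$fn), duration_min)
  per_fold <- dplyr::bind_cols(
    fold_tab[, c("fold", "l", "gamma", "tp", "fp", "fn", "tn")],
    purrr::pmap(fold_tab[, c("tp", "fp", "fn")],
                function(tp, fp, fn) {
                  detection_metrics(tp, fp, fn)[, c("sensitivity", "selectivity", "fscore")]
                }) |> purrr::list_rbind()
  )
  structure(
    list(
      metrics = pooled,
      fold_metrics = per_fold,
      mean_metrics = tibble::tibble(
        sensitivity = mean(per_fold$sensitivity),
        selectivity = mean(per_fold$selectivity),
        fscore = mean(per_fold$fscore)
      ),
      predictions = purrr::list_rbind(preds),
      folds = folds, seed = seed
    ),
    class = "spike_cv"
  )
}

#' @export
print.spike_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<spike_cv> %d-fold pooled: TP %d FP %d FN %d | sens %.3f sel %.3f F %.3f\n",
    x$folds, m$tp, m$fp, m$fn, m$sensitivity, m$selectivity, m$fscore))
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
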