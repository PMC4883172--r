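#' Pipeline configuration
#'
#' Nested configuration for the full two-stage pipeline, loadable from
#' YAML. Unknown keys are rejected so typos cannot silently fall back
#' to defaults.
#'
#' @param preprocess,detector,manifold,classifier,evaluation,synthetic
#'   named lists overriding the per-module defaults.
#' @param seed global seed; every stochastic step derives from it.
#' @param mode `"inductive"` (default; the embedding is learnt from
#'   training data only, keeping cross-validation leak-free) or
#'   `"transductive"` (train and test waveforms jointly define the
#'   neighbourhood graph).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = list(), detector = list(),
                            manifold = list(), classifier = list(),
                            evaluation = list(), synthetic = list(),
                            seed = 1, mode = c("inductive", "transductive")) {
  mode <- match.arg(mode)
  defaults <- list(
    preprocess = list(target_rate = 100, notch_freq = 50, notch_q = 30,
                      baseline_segment = 1.0, baseline_overlap = 0.5,
                      smooth_window = 5, baseline = TRUE),
    detector = list(a1_min = 20, a1_max = 500, a2_min = 50, a2_max = 500,
                    d1_max = 200, d2_max = 150, min_separation = 100,
                    min_prominence = 10, pre = 100, post = 200,
                    invert = FALSE),
    manifold = list(l = "mle", n_neighbors = 7, weight_mode = "heat",
                    heat_t = NULL, k_min = 6, k_max = 12),
    classifier = list(c_base = 1, kernel_fraction = 0.20, log_base = "e"),
    evaluation = list(latency = 50, realign = TRUE, folds = 10),
    synthetic = list()
  )
  user <- list(preprocess = preprocess, detector = detector,
               manifold = manifold, classifier = classifier,
               evaluation = evaluation, synthetic = synthetic)
  out <- defaults
  for (blk in names(user)) {
    extra <- setdiff(names(user[[blk]]), names(defaults[[blk]]))
    if (blk != "synthetic" && length(extra)) {
      abort(paste0("unknown key(s) in `", blk, "`: ", paste(extra, collapse = ", ")))
    }
    out[[blk]] <- modifyList(defaults[[blk]], user[[blk]], keep.null = TRUE)
  }
  out$seed <- seed
  out$mode <- mode
  structure(out, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with any subset of the configuration blocks.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y <- y %||% list()
  known <- c("preprocess", "detector", "manifold", "classifier",
             "evaluation", "synthetic", "seed", "mode")
  extra <- setdiff(names(y), known)
  if (length(extra)) {
    abort(paste0("unknown top-level config key(s): ", paste(extra, collapse = ", ")))
  }
  pipeline_config(
    preprocess = y$preprocess %||% list(),
    detector = y$detector %||% list(),
    manifold = y$manifold %||% list(),
    classifier = y$classifier %||% list(),
    evaluation = y$evaluation %||% list(),
    synthetic = y$synthetic %||% list(),
    seed = y$seed %||% 1,
    mode = y$mode %||% "inductive"
  )
}

cfg_log_base <- function(classifier) {
  if (identical(classifier$log_base, "10") || identical(classifier$log_base, 10)) 10 else exp(1)
}

cfg_preprocess <- function(cfg) {
  p <- cfg$preprocess
  preprocess_config(target_rate = p$target_rate, notch_freq = p$notch_freq,
                    notch_q = p$notch_q, baseline_segment = p$baseline_segment,
                    baseline_overlap = p$baseline_overlap,
                    smooth_window = p$smooth_window, baseline = p$baseline)
}

cfg_thresholds <- function(cfg) {
  d <- cfg$detector
  spike_thresholds(d$a1_min, d$a1_max, d$a2_min, d$a2_max, d$d1_max, d$d2_max)
}

cfg_graph <- function(cfg) {
  m <- cfg$manifold
  graph_params(m$n_neighbors, m$weight_mode, m$heat_t)
}

#' Stage-1 detection on a recording
#'
#' Preprocesses the recording (optionally inverting the trace for
#' positive-going montages) and runs the mimetic detector.
#'
#' @param rec an [eeg_recording()].
#' @param channels channels averaged into the analysis trace.
#' @param cfg a [pipeline_config()].
#' @return A `spike_candidates` tibble (see [detect_candidates()]).
#' @export
run_detect <- function(rec, channels = rec$labels, cfg = pipeline_config()) {
  clean <- preprocess(rec, channels, cfg_preprocess(cfg))
  if (isTRUE(cfg$detector$invert)) clean$samples <- -clean$samples
  d <- cfg$detector
  detect_candidates(clean, thresholds = cfg_thresholds(cfg),
                    min_separation = d$min_separation,
                    min_prominence = d$min_prominence,
                    pre = d$pre, post = d$post)
}

#' Train the stage-2 models from a recording and expert markers
#'
#' Runs stage 1, labels the passing candidates by the latency rule
#' (after optional marker realignment onto the analysis trace),
#' estimates the intrinsic dimensionality (unless fixed), fits the
#' locality preserving projection and the class-weighted classifier.
#'
#' @param rec an [eeg_recording()].
#' @param annotations marker tibble (from [read_annotations()]) or
#'   numeric times.
#' @param channels analysis channels.
#' @param cfg a [pipeline_config()].
#' @return Object of class `spike_model`: `embedding` (lpp),
#'   `classifier` (spike_svm), `candidates` (labeled stage-1 table) and
#'   a `metadata` list recording every resolved convention (l, gamma,
#'   k, penalties, mode, seed).
#' @export
run_train <- function(rec, annotations, channels = rec$labels,
                      cfg = pipeline_config()) {
  clean <- preprocess(rec, channels, cfg_preprocess(cfg))
  if (isTRUE(cfg$detector$invert)) clean$samples <- -clean$samples
  d <- cfg$detector
  cand <- detect_candidates(clean, thresholds = cfg_thresholds(cfg),
                            min_separation = d$min_separation,
                            min_prominence = d$min_prominence,
                            pre = d$pre, post = d$post)
  if (is.data.frame(annotations)) ann <- annotations else ann <- tibble::tibble(time = annotations)
  ev <- cfg$evaluation
  if (isTRUE(ev$realign)) ann <- realign_markers(ann, clean, radius = ev$latency)
  cand <- label_candidates(cand, ann, latency = ev$latency)
  train <- cand[cand$passed, ]
  if (!sum(train$label == "spike")) abort("no positive candidates to train on")
  X <- candidate_matrix(train)
  m <- cfg$manifold
  l <- if (identical(m$l, "mle")) {
    estimate_intrinsic_dim(X, m$k_min, m$k_max)
  } else as.integer(m$l)
  l <- max(2L, min(l, nrow(X)))
  emb <- fit_lpp(X, l, cfg_graph(cfg))
  Y <- lpp_transform(emb, X)
  clf <- train_classifier(Y, droplevels(train$label),
                          c_base = cfg$classifier$c_base,
                          kernel_fraction = cfg$classifier$kernel_fraction,
                          log_base = cfg_log_base(cfg$classifier))
  structure(
    list(
      embedding = emb, classifier = clf, candidates = cand,
      metadata = list(
        l = l, d = nrow(X), gamma = clf$gamma, k_const = clf$k_const,
        kernel_fraction = clf$kernel_fraction,
        penalties = as.list(clf$penalties),
        n_pos = clf$n_pos, n_neg = clf$n_neg,
        mode = cfg$mode, seed = cfg$seed,
        log_base = cfg$classifier$log_base,
        latency = ev$latency,
        package_version = as.character(utils::packageVersion("eegspike"))
      )
    ),
    class = "spike_model"
  )
}

#' @export
print.spike_model <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<spike_model> d = %d -> l = %d, gamma = %.4g, n = %d/%d (pos/neg)\n",
              md$d, md$l, md$gamma, md$n_pos, md$n_neg))
  invisible(x)
}

#' Detect spikes on a recording with trained models
#'
#' Stage 1 on the (preprocessed) recording, embedding of the passing
#' candidates by the exact linear out-of-sample map, classification,
#' and — when markers are supplied — latency-windowed scoring.
#'
#' @param rec an [eeg_recording()].
#' @param model a `spike_model` from [run_train()].
#' @param annotations optional markers for scoring.
#' @param channels analysis channels.
#' @param cfg a [pipeline_config()].
#' @return List of class `spike_detection`: `detections` tibble
#'   (`peak_time`, `score`, features), `candidates` (all stage-1 rows
#'   with predictions), and, with annotations, `match` and `metrics`.
#' @export
run_predict <- function(rec, model, annotations = NULL,
                        channels = rec$labels, cfg = pipeline_config()) {
  clean <- preprocess(rec, channels, cfg_preprocess(cfg))
  if (isTRUE(cfg$detector$invert)) clean$samples <- -clean$samples
  d <- cfg$detector
  cand <- detect_candidates(clean, thresholds = cfg_thresholds(cfg),
                            min_separation = d$min_separation,
                            min_prominence = d$min_prominence,
                            pre = d$pre, post = d$post)
  keep <- cand[cand$passed, ]
  if (nrow(keep)) {
    clf <- model$classifier
    if (identical(cfg$mode, "transductive")) {
      # re-learn the projection from training and new waveforms jointly
      # (the literal training/testing diagram); labels of the new data
      # are never used
      if (is.null(model$candidates)) {
        abort("transductive mode needs a model carrying its training candidates")
      }
      tr <- model$candidates[model$candidates$passed &
                               model$candidates$label != "unknown", ]
      X_tr <- candidate_matrix(tr)
      X_new <- candidate_matrix(keep)
      emb <- fit_lpp(cbind(X_tr, X_new), model$embedding$l,
                     model$embedding$graph)
      clf <- train_classifier(lpp_transform(emb, X_tr), droplevels(tr$label),
                              gamma = NULL,
                              c_base = cfg$classifier$c_base,
                              kernel_fraction = cfg$classifier$kernel_fraction,
                              log_base = cfg_log_base(cfg$classifier))
      Y <- lpp_transform(emb, X_new)
    } else {
      Y <- lpp_transform(model$embedding, candidate_matrix(keep))
    }
    pr <- predict(clf, Y)
    keep$predicted <- pr$label
    keep$score <- pr$score
  } else {
    keep$predicted <- factor(character(), levels = c("spike", "non_spike"))
    keep$score <- numeric()
  }
  detections <- keep[keep$predicted == "spike",
                     c("peak_time", "score", "A1", "A2", "D1", "D2")]
  out <- list(detections = detections, candidates = keep,
              duration_min = attr(cand, "duration") / 60)
  if (!is.null(annotations)) {
    ann <- if (is.data.frame(annotations)) annotations else tibble::tibble(time = annotations)
    ev <- cfg$evaluation
    if (isTRUE(ev$realign)) ann <- realign_markers(ann, clean, radius = ev$latency)
    mt <- match_events(detections$peak_time, sort(ann$time), latency = ev$latency)
    out$match <- mt
    out$metrics <- detection_metrics(mt, duration_min = out$duration_min)
  }
  structure(out, class = "spike_detection")
}

#' @export
print.spike_detection <- function(x, ...) {
  cat(sprintf("<spike_detection> %d detection(s) over %.1f min\n",
              nrow(x$detections), x$duration_min))
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat(sprintf("  sens %.3f sel %.3f FP/min %.3f F %.3f\n",
                m$sensitivity, m$selectivity, m$fp_per_min, m$fscore))
  }
  invisible(x)
}

#' Persist / restore a trained spike model
#'
#' The embedding is written as a portable JSON container
#' ([write_lpp()]); the classifier and metadata are stored alongside in
#' RDS.
#'
#' @param model a `spike_model`.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly; `read_spike_model()` returns the model.
#' @export
write_spike_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_lpp(model$embedding, file.path(dir, "embedding.json"))
  saveRDS(model$classifier, file.path(dir, "classifier.rds"))
  jsonlite::write_json(model$metadata, file.path(dir, "metadata.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_spike_model
#' @export
read_spike_model <- function(dir) {
  structure(
    list(
      embedding = read_lpp(file.path(dir, "embedding.json")),
      classifier = readRDS(file.path(dir, "classifier.rds")),
      candidates = NULL,
      metadata = jsonlite::read_json(file.path(dir, "metadata.json"),
                                     simplifyVector = TRUE)
    ),
    class = "spike_model"
  )
}
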