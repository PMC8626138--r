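#' Default pipeline configuration
#'
#' @param N maximum number of estimation pairs (default 5).
#' @param window_s,step_s band-power window and step in seconds.
#' @param baseline_s normalization baseline (first minute of a session).
#' @param floor_eps floor before the dB transform.
#' @param em_tol,em_max_iter EM stopping controls shared by both EM fits.
#' @param diagonal_cov constrain the combiner measurement covariance to
#'   be diagonal.
#' @return A named list of class `"seiztrack_config"`.
#' @export
default_config <- function(N = 5, window_s = 1, step_s = 1, baseline_s = 60,
                           floor_eps = 1e-6, em_tol = 1e-4,
                           em_max_iter = 200, diagonal_cov = FALSE) {
  structure(list(N = N, bands = default_bands(), window_s = window_s,
                 step_s = step_s, baseline_s = baseline_s,
                 floor_eps = floor_eps, em_tol = em_tol,
                 em_max_iter = em_max_iter, diagonal_cov = diagonal_cov),
            class = "seiztrack_config")
}

session_by_id <- function(sessions, id) {
  ids <- vapply(sessions, function(s) s$session_id, character(1))
  hit <- match(id, ids)
  if (is.na(hit)) stop("session not found: ", id)
  sessions[[hit]]
}

feature_sets <- function(rec, config) {
  extract_features(rec, bands = config$bands, window_s = config$window_s,
                   step_s = config$step_s, baseline_s = config$baseline_s,
                   floor_eps = config$floor_eps)
}

#' Fit the full seizure-tracking pipeline
#'
#' Runs the complete training procedure on one subject's sessions:
#' feature extraction on the training and validation sessions, greedy
#' wrapper selection of `N` (continuous, binary) feature pairs,
#' binarization LDAs for the selected binary features (fit on training +
#' validation), a mixed-filter EM per pair, fusion of the `N` filtered
#' state tracks by combiner EM plus square-root Kalman filter, and a
#' final 1-D cost-weighted LDA that binarizes the combined state. Errors
#' raised by a stage are tagged with that stage's name.
#'
#' @param sessions ordered list of [recording()] objects for one subject.
#' @param config a [default_config()].
#' @param split optional [split_sessions()] result; computed from
#'   `sessions` when `NULL`.
#' @return A fitted bundle of class `"seizure_model"` containing every
#'   fitted object and the config snapshot.
#' @export
fit_pipeline <- function(sessions, config = default_config(), split = NULL) {
  run <- function(stage, expr)
    tryCatch(expr, error = function(e) stop_stage(stage, e))

  split <- run("split", {
    if (is.null(split)) split <- split_sessions(sessions)
    if (length(split$validation) != 1L || !nzchar(split$validation))
      stop("split has no validation session")
    split
  })
  tr_rec <- run("split", session_by_id(sessions, split$train))
  va_rec <- run("split", session_by_id(sessions, split$validation))

  feats <- run("features", list(train = feature_sets(tr_rec, config),
                                val = feature_sets(va_rec, config)))
  lab_tr <- label_vector(tr_rec, config$step_s)
  lab_va <- label_vector(va_rec, config$step_s)

  sel <- run("select", wrapper_select(
    train = c(feats$train, list(labels = lab_tr)),
    val = c(feats$val, list(labels = lab_va)),
    N = config$N))

  lab_trval <- c(lab_tr, lab_va)
  p_chance <- run("chance", {
    p <- mean(lab_trval)
    if (p <= 0 || p >= 1)
      stop("train+validation labels must contain both classes")
    p
  })
  mu_bar <- mu_from_chance(p_chance)

  binarizers <- run("binarize", {
    out <- list()
    for (bid in unique(sel$pairs$bin_id)) {
      vals <- c(feats$train$bin[[bid]]$values, feats$val$bin[[bid]]$values)
      out[[bid]] <- binarize_feature(vals, lab_trval)$model
    }
    out
  })

  mixed <- run("mixed_em", lapply(seq_len(nrow(sel$pairs)), function(n) {
    cid <- sel$pairs$cont_id[n]; bid <- sel$pairs$bin_id[n]
    v <- c(feats$train$cont[[cid]]$values, feats$val$cont[[cid]]$values)
    bvals <- c(feats$train$bin[[bid]]$values, feats$val$bin[[bid]]$values)
    lam <- predict(binarizers[[bid]], matrix(bvals, ncol = 1))
    em_fit_mixed(v, lam, p_chance, tol = config$em_tol,
                 max_iter = config$em_max_iter)
  }))

  X <- run("combine", {
    do.call(rbind, lapply(mixed, function(f) f$track$x_filt))
  })
  comb <- run("combiner_em",
              em_fit_combiner(X, tol = config$em_tol,
                              max_iter = config$em_max_iter,
                              diagonal_cov = config$diagonal_cov))
  z_trval <- run("combine",
                 sqrt_kalman_filter(X, comb$params)$z_filt)
  final_lda <- run("final_lda", fit_lda(matrix(z_trval, ncol = 1), lab_trval))

  needed <- unique(sub("\\|.*$", "",
                       c(sel$pairs$cont_id, sel$pairs$bin_id)))
  structure(list(config = config, split = split, selection = sel,
                 binarizers = binarizers,
                 mixed = lapply(mixed, `[[`, "params"),
                 mixed_iters = vapply(mixed, `[[`, numeric(1), "n_iter"),
                 p_chance = p_chance, mu = mu_bar,
                 combiner = comb$params, final_lda = final_lda,
                 channels = needed),
            class = "seizure_model")
}

#' @export
print.seizure_model <- function(x, ...) {
  cat(sprintf("<seizure_model> %d estimation pair(s), p_chance=%.4f\n",
              nrow(x$selection$pairs), x$p_chance))
  print(x$selection)
  invisible(x)
}

#' Causal seizure-state tracking on a new session
#'
#' Forward-only inference with a fitted [fit_pipeline()] bundle: band
#' powers on the session (normalized against *this* session's first
#' minute), stored binarization LDAs, `N` causal mixed forward filters,
#' the square-root Kalman filter, and the final LDA. No smoother is used
#' and no future sample influences any output step. Metrics are computed
#' against the session's annotations when present.
#'
#' @param bundle a fitted `"seizure_model"`.
#' @param rec a [recording()] containing every channel the bundle's
#'   selected features need.
#' @return List with `combined` (a [sqrt_kalman_filter()] track), `pred`
#'   (0/1 series), `p_seizure` (`logistic(mu + z_k)`), `tracks` (the N
#'   [forward_filter()] outputs), and `metrics` (an [evaluate_binary()]
#'   result, or `NULL` without annotations).
#' @export
track <- function(bundle, rec) {
  missing <- setdiff(bundle$channels, rec$channel_labels)
  if (length(missing) > 0)
    stop("recording lacks required channel(s): ",
         paste(missing, collapse = ", "))
  config <- bundle$config
  feats <- extract_features(rec, bands = config$bands,
                            window_s = config$window_s,
                            step_s = config$step_s,
                            baseline_s = config$baseline_s,
                            floor_eps = config$floor_eps,
                            channels = bundle$channels)
  sel <- bundle$selection$pairs
  tracks <- lapply(seq_len(nrow(sel)), function(n) {
    v <- feats$cont[[sel$cont_id[n]]]$values
    bvals <- feats$bin[[sel$bin_id[n]]]$values
    lam <- predict(bundle$binarizers[[sel$bin_id[n]]],
                   matrix(bvals, ncol = 1))
    forward_filter(v, lam, bundle$mixed[[n]])
  })
  X <- do.call(rbind, lapply(tracks, `[[`, "x_filt"))
  combined <- sqrt_kalman_filter(X, bundle$combiner)
  pred <- predict(bundle$final_lda, matrix(combined$z_filt, ncol = 1))
  p_seizure <- logistic_prob(bundle$mu, combined$z_filt)
  metrics <- if (length(rec$seizure_intervals) > 0)
    evaluate_binary(pred, label_vector(rec, config$step_s)) else NULL
  list(combined = combined, pred = pred, p_seizure = p_seizure,
       tracks = tracks, metrics = metrics)
}

#' Confusion-matrix performance metrics
#'
#' Per-time-step accuracy, sensitivity (`TP/(TP+FN)`), specificity
#' (`TN/(TN+FP)`) and F1, with seizure as the positive class.
#'
#' @param pred,truth equal-length 0/1 series.
#' @return A list of class `"seizure_metrics"`.
#' @export
evaluate_binary <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  pred <- as.integer(pred); truth <- as.integer(truth)
  tp <- sum(pred == 1L & truth == 1L); fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L); fp <- sum(pred == 1L & truth == 0L)
  structure(list(
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    f1 = f1_score(pred, truth),
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn)),
    class = "seizure_metrics")
}

#' @export
print.seizure_metrics <- function(x, ...) {
  cat(sprintf(
    "<seizure_metrics> accuracy %.3f | sensitivity %.3f | specificity %.3f | F1 %.3f\n",
    x$accuracy, x$sensitivity, x$specificity, x$f1))
  invisible(x)
}
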