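#' F1 score of a binary prediction
#'
#' Harmonic mean of precision and recall, `2 p r / (p + r)`, with the
#' convention that the score is 0 when precision and recall are both
#' undefined or zero.
#'
#' @param pred,truth equal-length 0/1 vectors; seizure is the positive class.
#' @return A score in `[0, 1]`.
#' @export
f1_score <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  pred <- as.integer(pred); truth <- as.integer(truth)
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

#' Cost-weighted two-class linear discriminant
#'
#' Fisher discriminant `w = S_pooled^-1 (m1 - m0)` with the bias chosen
#' from the Gaussian equal-covariance decision rule including class priors
#' and a misclassification cost ratio: classify seizure (1) iff
#' `w'f - w'(m0 + m1)/2 + log(cost_ratio * n1/n0) > 0`.
#'
#' The default `cost_ratio = NULL` uses the duration-proportional cost —
#' cost(missed seizure)/cost(false alarm) equal to the non-seizure/seizure
#' duration ratio of the fitting data — under which the cost and prior
#' terms cancel exactly and the threshold sits at the midpoint between the
#' projected class means.
#'
#' @param features numeric matrix (steps x J) or vector (J = 1).
#' @param labels 0/1 vector; both classes must be present.
#' @param cost_ratio scalar cost(miss)/cost(false alarm), or `NULL` for
#'   the duration-proportional default.
#' @return An object of class `"lda_model"` with elements `weight`,
#'   `bias`, `cost_ratio`, `degenerate`.
#' @export
fit_lda <- function(features, labels, cost_ratio = NULL) {
  X <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(X) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n0 == 0L || n1 == 0L)
    stop("both classes must be present to fit an LDA")
  J <- ncol(X)
  m0 <- colMeans(X[labels == 0L, , drop = FALSE])
  m1 <- colMeans(X[labels == 1L, , drop = FALSE])
  c0 <- if (n0 > 1) stats::cov(X[labels == 0L, , drop = FALSE]) else matrix(0, J, J)
  c1 <- if (n1 > 1) stats::cov(X[labels == 1L, , drop = FALSE]) else matrix(0, J, J)
  S <- ((n0 - 1) * c0 + (n1 - 1) * c1) / max(n0 + n1 - 2, 1)

  tr <- sum(diag(S))
  if (tr < .Machine$double.eps) {
    warning("degenerate LDA fit: all features constant within classes")
    if (sum((m1 - m0)^2) < 1e-24)
      return(structure(list(weight = numeric(J), bias = -1,
                            cost_ratio = cost_ratio, degenerate = TRUE),
                       class = "lda_model"))
    S <- diag(1e-6, J)
    tr <- sum(diag(S))
  }
  w <- tryCatch(solve(S, m1 - m0), error = function(e) NULL)
  if (is.null(w) || !all(is.finite(w)) ||
      rcond(S) < .Machine$double.eps * 100) {
    warning("singular pooled covariance; applying ridge regularization")
    S <- S + diag(1e-6 * tr / J, J)
    w <- solve(S, m1 - m0)
  }
  log_odds <- if (is.null(cost_ratio)) 0 else log(cost_ratio * n1 / n0)
  bias <- -0.5 * sum(w * (m0 + m1)) + log_odds
  structure(list(weight = as.numeric(w), bias = bias,
                 cost_ratio = if (is.null(cost_ratio)) n0 / n1 else cost_ratio,
                 degenerate = FALSE),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d feature(s), bias %.4g, cost ratio %.4g%s\n",
              length(x$weight), x$bias, x$cost_ratio,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Apply a fitted LDA decision rule
#' @param object an [fit_lda()] model.
#' @param features matrix or vector of the same width the model was fit on.
#' @param ... unused.
#' @return Integer 0/1 decisions, `1` iff `w'f + bias > 0`.
#' @export
predict.lda_model <- function(object, features, ...) {
  X <- as.matrix(features)
  if (ncol(X) != length(object$weight))
    X <- matrix(X, ncol = length(object$weight))
  as.integer(drop(X %*% object$weight) + object$bias > 0)
}

#' Modified greedy wrapper feature selection
#'
#' Selects up to `N` (continuous, binary) feature pairs. At iteration
#' `n`, each remaining continuous candidate is evaluated by training an
#' LDA (duration-proportional cost) on the previously selected features
#' plus that candidate on the training set and scoring F1 on the
#' validation set; the arg-max joins the selected set, then the process
#' repeats over the binary-candidate pool. Binary candidates are
#' evaluated on their raw normalized values; binarization happens only
#' after selection (see [binarize_feature()]). Ties are broken toward the
#' lowest pool index (channel order, then band order).
#'
#' @param train,val lists with elements `cont` and `bin` (named lists of
#'   [feature_series()], same names in both sets) and `labels` (0/1).
#' @param N maximum number of pairs (default 5).
#' @return An object of class `"selection_result"`: `pairs` (data frame
#'   with `cont_id`, `bin_id`), `f1_trajectory` (validation F1 after each
#'   pair).
#' @export
wrapper_select <- function(train, val, N = 5) {
  stopifnot(length(train$cont) > 0, length(train$bin) > 0)
  if (length(unique(train$labels)) < 2 || length(unique(val$labels)) < 2)
    stop("train and validation labels must both contain both classes")

  sel_tr <- NULL; sel_va <- NULL
  cont_left <- names(train$cont); bin_left <- names(train$bin)
  pairs <- data.frame(cont_id = character(0), bin_id = character(0),
                      stringsAsFactors = FALSE)
  f1_traj <- numeric(0)

  pick <- function(cands, pool_tr, pool_va) {
    best <- -Inf; best_id <- NULL
    for (id in cands) {
      Xtr <- cbind(sel_tr, pool_tr[[id]]$values)
      Xva <- cbind(sel_va, pool_va[[id]]$values)
      model <- suppressWarnings(fit_lda(Xtr, train$labels))
      f1 <- f1_score(predict(model, Xva), val$labels)
      if (f1 > best) { best <- f1; best_id <- id }
    }
    list(id = best_id, f1 = best)
  }

  for (n in seq_len(N)) {
    if (length(cont_left) == 0 || length(bin_left) == 0) break
    pc <- pick(cont_left, train$cont, val$cont)
    sel_tr <- cbind(sel_tr, train$cont[[pc$id]]$values)
    sel_va <- cbind(sel_va, val$cont[[pc$id]]$values)
    cont_left <- setdiff(cont_left, pc$id)
    pb <- pick(bin_left, train$bin, val$bin)
    sel_tr <- cbind(sel_tr, train$bin[[pb$id]]$values)
    sel_va <- cbind(sel_va, val$bin[[pb$id]]$values)
    bin_left <- setdiff(bin_left, pb$id)
    pairs[n, ] <- c(pc$id, pb$id)
    f1_traj[n] <- pb$f1
  }
  structure(list(pairs = pairs, f1_trajectory = f1_traj),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d feature pair(s)\n", nrow(x$pairs)))
  for (i in seq_len(nrow(x$pairs)))
    cat(sprintf("  %d. cont %s + bin %s  (val F1 %.3f)\n", i,
                x$pairs$cont_id[i], x$pairs$bin_id[i], x$f1_trajectory[i]))
  invisible(x)
}

#' Binarize a selected binary-candidate feature
#'
#' Fits a single-feature LDA with duration-proportional misclassification
#' cost on the supplied (train + validation) data and returns both the
#' model and its 0/1 decision series on that data. A constant feature
#' yields a degenerate all-zero binarization with a warning.
#'
#' @param feature a [feature_series()] (or numeric vector).
#' @param labels 0/1 labels aligned with `feature`.
#' @return List with `series` (a `kind = "binary"` [feature_series()])
#'   and `model` (an [fit_lda()] model).
#' @export
binarize_feature <- function(feature, labels) {
  vals <- if (inherits(feature, "feature_series")) feature$values else as.numeric(feature)
  model <- fit_lda(matrix(vals, ncol = 1), labels)
  lam <- predict(model, matrix(vals, ncol = 1))
  series <- if (inherits(feature, "feature_series"))
    feature_series(lam, feature$channel, feature$band, "binary", feature$step_s)
  else feature_series(lam, "x", "x", "binary", 1)
  list(series = series, model = model)
}
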