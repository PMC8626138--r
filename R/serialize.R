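# Plain-text persistence: JSON for fitted parameters and models, CSV for
# time series. Serialization is deterministic given the fitted objects.

#' Save a fitted seizure model to JSON
#' @param bundle a `"seizure_model"` from [fit_pipeline()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_model <- function(bundle, path) {
  obj <- list(
    config = bundle$config[setdiff(names(bundle$config), "bands")],
    bands = bundle$config$bands,
    split = unclass(bundle$split),
    pairs = bundle$selection$pairs,
    f1_trajectory = bundle$selection$f1_trajectory,
    binarizers = lapply(bundle$binarizers, function(m)
      list(weight = m$weight, bias = m$bias, cost_ratio = m$cost_ratio)),
    mixed = lapply(bundle$mixed, unclass),
    p_chance = bundle$p_chance, mu = bundle$mu,
    combiner = list(A = bundle$combiner$A, B = bundle$combiner$B,
                    C = bundle$combiner$C,
                    var_omega = bundle$combiner$var_omega,
                    cov_nu = bundle$combiner$cov_nu),
    final_lda = list(weight = bundle$final_lda$weight,
                     bias = bundle$final_lda$bias,
                     cost_ratio = bundle$final_lda$cost_ratio),
    channels = bundle$channels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

as_lda <- function(x, degenerate = FALSE) {
  structure(list(weight = as.numeric(x$weight), bias = x$bias,
                 cost_ratio = x$cost_ratio, degenerate = degenerate),
            class = "lda_model")
}

#' Load a fitted seizure model from JSON
#' @param path JSON file written by [save_model()].
#' @return A `"seizure_model"` bundle usable with [track()].
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- do.call(default_config, obj$config[setdiff(names(obj$config),
                                                       c("bands"))])
  config$bands <- as.data.frame(obj$bands)
  comb <- combiner_params(obj$combiner$A, obj$combiner$B, obj$combiner$C,
                          obj$combiner$var_omega,
                          as.matrix(obj$combiner$cov_nu))
  structure(list(
    config = config,
    split = structure(obj$split, class = "session_split"),
    selection = structure(list(pairs = as.data.frame(obj$pairs),
                               f1_trajectory = obj$f1_trajectory),
                          class = "selection_result"),
    binarizers = lapply(obj$binarizers, as_lda),
    mixed = {
      mx <- obj$mixed
      if (is.data.frame(mx)) mx <- split(mx, seq_len(nrow(mx)))
      lapply(mx, function(m)
        mixed_params(m$rho, m$alpha, m$beta, m$var_eta, m$var_eps, m$mu))
    },
    p_chance = obj$p_chance, mu = obj$mu,
    combiner = comb,
    final_lda = as_lda(obj$final_lda),
    channels = obj$channels),
    class = "seizure_model")
}

#' Write a feature series as CSV plus JSON header sidecar
#' @param series a [feature_series()].
#' @param path CSV output path (`time_s,value`); metadata goes to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_series <- function(series, path) {
  t <- (seq_along(series$values) - 1) * series$step_s
  utils::write.csv(data.frame(time_s = t, value = series$values),
                   path, row.names = FALSE)
  jsonlite::write_json(list(channel = series$channel, band = series$band,
                            kind = series$kind, step_s = series$step_s),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature series written by [write_feature_series()]
#' @param path CSV path with a `<path>.json` sidecar.
#' @return A [feature_series()].
#' @export
read_feature_series <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  feature_series(df$value, meta$channel, meta$band, meta$kind, meta$step_s)
}

#' Write an estimation or combined track as CSV
#' @param trk an [forward_filter()] or [sqrt_kalman_filter()] result.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(trk, path) {
  df <- if (inherits(trk, "estimation_track"))
    data.frame(k = seq_along(trk$x_filt), x_pred = trk$x_pred,
               var_pred = trk$var_pred, x_filt = trk$x_filt,
               var_filt = trk$var_filt, p = trk$p)
  else
    data.frame(k = seq_along(trk$z_filt), z = trk$z_filt,
               var = trk$sqrt_cov^2)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
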