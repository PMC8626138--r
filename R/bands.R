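#' Default EEG frequency bands
#'
#' The four candidate bands: Delta (0.1-4 Hz), Theta (4-7 Hz), Alpha
#' (8-15 Hz) and Beta (16-31 Hz). Gamma (31+ Hz) is excluded from the
#' candidate pool because of its susceptibility to muscle artifact. Band
#' membership of an FFT bin is half-open, `f_lo <= f < f_hi`, so adjacent
#' printed edges never double-count a bin.
#'
#' @return A data frame with columns `name`, `f_lo`, `f_hi`.
#' @export
default_bands <- function() {
  data.frame(name = c("Delta", "Theta", "Alpha", "Beta"),
             f_lo = c(0.1, 4, 8, 16),
             f_hi = c(4, 7, 15, 31),
             stringsAsFactors = FALSE)
}

band_def <- function(name, f_lo, f_hi) {
  stopifnot(f_lo >= 0, f_lo < f_hi)
  list(name = name, f_lo = f_lo, f_hi = f_hi)
}

#' Band-power / dB / binary feature time series
#'
#' @param values numeric (or 0/1) vector of feature values.
#' @param channel bipolar channel label the feature came from.
#' @param band band name (e.g. `"Theta"`).
#' @param kind one of `"power"`, `"db"`, `"binary"`.
#' @param step_s seconds between consecutive steps.
#' @return An object of class `"feature_series"`.
#' @export
feature_series <- function(values, channel, band, kind = "power", step_s = 1) {
  kind <- match.arg(kind, c("power", "db", "binary"))
  values <- as.numeric(values)
  step_s <- as.numeric(step_s)
  if (kind == "power" && any(values < 0))
    stop("power features must be non-negative")
  if (kind == "binary" && !all(values %in% c(0, 1)))
    stop("binary features must take values in {0, 1}")
  structure(list(values = values, channel = channel, band = band,
                 kind = kind, step_s = step_s),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %s|%s [%s], %d steps @ %g s\n",
              x$channel, x$band, x$kind, length(x$values), x$step_s))
  invisible(x)
}

feature_id <- function(f) paste(f$channel, f$band, f$kind, sep = "|")

# FFT magnitudes-squared of trailing windows, summed over the one-sided
# bins whose frequency lies in [f_lo, f_hi). `win` is a samples x windows
# matrix; returns one power per column.
window_band_power <- function(win, fs, f_lo, f_hi) {
  L <- nrow(win)
  freqs <- (seq_len(L) - 1) * fs / L
  half <- freqs <= fs / 2
  sel <- which(half & freqs >= f_lo & freqs < f_hi)
  if (length(sel) == 0) return(numeric(ncol(win)))
  sp <- Mod(stats::mvfft(win))^2
  colSums(sp[sel, , drop = FALSE])
}

#' Sliding-window FFT band power
#'
#' At each step `k` (timestamp `k * step_s`, trailing window of the last
#' `window_s` seconds) the power is the sum of squared FFT magnitudes over
#' the one-sided bins whose frequency lies in `[f_lo, f_hi)`. Steps whose
#' trailing window would start before the recording are padded by
#' repeating the first full-window value, so the output always has
#' `floor(duration / step_s)` steps aligned with [label_vector()].
#'
#' @param rec a [recording()].
#' @param channel channel label present in `rec`.
#' @param band a row of [default_bands()] or `list(name, f_lo, f_hi)`.
#' @param window_s trailing window length in seconds (default 1).
#' @param step_s step between estimates in seconds; defaults to one sample
#'   (`1/fs`) for sample-by-sample estimation, and is typically set larger
#'   for speed.
#' @return A [feature_series()] with `kind = "power"`.
#' @export
band_power <- function(rec, channel, band, window_s = 1, step_s = 1 / rec$fs) {
  fs <- rec$fs
  if (band$f_hi > fs / 2)
    stop(sprintf("band %s upper edge %.1f Hz is above Nyquist (%.1f Hz)",
                 band$name, band$f_hi, fs / 2))
  L <- round(window_s * fs)
  if (L < 2) stop("window_s * fs must be at least 2")
  ch <- match(channel, rec$channel_labels)
  if (is.na(ch)) stop("unknown channel: ", channel)
  x <- rec$data[ch, ]
  n_steps <- floor(duration(rec) / step_s)
  ends <- pmin(floor(seq_len(n_steps) * step_s * fs), length(x))
  valid <- ends >= L
  if (!any(valid)) stop("recording shorter than one analysis window")
  win <- vapply(ends[valid], function(e) x[(e - L + 1):e], numeric(L))
  pw <- window_band_power(win, fs, band$f_lo, band$f_hi)
  out <- numeric(n_steps)
  out[valid] <- pw
  out[!valid] <- pw[1]
  feature_series(out, channel, band$name, "power", step_s)
}

#' Decibel transform of band power
#'
#' `10 * log10(r)`, with non-positive inputs floored at `floor_eps` so the
#' transform never errors on a normalized power that reaches zero.
#'
#' @param r numeric vector of powers (amplitude squared).
#' @param floor_eps floor applied before the log (default `1e-6`).
#' @return `10 * log10(pmax(r, floor_eps))`.
#' @export
to_db <- function(r, floor_eps = 1e-6) 10 * log10(pmax(r, floor_eps))

#' Min/max normalization against a session-initial baseline
#'
#' Rescales a feature series by the minimum and maximum observed during
#' the first `baseline_s` seconds of the session (default one minute),
#' the session-to-session normalization used before any model fitting.
#' Values outside the baseline range legitimately fall outside `[0, 1]`.
#'
#' @param series a [feature_series()].
#' @param baseline_s baseline length in seconds (default 60).
#' @return A [feature_series()] of the same kind with normalized values;
#'   a constant baseline yields all zeros with a warning.
#' @export
minmax_normalize <- function(series, baseline_s = 60) {
  n_base <- sum((seq_along(series$values) - 1) * series$step_s < baseline_s)
  if (n_base < 1 || n_base > length(series$values))
    stop("baseline_s must cover at least one step and at most the series")
  b <- series$values[seq_len(n_base)]
  lo <- min(b); hi <- max(b)
  out <- series
  if (hi - lo < .Machine$double.eps * max(abs(hi), 1)) {
    warning("degenerate baseline (constant over first ", baseline_s,
            " s); returning all zeros")
    out$values <- numeric(length(series$values))
  } else {
    out$values <- (series$values - lo) / (hi - lo)
  }
  out
}

#' Extract the candidate feature pools from a recording
#'
#' Computes band power for every channel x band and builds the two
#' candidate pools. The continuous pool takes the dB transform first
#' (floored at `floor_eps`) and then min/max-normalizes the dB series
#' against the session's first `baseline_s` seconds — the log-then-scale
#' order keeps the feature affine in log-power and unbounded on both
#' sides, as the Gaussian observation channel requires, instead of
#' railing sub-baseline values at the dB floor. The binary-candidate pool
#' is the min/max-normalized raw power (binarized only after selection).
#'
#' @param rec a [recording()].
#' @param bands data frame of bands as [default_bands()].
#' @param window_s,step_s analysis window and step in seconds.
#' @param baseline_s normalization baseline in seconds.
#' @param floor_eps floor before the dB transform.
#' @param channels channels to extract (default: all in `rec`).
#' @return List with elements `cont` and `bin`, each a named list of
#'   [feature_series()] keyed by `"channel|band|kind"`.
#' @export
extract_features <- function(rec, bands = default_bands(), window_s = 1,
                             step_s = 1, baseline_s = 60, floor_eps = 1e-6,
                             channels = rec$channel_labels) {
  cont <- list(); bin <- list()
  for (ch in channels) {
    for (i in seq_len(nrow(bands))) {
      bd <- band_def(bands$name[i], bands$f_lo[i], bands$f_hi[i])
      pw <- band_power(rec, ch, bd, window_s, step_s)
      dbs <- pw
      dbs$values <- to_db(pw$values, floor_eps)
      dbs$kind <- "db"
      dbs <- minmax_normalize(dbs, baseline_s)
      cont[[feature_id(dbs)]] <- dbs
      nm <- minmax_normalize(pw, baseline_s)
      bin[[feature_id(nm)]] <- nm
    }
  }
  list(cont = cont, bin = bin)
}
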