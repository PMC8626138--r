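#' Multichannel EEG recording with seizure annotations
#'
#' Container for one EEG session: a channels-by-samples matrix in microvolts
#' (bipolar-montage channel labels), the sampling rate, and a list of
#' annotated seizure intervals in seconds. Intervals follow the half-open
#' convention `[start, end)`.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per data row
#'   (e.g. `"FP1-F7"`).
#' @param seizure_intervals list of length-2 numeric vectors
#'   `c(start_s, end_s)`, each with `0 <= start_s < end_s <= duration`.
#' @param session_id character scalar identifying the session.
#'
#' @return An object of class `"recording"`.
#' @export
recording <- function(data, fs, channel_labels = rownames(data),
                      seizure_intervals = list(), session_id = "S01") {
  data <- as.matrix(data)
  if (is.null(channel_labels))
    channel_labels <- paste0("CH", seq_len(nrow(data)))
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length must equal the number of data rows")
  dur <- ncol(data) / fs
  seizure_intervals <- lapply(seizure_intervals, function(iv) {
    iv <- as.numeric(iv)
    if (length(iv) != 2L || !(iv[1] >= 0 && iv[1] < iv[2] && iv[2] <= dur))
      stop(sprintf(
        "invalid seizure interval (%s): need 0 <= start < end <= %.3f s",
        paste(iv, collapse = ", "), dur))
    iv
  })
  structure(
    list(channel_labels = as.character(channel_labels), fs = fs,
         data = data, seizure_intervals = seizure_intervals,
         session_id = as.character(session_id)),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d channel(s) x %.1f s @ %g Hz, %d seizure interval(s)\n",
              x$session_id, nrow(x$data), duration(x), x$fs,
              length(x$seizure_intervals)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a [recording()].
#' @return numeric scalar, seconds.
#' @export
duration <- function(rec) ncol(rec$data) / rec$fs

has_seizure <- function(rec) length(rec$seizure_intervals) > 0L

#' Session split into training, validation and test sets
#'
#' The first session containing a recorded seizure becomes the training set,
#' the session with the second recorded seizure the validation set, and all
#' remaining seizure-containing sessions (in their original order) the test
#' set. Sessions with no seizure after the validation session are not used
#' for evaluation.
#'
#' @param sessions ordered list of [recording()] objects.
#' @return A list of class `"session_split"` with character vectors
#'   `train`, `validation` and `test` of session ids.
#' @export
split_sessions <- function(sessions) {
  stopifnot(is.list(sessions))
  ids <- vapply(sessions, function(s) s$session_id, character(1))
  seiz <- vapply(sessions, has_seizure, logical(1))
  if (sum(seiz) < 3L)
    stop("need at least three seizure-containing sessions (train, validation, >=1 test)")
  sids <- ids[seiz]
  structure(list(train = sids[1L], validation = sids[2L],
                 test = sids[-(1:2)]),
            class = "session_split")
}

#' @export
print.session_split <- function(x, ...) {
  cat("<session_split>\n  train:     ", x$train,
      "\n  validation:", x$validation,
      "\n  test:      ", paste(x$test, collapse = ", "), "\n")
  invisible(x)
}

#' Per-step ground-truth seizure labels
#'
#' One binary label per feature time step: label 1 iff the step's timestamp
#' `(k - 1) * step_s` lies inside any annotated seizure interval, using the
#' half-open convention `[start, end)`.
#'
#' @param rec a [recording()].
#' @param step_s step between feature samples in seconds (> 0).
#' @return Integer vector of 0/1 labels of length `floor(duration / step_s)`.
#' @export
label_vector <- function(rec, step_s) {
  stopifnot(step_s > 0)
  n <- floor(duration(rec) / step_s)
  t <- (seq_len(n) - 1) * step_s
  lab <- integer(n)
  for (iv in rec$seizure_intervals)
    lab[t >= iv[1] & t < iv[2]] <- 1L
  lab
}
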