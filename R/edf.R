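# Minimal plain-EDF (European Data Format) reader/writer: ASCII header
# blocks plus little-endian int16 data records with per-channel linear
# physical scaling. Covers continuous whole-second recordings with one
# record per second, which is all this package emits or consumes.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: ", x)
  formatC(x, width = -width)  # left-justified, space padded
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = 1)
  edf_pad(s, width)
}

#' Write a recording to an EDF file (with annotation sidecar)
#'
#' Emits a plain EDF file (1-second data records, 16-bit samples with
#' per-channel physical scaling) and, when the recording has seizure
#' annotations, a plain-text sidecar `<path>.ann` with one
#' `start_s<TAB>end_s` line per interval.
#'
#' @param rec a [recording()]; its duration must be a whole number of
#'   seconds and `fs` a whole number.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) / fs
  if (n_rec != round(n_rec))
    stop("EDF writer requires a whole number of seconds of data")
  n_rec <- as.integer(n_rec)

  pmin <- apply(rec$data, 1, min)
  pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  # widen to the 8-char printed precision so the printed bounds still bracket
  pmin <- pmin - abs(pmin) * 1e-5 - 1e-8
  pmax <- pmax + abs(pmax) * 1e-5 + 1e-8
  pmin_s <- vapply(pmin, edf_num, character(1))
  pmax_s <- vapply(pmax, edf_num, character(1))
  pmin <- as.numeric(pmin_s); pmax <- as.numeric(pmax_s)
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(edf_pad("0", 8))                            # version
  wr(edf_pad(rec$session_id, 80))                # patient id field
  wr(edf_pad("seiztrack", 80))                   # recording id field
  wr(edf_pad("01.01.00", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256 + 256 * ns, 8))                 # header bytes
  wr(edf_pad("", 44))
  wr(edf_pad(n_rec, 8)); wr(edf_pad(1, 8)); wr(edf_pad(ns, 4))
  for (lab in rec$channel_labels) wr(edf_pad(lab, 16))
  wr(strrep(" ", 80 * ns))                       # transducer
  for (i in seq_len(ns)) wr(edf_pad("uV", 8))
  for (i in seq_len(ns)) wr(pmin_s[i])
  for (i in seq_len(ns)) wr(pmax_s[i])
  for (i in seq_len(ns)) wr(edf_pad(dmin, 8))
  for (i in seq_len(ns)) wr(edf_pad(dmax, 8))
  wr(strrep(" ", 80 * ns))                       # prefiltering
  for (i in seq_len(ns)) wr(edf_pad(fs, 8))
  wr(strrep(" ", 32 * ns))

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((rec$data[i, idx] - pmin[i]) * scale[i] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2, endian = "little")
    }
  }
  if (length(rec$seizure_intervals) > 0)
    write_annotations(rec$seizure_intervals, paste0(path, ".ann"))
  invisible(path)
}

#' Write seizure annotations to a sidecar file
#'
#' @param intervals list of `c(start_s, end_s)` vectors.
#' @param path output path; one tab-separated `start_s end_s` line each.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(intervals, path) {
  lines <- vapply(intervals, function(iv)
    sprintf("%.6f\t%.6f", iv[1], iv[2]), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read seizure annotations from a sidecar file
#' @param path annotation file: one `start_s<TAB>end_s` line per interval.
#' @return list of `c(start_s, end_s)` numeric vectors.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) as.numeric(strsplit(l, "[\t ]+")[[1]][1:2]))
}

#' Read an EDF recording with optional seizure annotations
#'
#' @param path EDF file path.
#' @param annotations either a list of `c(start_s, end_s)` intervals, the
#'   path of an annotation sidecar, or `NULL` (the default) to pick up
#'   `<path>.ann` when it exists.
#' @param session_id session identifier; defaults to the file base name.
#' @return A [recording()].
#' @export
read_recording <- function(path, annotations = NULL, session_id = NULL) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rdnum <- function(n) as.numeric(trimws(rd(n)))
  version <- trimws(rd(8))
  if (version != "0") stop("not an EDF file (bad version field): ", path)
  rd(80); rd(80); rd(8); rd(8)
  rdnum(8)                                      # header bytes
  rd(44)
  n_rec <- rdnum(8); rec_dur <- rdnum(8); ns <- as.integer(rdnum(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  rd(80 * ns); rd(8 * ns)                       # transducer, phys dim
  pmin <- vapply(seq_len(ns), function(i) rdnum(8), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) rdnum(8), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) rdnum(8), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) rdnum(8), numeric(1))
  rd(80 * ns)
  spr <- vapply(seq_len(ns), function(i) rdnum(8), numeric(1))
  rd(32 * ns)

  fs <- spr / rec_dur
  if (length(unique(fs)) != 1L)
    stop("EDF reader supports a single common sampling rate only")
  fs <- fs[1]
  data <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2,
                     signed = TRUE, endian = "little")
      data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (dig - dmin[i]) * scale[i] + pmin[i]
    }
  }

  if (is.null(annotations)) {
    side <- paste0(path, ".ann")
    annotations <- if (file.exists(side)) read_annotations(side) else list()
  } else if (is.character(annotations)) {
    annotations <- read_annotations(annotations)
  }
  if (is.null(session_id))
    session_id <- sub("\\.edf$", "", basename(path), ignore.case = TRUE)
  recording(data, fs, labels, annotations, session_id)
}
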