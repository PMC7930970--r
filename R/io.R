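#' Read and write multi-channel signal tables
#'
#' The canonical on-disk signal format is delimited text with one `time_s`
#' column and one column per channel, with a header row carrying channel
#' labels. `write_signal_table()` writes a list of equal-rate, aligned
#' [time_series()] channels; `read_signal_table()` reads them back. The
#' round trip preserves the sample count and sampling rate exactly and the
#' sample values to the written decimal precision.
#'
#' @param channels Named list of `time_series` objects sharing `fs` and
#'   `t0` (names are ignored; channel labels are taken from each series).
#' @param path File path.
#' @param digits Significant digits written for voltages (default 9).
#' @return `read_signal_table()` returns a named list of `time_series`, one
#'   per non-time column; `write_signal_table()` returns `path` invisibly.
#' @export
write_signal_table <- function(channels, path, digits = 9) {
  if (inherits(channels, "time_series")) channels <- list(channels)
  stopifnot(length(channels) >= 1L,
            all(vapply(channels, inherits, TRUE, "time_series")))
  fs <- channels[[1L]]$fs
  t0 <- channels[[1L]]$t0
  n <- length(channels[[1L]]$samples)
  for (ch in channels) {
    if (ch$fs != fs || abs(ch$t0 - t0) > 1e-12 || length(ch$samples) != n) {
      stop("all channels must share fs, t0 and length", call. = FALSE)
    }
  }
  labels <- vapply(channels, function(ch) ch$label, "")
  if (anyDuplicated(labels)) stop("duplicate channel labels", call. = FALSE)
  dt <- data.table::as.data.table(
    c(list(time_s = signif(t0 + (seq_len(n) - 1) / fs, 12)),
      stats::setNames(lapply(channels, function(ch) signif(ch$samples, digits)),
                      labels)))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_signal_table
#' @export
read_signal_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (!"time_s" %in% names(dt)) {
    stop("signal table must contain a 'time_s' column: ", path, call. = FALSE)
  }
  labels <- setdiff(names(dt), "time_s")
  if (length(labels) == 0L) {
    stop("signal table has no channel columns: ", path, call. = FALSE)
  }
  tt <- dt[["time_s"]]
  if (length(tt) < 2L) stop("signal table needs >= 2 rows", call. = FALSE)
  dts <- diff(tt)
  if (any(dts <= 0)) {
    stop("time column must be strictly increasing: ", path, call. = FALSE)
  }
  if (max(dts) - min(dts) > 1e-6 * stats::median(dts)) {
    stop("time column is not uniformly sampled: ", path, call. = FALSE)
  }
  fs <- round(1 / stats::median(dts), 6)
  stats::setNames(
    lapply(labels, function(lab) {
      time_series(dt[[lab]], fs = fs, t0 = tt[1L], label = lab)
    }),
    labels)
}

#' Read and write event annotation files
#'
#' Annotations are delimited text with columns `time_s` and `label`.
#'
#' @param path File path.
#' @param ann An [event_annotations()] object (for writing).
#' @return `read_annotations()` returns an `event_annotations` object.
#' @export
read_annotations <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (!all(c("time_s", "label") %in% names(dt))) {
    stop("annotation file must have 'time_s' and 'label' columns: ",
         path, call. = FALSE)
  }
  event_annotations(dt[["time_s"]], dt[["label"]])
}

#' @rdname read_annotations
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "event_annotations"))
  data.table::fwrite(as.data.frame(ann), path)
  invisible(path)
}
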