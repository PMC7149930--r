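#' Normal-to-normal R-R interval series
#'
#' Container for a sequence of normal-to-normal (NN) R-R intervals in
#' milliseconds, together with the cumulative occurrence time of the end of
#' each interval. The timestamps carry the real-time axis of the recording,
#' which is what makes spectral analysis of the (inherently unevenly sampled)
#' interval series well defined.
#'
#' When `t_end` is not supplied it is taken as the cumulative sum of the
#' intervals. A supplied `t_end` may run ahead of the cumulative sum (gaps
#' arise when abnormal intervals have been excised by [clean_nn()]), but it
#' must be strictly increasing and each step must be at least as long as the
#' interval it terminates.
#'
#' @param intervals numeric vector of positive interval durations (ms).
#' @param t_end optional numeric vector of cumulative end times (ms), same
#'   length as `intervals`.
#' @param source_id free-text record label.
#' @return An object of class `rr_series`: a list with elements `intervals`,
#'   `t_end` and `source_id`.
#' @examples
#' rr <- rr_series(c(800, 810, 790, 805, 795, 820))
#' rr
#' @export
rr_series <- function(intervals, t_end = NULL, source_id = "") {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L) stop("'intervals' is empty", call. = FALSE)
  if (anyNA(intervals)) stop("'intervals' contains NA", call. = FALSE)
  if (any(intervals <= 0)) stop("all intervals must be > 0", call. = FALSE)
  if (is.null(t_end)) {
    t_end <- cumsum(intervals)
  } else {
    t_end <- as.numeric(t_end)
    if (length(t_end) != length(intervals))
      stop("'t_end' and 'intervals' must have the same length", call. = FALSE)
    steps <- diff(c(0, t_end))
    if (any(diff(t_end) <= 0))
      stop("'t_end' must be strictly increasing", call. = FALSE)
    if (any(steps < intervals - 1e-6))
      stop("each t_end step must be >= the interval it ends", call. = FALSE)
  }
  structure(
    list(intervals = intervals, t_end = t_end,
         source_id = as.character(source_id)[1]),
    class = "rr_series"
  )
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x$intervals)
  cat(sprintf("<rr_series> %d NN intervals%s\n", n,
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  cat(sprintf("  mean %.1f ms, range %.0f-%.0f ms, duration %.1f s\n",
              mean(x$intervals), min(x$intervals), max(x$intervals),
              max(x$t_end) / 1000))
  invisible(x)
}

is_rr_series <- function(x) inherits(x, "rr_series")

#' Read an R-R interval series from a text or CSV file
#'
#' Two plain-text layouts are accepted: one interval per line in ms (`#`
#' starts a comment), or a CSV with columns `t_end_ms,interval_ms`.
#'
#' @param path file path.
#' @param source_id record label; defaults to the file name.
#' @return An [rr_series()].
#' @export
read_rr <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no data in ", path, call. = FALSE)
  if (grepl(",", lines[1])) {
    header <- grepl("interval_ms", lines[1], fixed = TRUE)
    txt <- paste(lines, collapse = "\n")
    df <- if (header) read.csv(text = txt)
    else read.csv(text = txt, header = FALSE,
                  col.names = c("t_end_ms", "interval_ms"))
    if (!all(c("t_end_ms", "interval_ms") %in% names(df)))
      stop("CSV input needs columns t_end_ms,interval_ms", call. = FALSE)
    rr_series(df$interval_ms, t_end = df$t_end_ms, source_id = source_id)
  } else {
    rr_series(as.numeric(lines), source_id = source_id)
  }
}

#' Write an R-R interval series
#'
#' Writes the two-column CSV layout (`t_end_ms,interval_ms`) understood by
#' [read_rr()].
#'
#' @param x an [rr_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rr <- function(x, path) {
  stopifnot(is_rr_series(x))
  df <- data.frame(t_end_ms = x$t_end, interval_ms = x$intervals)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
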