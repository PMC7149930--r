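#' Canonical HRnV sequence label
#'
#' `"HRV"` for n = 1, `"HR{n}V"` for the non-overlapping case m = n, and
#' `"HR{n}V{m}"` for the overlapping case m < n.
#'
#' @param n window length (number of constituent R-R intervals).
#' @param m stride; defaults to `n`.
#' @return character scalar.
#' @export
hrnv_label <- function(n, m = n) {
  if (n == 1) "HRV"
  else if (m == n) sprintf("HR%dV", n)
  else sprintf("HR%dV%d", n, m)
}

new_hrnv_series <- function(intervals, t_end, n, m, parent) {
  structure(
    list(intervals = intervals, t_end = t_end,
         source_id = parent$source_id,
         n = as.integer(n), m = as.integer(m),
         label = hrnv_label(n, m)),
    class = c("hrnv_series", "rr_series")
  )
}

#' @export
print.hrnv_series <- function(x, ...) {
  cat(sprintf("<hrnv_series %s> n=%d m=%d, %d composite intervals, mean %.1f ms\n",
              x$label, x$n, x$m, length(x$intervals), mean(x$intervals)))
  invisible(x)
}

#' Construct a non-overlapping RRnI sequence
#'
#' Sums every block of `n` adjacent R-R intervals, starting at the first
#' interval, into one composite RRnI interval. Trailing intervals that do not
#' fill a complete block are dropped. Each composite interval inherits the
#' cumulative end time of its last constituent beat, preserving the real-time
#' axis for spectral analysis. For n = 1 the result is element-wise identical
#' to the parent series.
#'
#' @param parent an [rr_series()].
#' @param n integer window length, `1 <= n <= length(parent)`.
#' @return An `hrnv_series` (subclass of `rr_series`) carrying `n`, `m = n`
#'   and the label `"HRV"`/`"HR{n}V"`.
#' @examples
#' rr <- rr_series(c(800, 810, 790, 805, 795, 820))
#' rr_ni(rr, 2)$intervals  # 1610 1595 1615
#' @export
rr_ni <- function(parent, n) {
  rr_nim(parent, n, n)
}

#' Construct an overlapping RRnIm sequence
#'
#' Element k (0-based) is the sum of parent intervals `[k*m + 1, k*m + n]`,
#' so consecutive composites share `n - m` constituent intervals. The number
#' of elements is `floor((N - n)/m) + 1` for a parent of length N. With
#' `m = n` the construction coincides with the non-overlapping [rr_ni()].
#'
#' @param parent an [rr_series()].
#' @param n integer window length.
#' @param m integer stride, `1 <= m <= n`.
#' @return An `hrnv_series`.
#' @examples
#' rr <- rr_series(c(800, 810, 790, 805, 795, 820))
#' rr_nim(rr, 2, 1)$intervals  # 1610 1600 1595 1600 1615
#' @export
rr_nim <- function(parent, n, m = n) {
  stopifnot(is_rr_series(parent))
  n <- as.integer(n); m <- as.integer(m)
  N <- length(parent$intervals)
  if (is.na(n) || n < 1L || n > N)
    stop("'n' must satisfy 1 <= n <= ", N, call. = FALSE)
  if (is.na(m) || m < 1L || m > n)
    stop("'m' must satisfy 1 <= m <= n", call. = FALSE)
  k <- (N - n) %/% m + 1L
  if (k < 2L)
    stop("sequence too short: only ", k, " composite interval(s) for n=",
         n, ", m=", m, call. = FALSE)
  starts <- (seq_len(k) - 1L) * m + 1L
  ends <- starts + n - 1L
  if (n == 1L) {
    intervals <- parent$intervals[starts]   # exact identity when n = 1
  } else {
    cs <- c(0, cumsum(parent$intervals))
    intervals <- cs[ends + 1L] - cs[starts]
  }
  new_hrnv_series(intervals, parent$t_end[ends], n, m, parent)
}

#' Enumerate every HRnV sequence up to n_max
#'
#' Returns, in deterministic order, the conventional series (n = 1), all
#' non-overlapping RRnI for `2 <= n <= n_max`, then all overlapping RRnIm for
#' `2 <= n <= n_max`, `1 <= m <= n - 1`. The total number of sequences is
#' `1 + (n_max - 1) + n_max * (n_max - 1) / 2`; for `n_max = 3` this is the
#' six-set family HRV, HR2V, HR3V, HR2V1, HR3V1, HR3V2.
#'
#' @param parent an [rr_series()].
#' @param n_max upper limit of the window length n. Should be much smaller
#'   than the series length; a warning is issued when `n_max > N/10`.
#' @return Named list of `hrnv_series`, names being the canonical labels.
#' @export
hrnv_sequences <- function(parent, n_max = 3) {
  stopifnot(is_rr_series(parent))
  n_max <- as.integer(n_max)
  if (is.na(n_max) || n_max < 1L) stop("'n_max' must be >= 1", call. = FALSE)
  N <- length(parent$intervals)
  if (n_max > N / 10)
    warning("n_max = ", n_max, " is large relative to series length ", N,
            "; composite sequences will be short", call. = FALSE)
  out <- list(rr_nim(parent, 1L, 1L))
  for (n in seq_len(n_max)[-1]) out <- c(out, list(rr_ni(parent, n)))
  for (n in seq_len(n_max)[-1])
    for (m in seq_len(n - 1L)) out <- c(out, list(rr_nim(parent, n, m)))
  names(out) <- vapply(out, `[[`, "", "label")
  out
}
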