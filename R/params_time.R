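#' Time-domain parameters
#'
#' Scalar descriptors of an interval sequence (conventional or composite).
#' All accept either an [rr_series()]/`hrnv_series` or a bare numeric vector
#' of intervals in ms.
#'
#' @param seq interval sequence (ms).
#' @param sd_type `"sample"` (N-1) or `"population"` (N) denominator.
#' @return numeric scalar (ms, except where noted).
#' @name time_domain
NULL

#' @rdname time_domain
#' @export
mean_nn <- function(seq) {
  x <- seq_intervals(seq)
  if (length(x) < 1L) stop("empty sequence", call. = FALSE)
  mean(x)
}

#' @rdname time_domain
#' @export
sdnn <- function(seq, sd_type = c("sample", "population")) {
  x <- seq_intervals(seq)
  if (length(x) < 2L) stop("need >= 2 intervals", call. = FALSE)
  sd_type <- match.arg(sd_type)
  v <- var(x)
  if (sd_type == "population") v <- v * (length(x) - 1) / length(x)
  sqrt(v)
}

#' @rdname time_domain
#' @export
rmssd <- function(seq) {
  x <- seq_intervals(seq)
  if (length(x) < 2L) stop("need >= 2 intervals", call. = FALSE)
  sqrt(mean(diff(x)^2))
}

#' NN50-family counts on a (composite) interval sequence
#'
#' `nn50` counts successive differences whose absolute value exceeds 50 ms;
#' `pnn50` expresses it as a percentage. On composite sequences (n > 1) the
#' scaled variants `nn50n`/`pnn50n` use the threshold `50 * n` ms instead,
#' reflecting that a composite interval is n beats long; for n = 1 they are
#' returned as `NA` (they duplicate nn50/pnn50 there and are not reported).
#'
#' The percentage denominator is the total number of intervals by default
#' (`pnn_denominator = "intervals"`); set `"pairs"` to divide by the number
#' of successive differences instead.
#'
#' @param seq interval sequence (ms).
#' @param n the window length tag of the sequence; taken from an
#'   `hrnv_series` automatically.
#' @param pnn_denominator see Description.
#' @return named list `nn50`, `pnn50`, `nn50n`, `pnn50n`.
#' @export
nn50_stats <- function(seq, n = NULL,
                       pnn_denominator = c("intervals", "pairs")) {
  x <- seq_intervals(seq)
  if (is.null(n)) n <- if (inherits(seq, "hrnv_series")) seq$n else 1L
  if (length(x) < 2L) stop("need >= 2 intervals", call. = FALSE)
  pnn_denominator <- match.arg(pnn_denominator)
  d <- abs(diff(x))
  denom <- if (pnn_denominator == "intervals") length(x) else length(d)
  nn50 <- sum(d > 50)
  out <- list(nn50 = nn50, pnn50 = 100 * nn50 / denom,
              nn50n = NA_real_, pnn50n = NA_real_)
  if (n > 1L) {
    nn50n <- sum(d > 50 * n)
    out$nn50n <- nn50n
    out$pnn50n <- 100 * nn50n / denom
  }
  out
}

skewness_p <- function(x) {
  if (length(x) < 3L) stop("need >= 3 intervals", call. = FALSE)
  if (sd(x) == 0) {
    warning("zero variance: skewness undefined", call. = FALSE)
    return(NA_real_)
  }
  e1071::skewness(x, type = 1)
}

kurtosis_p <- function(x, kurtosis_type = "pearson") {
  if (length(x) < 3L) stop("need >= 3 intervals", call. = FALSE)
  if (sd(x) == 0) {
    warning("zero variance: kurtosis undefined", call. = FALSE)
    return(NA_real_)
  }
  k <- e1071::kurtosis(x, type = 1)
  if (kurtosis_type == "pearson") k + 3 else k
}

#' Triangular index of the interval histogram
#'
#' Total number of intervals divided by the occupancy of the modal histogram
#' bin, with bins aligned to integer multiples of `bin_width`.
#'
#' @param seq interval sequence (ms).
#' @param bin_width histogram bin width in ms (default 1000/128 = 7.8125).
#' @return dimensionless scalar >= 1.
#' @export
triangular_index <- function(seq, bin_width = 1000 / 128) {
  x <- seq_intervals(seq)
  if (length(x) < 2L) stop("need >= 2 intervals", call. = FALSE)
  if (bin_width <= 0) stop("'bin_width' must be > 0", call. = FALSE)
  counts <- table(floor(x / bin_width))
  length(x) / max(counts)
}

#' Full time-domain panel for one sequence
#'
#' @param seq interval sequence, ideally an `hrnv_series` so the n tag is
#'   known for NN50n/pNN50n.
#' @param cfg an [hrnv_config()].
#' @return named list of the ten time-domain parameters.
#' @export
time_domain <- function(seq, cfg = hrnv_config()) {
  x <- seq_intervals(seq)
  nn <- nn50_stats(seq, pnn_denominator = cfg$pnn_denominator)
  list(
    MeanNN = mean_nn(x),
    SDNN = sdnn(x, sd_type = cfg$sd_type),
    RMSSD = rmssd(x),
    Skewness = skewness_p(x),
    Kurtosis = kurtosis_p(x, cfg$kurtosis_type),
    TriangularIndex = triangular_index(x, cfg$tri_bin_width),
    NN50 = nn$nn50, pNN50 = nn$pnn50,
    NN50n = nn$nn50n, pNN50n = nn$pnn50n
  )
}
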