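#' Single-lead ECG trace
#'
#' @param samples voltage samples (mV).
#' @param fs sampling rate (Hz), > 0.
#' @param source_id free-text record label.
#' @return Object of class `ecg_trace`.
#' @export
ecg_trace <- function(samples, fs, source_id = "") {
  samples <- as.numeric(samples)
  if (!is.finite(fs) || fs <= 0) stop("'fs' must be > 0", call. = FALSE)
  if (length(samples) < 2L) stop("'samples' too short", call. = FALSE)
  structure(list(samples = samples, fs = fs,
                 duration = length(samples) / fs,
                 source_id = as.character(source_id)[1]),
            class = "ecg_trace")
}

#' @export
print.ecg_trace <- function(x, ...) {
  cat(sprintf("<ecg_trace> %.1f s at %g Hz (%d samples)\n",
              x$duration, x$fs, length(x$samples)))
  invisible(x)
}

#' Read an ECG trace from CSV
#'
#' Single voltage column; the sampling rate is given in a `# fs=...` comment
#' line or via the `fs` argument.
#'
#' @param path file path.
#' @param fs sampling rate (Hz); overrides any value in the file.
#' @return An [ecg_trace()].
#' @export
read_ecg <- function(path, fs = NULL) {
  lines <- readLines(path, warn = FALSE)
  fsline <- grep("^#\\s*fs\\s*=", lines, value = TRUE)
  if (is.null(fs)) {
    if (!length(fsline)) stop("sampling rate not found; pass 'fs'", call. = FALSE)
    fs <- as.numeric(sub(".*=\\s*", "", fsline[1]))
  }
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (identical(tolower(trimws(lines[1])), "mv")) lines <- lines[-1]
  ecg_trace(as.numeric(lines), fs, source_id = basename(path))
}

#' Detect QRS complexes in a single-lead ECG
#'
#' Classic energy-based detector: Butterworth band-pass (5-15 Hz),
#' differentiation, squaring, 150 ms moving-window integration, then an
#' adaptive signal/noise threshold with a 200 ms refractory period. Each
#' detection is refined to the local maximum of the raw signal.
#'
#' @param ecg an [ecg_trace()]; requires `fs >= 100` Hz and at least 10 s of
#'   signal.
#' @param refractory minimum beat spacing (s).
#' @return Numeric vector of strictly increasing beat times (s).
#' @export
detect_beats <- function(ecg, refractory = 0.2) {
  stopifnot(inherits(ecg, "ecg_trace"))
  fs <- ecg$fs
  x <- ecg$samples
  if (fs < 100) stop("'fs' must be >= 100 Hz", call. = FALSE)
  if (length(x) / fs < 10) stop("need >= 10 s of signal", call. = FALSE)
  if (sd(x) < 1e-8 || mean(abs(diff(x)) < 1e-12) > 0.98)
    stop("unusable signal: flatline or saturated input", call. = FALSE)

  bp <- signal::filtfilt(signal::butter(3, c(5, 15) / (fs / 2), "pass"), x)
  energy <- c(0, diff(bp))^2
  w <- max(1L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(energy, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0

  # candidate peaks: local maxima of the integrated energy
  up <- diff(integ) > 0
  cand <- which(head(up, -1) & !tail(up, -1)) + 1L
  cand <- cand[integ[cand] > 0]
  if (!length(cand)) stop("unusable signal: no QRS energy found", call. = FALSE)

  spki <- max(integ[seq_len(min(length(integ), round(2 * fs)))]) * 0.5
  npki <- mean(integ[seq_len(min(length(integ), round(2 * fs)))]) * 0.5
  thr <- npki + 0.25 * (spki - npki)
  ref <- round(refractory * fs)
  beats_idx <- integer(0)
  last <- -ref
  for (i in cand) {
    if (i - last < ref) {
      # within refractory: keep the larger peak
      if (length(beats_idx) && integ[i] > integ[beats_idx[length(beats_idx)]]) {
        beats_idx[length(beats_idx)] <- i
        last <- i
      }
      next
    }
    if (integ[i] > thr) {
      beats_idx <- c(beats_idx, i)
      last <- i
      spki <- 0.125 * integ[i] + 0.875 * spki
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (length(beats_idx) < 3L)
    stop("unusable signal: fewer than 3 beats detected", call. = FALSE)

  # refine each detection to the raw-signal maximum nearby (R wave apex)
  half <- as.integer(round(0.08 * fs))
  refined <- vapply(beats_idx, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    lo + which.max(x[lo:hi]) - 1L
  }, numeric(1))
  sort(unique(refined)) / fs
}

#' Clean beat times into a normal-to-normal interval series
#'
#' Converts beat times to intervals and excises abnormal ones: intervals
#' outside the physiological `bounds` (default 300-2000 ms) or deviating more
#' than `max_dev` (default 20%) from the running median of the last five
#' accepted intervals. Excised intervals are removed, not merged, so the
#' retained timestamps keep their true positions on the recording axis (the
#' Lomb spectral estimator tolerates the resulting gaps). Records losing more
#' than `max_removed` of their intervals are rejected as non-sinus or noisy.
#'
#' @param beats numeric vector of beat times (s), length >= 3.
#' @param bounds numeric length-2, allowed interval range in ms.
#' @param max_dev maximum relative deviation from the running median.
#' @param max_removed rejection threshold on the fraction removed.
#' @param source_id record label.
#' @return An [rr_series()]; attribute `fraction_removed` gives the fraction
#'   of intervals excised.
#' @export
clean_nn <- function(beats, bounds = c(300, 2000), max_dev = 0.2,
                     max_removed = 0.2, source_id = "") {
  beats <- as.numeric(beats)
  if (length(beats) < 3L) stop("need >= 3 beats", call. = FALSE)
  if (any(diff(beats) <= 0)) stop("beat times must be increasing", call. = FALSE)
  iv <- diff(beats) * 1000
  t_end <- beats[-1] * 1000
  keep <- logical(length(iv))
  accepted <- numeric(0)
  for (i in seq_along(iv)) {
    ok <- iv[i] >= bounds[1] && iv[i] <= bounds[2]
    if (ok && length(accepted) >= 1L) {
      med <- median(tail(accepted, 5))
      ok <- abs(iv[i] - med) <= max_dev * med
    }
    keep[i] <- ok
    if (ok) accepted <- c(accepted, iv[i])
  }
  frac <- 1 - mean(keep)
  if (frac > max_removed)
    stop(sprintf("non-sinus or noisy record: %.0f%% of intervals removed",
                 100 * frac), call. = FALSE)
  out <- rr_series(iv[keep], t_end = t_end[keep], source_id = source_id)
  attr(out, "fraction_removed") <- frac
  out
}
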