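#' Lomb-Scargle power spectral density of an interval sequence
#'
#' Evaluates the classical Lomb-Scargle periodogram of the mean-subtracted
#' intervals on their native (uneven) end-time axis — no resampling — over a
#' uniform frequency grid. The density is scaled so that numerically
#' integrating it over the grid returns variance-scale power in ms^2: a pure
#' sinusoidal modulation of amplitude a integrates to approximately a^2/2.
#'
#' The grid runs from `1/(ofac*T)` (T the record span) up to
#' `max(0.4, 0.5/median interval)` Hz in steps of `1/(ofac*T)`, so the
#' conventional HF band upper edge at 0.4 Hz is always covered even for
#' composite sequences whose mean beat rate is low.
#'
#' @param seq an [rr_series()]/`hrnv_series` (timestamps required) or a
#'   numeric vector of intervals (ms), in which case timestamps are taken as
#'   the cumulative sums.
#' @param ofac oversampling factor (>= 1) of the frequency grid.
#' @param fmax optional upper frequency limit (Hz).
#' @return Object of class `power_spectrum`: list with `freq` (Hz), `density`
#'   (ms^2/Hz), and `method = "lomb"`.
#' @export
lomb_psd <- function(seq, ofac = 4, fmax = NULL) {
  if (is_rr_series(seq)) {
    x <- seq$intervals
    t <- seq$t_end / 1000           # seconds
  } else {
    x <- as.numeric(seq)
    t <- cumsum(x) / 1000
  }
  N <- length(x)
  if (N < 8L) stop("need >= 8 intervals for spectral analysis", call. = FALSE)
  if (anyDuplicated(t)) stop("duplicate timestamps", call. = FALSE)
  Tspan <- max(t) - min(t)
  df <- 1 / (ofac * Tspan)
  if (is.null(fmax)) fmax <- max(0.4, 0.5 / (median(x) / 1000))
  freq <- seq(df, fmax, by = df)
  xm <- x - mean(x)
  varx <- sum(xm^2) / N

  if (varx == 0) {
    dens <- rep(0, length(freq))
  } else {
    w <- 2 * pi * freq
    # tau makes the sine and cosine bases orthogonal at each frequency
    tw2 <- outer(2 * t, w)                       # N x F
    tau <- atan2(colSums(sin(tw2)), colSums(cos(tw2))) / (2 * w)
    arg <- outer(t, w) - matrix(w * tau, N, length(w), byrow = TRUE)
    ca <- cos(arg); sa <- sin(arg)
    P <- 0.5 * ((colSums(xm * ca))^2 / colSums(ca^2) +
                (colSums(xm * sa))^2 / colSums(sa^2))
    # one-sided density: 2 P / (mean sampling rate); integrates to ~variance
    dens <- 2 * P / (N / Tspan)
  }
  structure(list(freq = freq, density = dens, method = "lomb"),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum %s> %d frequencies, %.4g-%.4g Hz\n",
              x$method, length(x$freq), min(x$freq), max(x$freq)))
  invisible(x)
}

# trapezoidal integral of the density over (lo, hi], with linear
# interpolation at the band edges so contiguous bands partition exactly
band_integral <- function(spec, lo, hi) {
  f <- spec$freq; d <- spec$density
  hi <- min(hi, max(f))
  if (hi <= lo || lo >= max(f)) return(0)
  inner <- which(f > lo & f < hi)
  fs <- f[inner]; ds <- d[inner]
  if (lo >= min(f)) {
    fs <- c(lo, fs); ds <- c(approx(f, d, xout = lo)$y, ds)
  }
  fs <- c(fs, hi); ds <- c(ds, approx(f, d, xout = hi)$y)
  sum(diff(fs) * (head(ds, -1) + tail(ds, -1)) / 2)
}

#' Band powers from a power spectrum
#'
#' Integrates the density over the conventional VLF (0, 0.04], LF
#' (0.04, 0.15] and HF (0.15, 0.4] Hz bands (trapezoid, half-open so no bin
#' is counted twice), and derives total power, normalized LF/HF powers and
#' their ratio. Total power is the sum of the three band powers;
#' `LFPowerNorm + HFPowerNorm` is exactly 100 whenever LF + HF > 0.
#'
#' @param spec a `power_spectrum` from [lomb_psd()], or a sequence accepted
#'   by it.
#' @param cfg an [hrnv_config()] carrying the band edges.
#' @return named list: `TotalPower`, `VLFPower`, `LFPower`, `HFPower` (ms^2),
#'   `LFPowerNorm`, `HFPowerNorm` (nu, 0-100), `LF_HF` (ratio; `NA` with a
#'   warning when HF power is 0).
#' @export
band_powers <- function(spec, cfg = hrnv_config()) {
  if (!inherits(spec, "power_spectrum")) spec <- lomb_psd(spec, ofac = cfg$psd_ofac)
  vlf <- band_integral(spec, cfg$vlf[1], cfg$vlf[2])
  lf <- band_integral(spec, cfg$lf[1], cfg$lf[2])
  hf <- band_integral(spec, cfg$hf[1], cfg$hf[2])
  lfhf <- lf + hf
  if (lfhf > 0) {
    lfn <- 100 * lf / lfhf
    hfn <- 100 - lfn
  } else {
    lfn <- NA_real_; hfn <- NA_real_
  }
  ratio <- if (hf > 0) lf / hf else {
    warning("HF power is 0: LF/HF undefined", call. = FALSE)
    NA_real_
  }
  list(TotalPower = vlf + lf + hf, VLFPower = vlf, LFPower = lf,
       HFPower = hf, LFPowerNorm = lfn, HFPowerNorm = hfn, LF_HF = ratio)
}

#' Full frequency-domain panel for one sequence
#'
#' @param seq interval sequence.
#' @param cfg an [hrnv_config()].
#' @return named list of the seven frequency-domain parameters.
#' @export
freq_domain <- function(seq, cfg = hrnv_config()) {
  band_powers(lomb_psd(seq, ofac = cfg$psd_ofac), cfg)
}
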