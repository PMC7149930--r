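with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate an R-R interval series with known spectral ground truth
#'
#' Intervals follow `mean_nn + lf_amp*sin(2*pi*lf_freq*t) +
#' hf_amp*sin(2*pi*hf_freq*t) + jitter`, evaluated at the cumulative beat
#' time, emulating sympathetically (LF, default 0.1 Hz) and respiratorily
#' (HF, default 0.25 Hz) modulated sinus rhythm. A sinusoid of amplitude `a`
#' contributes band power `a^2/2` ms^2, so the generated record carries exact
#' spectral ground truth. Optional ectopy replaces an interval by a
#' short-long couplet at the given rate.
#'
#' @param mean_nn mean interval (ms); default 830 ms, a typical resting
#'   value.
#' @param lf_freq,hf_freq modulation frequencies (Hz).
#' @param lf_amp,hf_amp modulation amplitudes (ms).
#' @param jitter_sd SD of white Gaussian beat-to-beat jitter (ms).
#' @param ectopic_rate expected ectopic couplets per minute.
#' @param duration record length (s); default 330 s (mid five-to-six
#'   minutes).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return An [rr_series()]; attribute `ground_truth` is a list with the
#'   true `mean_nn`, `lf_power` and `hf_power` (ms^2) and the indices of
#'   injected ectopics.
#' @export
simulate_rr <- function(mean_nn = 830, lf_freq = 0.1, hf_freq = 0.25,
                        lf_amp = 25, hf_amp = 20, jitter_sd = 10,
                        ectopic_rate = 0, duration = 330, seed = NULL) {
  stopifnot(lf_amp >= 0, hf_amp >= 0, jitter_sd >= 0, duration > 0)
  with_seed(seed, {
    nmax <- ceiling(duration / (max(mean_nn - lf_amp - hf_amp, 200) / 1000)) + 2L
    jit <- rnorm(nmax, 0, jitter_sd)
    iv <- numeric(nmax); tt <- 0; i <- 0L
    while (tt < duration && i < nmax) {
      i <- i + 1L
      iv[i] <- mean_nn +
        lf_amp * sin(2 * pi * lf_freq * tt) +
        hf_amp * sin(2 * pi * hf_freq * tt) + jit[i]
      iv[i] <- max(iv[i], 200)
      tt <- tt + iv[i] / 1000
    }
    iv <- iv[seq_len(i)]
    ect <- integer(0)
    if (ectopic_rate > 0) {
      n_ect <- max(0L, round(ectopic_rate * duration / 60))
      if (n_ect > 0) {
        ect <- sort(sample(seq(2L, length(iv) - 2L), n_ect))
        for (j in ect) {
          tot <- iv[j] + iv[j + 1L]
          iv[j] <- 0.55 * iv[j]          # premature beat: short coupling
          iv[j + 1L] <- tot - iv[j]      # compensatory pause
        }
      }
    }
    out <- rr_series(iv, source_id = sprintf("sim-rr-seed%s",
                                             if (is.null(seed)) "NA" else seed))
    attr(out, "ground_truth") <- list(
      mean_nn = mean_nn,
      lf_power = lf_amp^2 / 2, hf_power = hf_amp^2 / 2,
      ectopic_index = ect)
    out
  })
}

ecg_beat_template <- function(tt) {
  # offsets (s), amplitudes (mV), widths (s) of P-QRS-T Gaussians
  off <- c(-0.20, -0.035, 0, 0.035, 0.22)
  amp <- c(0.12, -0.12, 1.0, -0.15, 0.30)
  wid <- c(0.025, 0.010, 0.009, 0.010, 0.045)
  v <- 0
  for (k in seq_along(off)) v <- v + amp[k] * exp(-((tt - off[k])^2) / (2 * wid[k]^2))
  v
}

#' Synthesize a single-lead ECG from an R-R series
#'
#' Places a fixed P-QRS-T template (sum of Gaussians, sharp 1 mV R wave) at
#' each cumulative beat time and samples at `fs`. Optionally adds white
#' Gaussian noise at a given signal-to-noise ratio.
#'
#' @param rr an [rr_series()].
#' @param fs sampling rate (Hz), >= 100.
#' @param snr_db signal-to-noise ratio in dB; `Inf` (default) for a clean
#'   trace.
#' @param seed seed for the noise.
#' @return An [ecg_trace()]; attribute `beat_times` holds the true beat
#'   times (s).
#' @export
simulate_ecg <- function(rr, fs = 250, snr_db = Inf, seed = NULL) {
  stopifnot(is_rr_series(rr), fs >= 100)
  beats <- c(0, rr$t_end / 1000)
  dur <- max(beats) + 0.5
  t <- seq(0, dur, by = 1 / fs)
  x <- numeric(length(t))
  for (b in beats) {
    lo <- max(1L, floor((b - 0.35) * fs) + 1L)
    hi <- min(length(t), ceiling((b + 0.45) * fs) + 1L)
    idx <- lo:hi
    x[idx] <- x[idx] + ecg_beat_template(t[idx] - b)
  }
  if (is.finite(snr_db)) {
    x <- with_seed(seed, {
      psig <- mean(x^2)
      x + rnorm(length(x), 0, sqrt(psig / 10^(snr_db / 10)))
    })
  }
  out <- ecg_trace(x, fs, source_id = rr$source_id)
  attr(out, "beat_times") <- beats
  out
}

mace_or_defaults <- function() {
  # adjusted odds ratios of the 16-variable chest-pain model, on log scale
  log(c(age = 1.021, diastolic_bp = 1.018, pain_score = 1.082,
        st_elevation = 6.449, st_depression = 4.827, q_wave = 3.383,
        cardiac_history = 7.838, troponin = 4.406,
        hrv_nn50 = 0.981, hr2v_skewness = 0.806, hr2v_sampen = 0.600,
        hr2v_apen = 0.095, hr2v1_apen = 19.700, hr3v_rmssd = 1.024,
        hr3v_skewness = 1.560, hr3v2_hf_power = 1.000))
}

#' Simulate a chest-pain cohort with a known outcome model
#'
#' Draws a patient-level feature table emulating an emergency-department
#' chest-pain cohort: age (mean 59.6, SD 12.9 years), male sex (68%),
#' diastolic blood pressure, pain score, 12-lead ECG findings
#' (ST-elevation/depression, Q wave), a 0/1/2 cardiac-history code, a 0/1/2
#' troponin code derived from a log-normal troponin value via
#' [encode_troponin()], and a set of HRV/HRnV parameters with the printed
#' cohort marginals. The binary 30-day MACE outcome is sampled from a
#' logistic model whose log-odds use `coefficients` (default: the log
#' adjusted odds ratios of a reference 16-predictor chest-pain model); the intercept
#' is solved numerically so the expected event rate matches `event_rate`.
#'
#' BP, pain-score and ECG-finding marginals have no reference values and are
#' invented plausible defaults.
#'
#' @param n_patients number of rows (default 795).
#' @param event_rate target outcome prevalence (default 0.31).
#' @param coefficients named log-OR vector over the 16 model predictors; see
#'   `hrnv:::mace_or_defaults()` for names.
#' @param missingness fraction of HRnV entropy values set missing (emulating
#'   undefined sample entropy on short records).
#' @param seed integer seed.
#' @return `data.frame` with the predictors, `male` (0/1), `troponin_ngml`,
#'   and the outcome column `mace` (0/1); attribute `true_coefficients`
#'   stores the generating vector including the solved `(Intercept)`.
#' @export
simulate_cohort <- function(n_patients = 795, event_rate = 0.31,
                            coefficients = mace_or_defaults(),
                            missingness = 0, seed = NULL) {
  stopifnot(event_rate > 0, event_rate < 1, n_patients >= 10)
  beta <- mace_or_defaults()
  if (!is.null(coefficients)) {
    if (is.null(names(coefficients)) ||
        !all(names(coefficients) %in% names(beta)))
      stop("'coefficients' must be named after the model predictors",
           call. = FALSE)
    beta[names(coefficients)] <- coefficients
  }
  with_seed(seed, {
    n <- n_patients
    df <- data.frame(
      age = rnorm(n, 59.63, 12.88),
      male = rbinom(n, 1, 0.682),
      diastolic_bp = rnorm(n, 74, 12),
      pain_score = pmin(10, pmax(0, round(rnorm(n, 5, 2)))),
      st_elevation = rbinom(n, 1, 0.07),
      st_depression = rbinom(n, 1, 0.14),
      q_wave = rbinom(n, 1, 0.09),
      cardiac_history = sample(0:2, n, TRUE, prob = c(0.45, 0.30, 0.25)),
      troponin_ngml = exp(rnorm(n, log(0.02), 1.3)),
      hrv_nn50 = pmax(0, rnorm(n, 21.08, 33.98)),
      hr2v_skewness = rnorm(n, -0.41, 1.66),
      hr2v_sampen = pmax(0, rnorm(n, 1.33, 0.48)),
      hr2v_apen = pmax(0.05, rnorm(n, 0.72, 0.18)),
      hr2v1_apen = pmax(0.05, rnorm(n, 0.91, 0.17)),
      hr3v_rmssd = pmax(1, rnorm(n, 34.83, 28.86)),
      hr3v_skewness = rnorm(n, -0.29, 1.29),
      hr3v2_hf_power = exp(rnorm(n, log(400), 1.2))
    )
    df$troponin <- vapply(df$troponin_ngml, encode_troponin, 0)
    X <- as.matrix(df[names(beta)])
    lp <- drop(X %*% beta)
    lp <- lp - mean(lp)
    f <- function(c0) mean(plogis(c0 + lp)) - event_rate
    if (f(-50) > 0 || f(50) < 0)
      stop("target event rate unattainable with these coefficients",
           call. = FALSE)
    c0 <- uniroot(f, c(-50, 50), tol = 1e-10)$root
    df$mace <- rbinom(n, 1, plogis(c0 + lp))
    if (missingness > 0) {
      for (col in c("hr2v_sampen", "hr2v_apen", "hr2v1_apen")) {
        idx <- runif(n) < missingness
        df[[col]][idx] <- NA_real_
      }
    }
    attr(df, "true_coefficients") <-
      c("(Intercept)" = c0 - sum(beta * colMeans(X)), beta)
    attr(df, "linear_predictor_center") <- mean(drop(X %*% beta))
    df
  })
}
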