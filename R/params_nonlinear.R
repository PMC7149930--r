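#' Poincare plot descriptors SD1 and SD2
#'
#' SD1 is the root-mean-square distance of the lag-1 scatter
#' (x\[i\], x\[i+1\]) from the line of identity, which equals
#' `rmssd/sqrt(2)` exactly. SD2 is derived from the variance decomposition
#' `SD1^2 + SD2^2 = 2 * SDNN^2`, truncated at zero.
#'
#' @param seq interval sequence (ms).
#' @param sd_type variance convention for the SDNN entering SD2.
#' @return named list `SD1`, `SD2` (ms).
#' @export
poincare_sd <- function(seq, sd_type = c("sample", "population")) {
  x <- seq_intervals(seq)
  if (length(x) < 3L) stop("need >= 3 intervals", call. = FALSE)
  sd_type <- match.arg(sd_type)
  sd1 <- rmssd(x) / sqrt(2)
  sd2 <- sqrt(max(0, 2 * sdnn(x, sd_type)^2 - sd1^2))
  list(SD1 = sd1, SD2 = sd2)
}

embed_templates <- function(x, m) {
  N <- length(x)
  k <- N - m + 1L
  mat <- matrix(0, k, m)
  for (j in seq_len(m)) mat[, j] <- x[j:(j + k - 1L)]
  mat
}

cheb_dist_mat <- function(tpl) {
  k <- nrow(tpl)
  d <- matrix(0, k, k)
  for (j in seq_len(ncol(tpl)))
    d <- pmax(d, abs(outer(tpl[, j], tpl[, j], "-")))
  d
}

#' Approximate entropy
#'
#' Standard ApEn with Chebyshev distance and self-matches included:
#' `phi(m) - phi(m+1)` where `phi(m)` is the mean log of the fraction of
#' templates within tolerance `r` of each length-m template. The tolerance is
#' `r_frac` times the SD of the analysed sequence, so the statistic is
#' invariant to affine rescaling of the intervals.
#'
#' @param seq interval sequence (ms).
#' @param m_dim embedding dimension (default 2).
#' @param r_frac tolerance as a fraction of the sequence SD (default 0.2).
#' @param sd_type variance convention for the tolerance scale.
#' @return dimensionless scalar >= 0.
#' @export
apen <- function(seq, m_dim = 2, r_frac = 0.2,
                 sd_type = c("sample", "population")) {
  x <- seq_intervals(seq)
  m_dim <- as.integer(m_dim)
  if (length(x) < m_dim + 2L) stop("sequence too short for ApEn", call. = FALSE)
  s <- sdnn(x, match.arg(sd_type))
  if (s == 0) return(0)
  r <- r_frac * s
  phi <- function(m) {
    d <- cheb_dist_mat(embed_templates(x, m))
    mean(log(rowSums(d <= r) / nrow(d)))
  }
  phi(m_dim) - phi(m_dim + 1L)
}

#' Sample entropy
#'
#' `-ln(A/B)` where B and A count template pairs (self-matches excluded,
#' Chebyshev distance <= r) of lengths m and m+1, both over the first
#' `N - m` templates. When no length-(m+1) pair matches (A = 0) the statistic
#' is undefined on this record: `NA` is returned with the attribute
#' `undefined = TRUE` rather than an arbitrary large sentinel, and downstream
#' code must treat it as missing.
#'
#' @inheritParams apen
#' @return dimensionless scalar, or `NA` (attribute `undefined = TRUE`).
#' @export
sampen <- function(seq, m_dim = 2, r_frac = 0.2,
                   sd_type = c("sample", "population")) {
  x <- seq_intervals(seq)
  m_dim <- as.integer(m_dim)
  N <- length(x)
  if (N < m_dim + 2L) stop("sequence too short for SampEn", call. = FALSE)
  s <- sdnn(x, match.arg(sd_type))
  if (s == 0) return(0)   # all templates match: A = B > 0, -ln(1) = 0
  r <- r_frac * s
  k <- N - m_dim          # number of templates of both lengths
  count_pairs <- function(m) {
    d <- cheb_dist_mat(embed_templates(x, m)[seq_len(k), , drop = FALSE])
    (sum(d <= r) - k) / 2
  }
  B <- count_pairs(m_dim)
  A <- count_pairs(m_dim + 1L)
  if (A == 0 || B == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  -log(A / B)
}

dfa_fluctuation <- function(y, s) {
  nbox <- length(y) %/% s
  if (nbox < 1L) return(NA_real_)
  ymat <- matrix(y[seq_len(nbox * s)], nrow = s)
  X <- cbind(1, seq_len(s))
  res <- ymat - X %*% qr.coef(qr(X), ymat)
  sqrt(mean(res^2))
}

#' Detrended fluctuation analysis
#'
#' Integrates the mean-centred sequence, detrends it linearly in
#' non-overlapping boxes of each scale, and fits the log-log slope of the RMS
#' fluctuation over the short-range (`scales1`, default 4-16 beats, alpha1)
#' and long-range (`scales2`, default 16-64 beats, alpha2) windows. When the
#' sequence is shorter than four times the largest requested scale the scale
#' range is restricted with a warning; if no long-range scale is usable,
#' `alpha2` is `NA`.
#'
#' @param seq interval sequence (ms).
#' @param scales1,scales2 integer vectors of box sizes (beats).
#' @return named list `alpha1`, `alpha2`.
#' @export
dfa <- function(seq, scales1 = 4:16, scales2 = 16:64) {
  x <- seq_intervals(seq)
  N <- length(x)
  if (N < 4 * max(scales2)) {
    keep1 <- scales1[scales1 <= N %/% 4]
    keep2 <- scales2[scales2 <= N %/% 4]
    if (length(keep1) < length(scales1) || length(keep2) < length(scales2))
      warning("series length ", N, " restricts DFA scales", call. = FALSE)
    scales1 <- keep1; scales2 <- keep2
  }
  slope <- function(scales) {
    if (length(scales) < 2L) return(NA_real_)
    Fs <- vapply(scales, function(s) dfa_fluctuation(y, s), 0)
    ok <- is.finite(Fs) & Fs > 0
    if (sum(ok) < 2L) return(NA_real_)
    unname(coef(lm.fit(cbind(1, log(scales[ok])), log(Fs[ok])))[2])
  }
  y <- cumsum(x - mean(x))
  a1 <- slope(scales1)
  a2 <- slope(scales2)
  if (is.na(a2)) warning("insufficient length for DFA alpha2", call. = FALSE)
  list(alpha1 = a1, alpha2 = a2)
}

#' Full nonlinear panel for one sequence
#'
#' @param seq interval sequence.
#' @param cfg an [hrnv_config()].
#' @return named list `SD1`, `SD2`, `SampEn`, `ApEn`, `DFA_alpha1`,
#'   `DFA_alpha2`; the attribute `sampen_undefined` is `TRUE` when SampEn had
#'   no length-(m+1) matches.
#' @export
nonlinear_domain <- function(seq, cfg = hrnv_config()) {
  x <- seq_intervals(seq)
  ps <- poincare_sd(x, cfg$sd_type)
  se <- sampen(x, cfg$entropy_m, cfg$entropy_r_frac, cfg$sd_type)
  dd <- withCallingHandlers(
    dfa(x, cfg$dfa_scales1, cfg$dfa_scales2),
    warning = function(w) invokeRestart("muffleWarning"))
  out <- list(SD1 = ps$SD1, SD2 = ps$SD2,
              SampEn = as.numeric(se),
              ApEn = apen(x, cfg$entropy_m, cfg$entropy_r_frac, cfg$sd_type),
              DFA_alpha1 = dd$alpha1, DFA_alpha2 = dd$alpha2)
  attr(out, "sampen_undefined") <- isTRUE(attr(se, "undefined"))
  out
}
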