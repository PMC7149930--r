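#' Analysis configuration
#'
#' Bundles every tunable of the parameter panel. Defaults follow the common
#' conventions of short-term HRV analysis; each is documented with its unit.
#'
#' @param n_max upper limit of the composite window length n (default 3,
#'   appropriate for 5-6 minute recordings).
#' @param vlf,lf,hf numeric length-2 band edges in Hz. Bands are half-open on
#'   the left: VLF (0, 0.04], LF (0.04, 0.15], HF (0.15, 0.4]. Edges are not
#'   rescaled with n.
#' @param entropy_m embedding dimension for approximate/sample entropy.
#' @param entropy_r_frac tolerance as a fraction of the SD of the analysed
#'   sequence (so composite sequences get composite-scale tolerance).
#' @param dfa_scales1,dfa_scales2 integer box-size ranges (beats) over which
#'   the short- and long-range DFA slopes are fitted.
#' @param tri_bin_width histogram bin width for the triangular index, ms.
#'   Default 1000/128 = 7.8125 ms; not scaled with n.
#' @param sd_type `"sample"` (denominator N-1) or `"population"` (N) for
#'   SDNN and the SD feeding Poincare SD2 and the entropy tolerance.
#' @param pnn_denominator `"intervals"` (count of composite intervals, the
#'   default) or `"pairs"` (count of successive differences) for pNN50 and
#'   pNN50n.
#' @param kurtosis_type `"pearson"` (normal -> 3, the default) or `"excess"`
#'   (normal -> 0).
#' @param psd_ofac oversampling factor of the Lomb-Scargle frequency grid
#'   relative to the fundamental 1/T.
#' @return An object of class `hrnv_config` (a named list).
#' @export
hrnv_config <- function(n_max = 3,
                        vlf = c(0, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.4),
                        entropy_m = 2, entropy_r_frac = 0.2,
                        dfa_scales1 = 4:16, dfa_scales2 = 16:64,
                        tri_bin_width = 1000 / 128,
                        sd_type = c("sample", "population"),
                        pnn_denominator = c("intervals", "pairs"),
                        kurtosis_type = c("pearson", "excess"),
                        psd_ofac = 4) {
  edges <- c(vlf, lf, hf)
  if (any(diff(c(vlf[1], vlf[2], lf[2], hf[2])) <= 0) ||
      vlf[2] != lf[1] || lf[2] != hf[1])
    stop("band edges must be strictly increasing and contiguous", call. = FALSE)
  if (tri_bin_width <= 0) stop("'tri_bin_width' must be > 0", call. = FALSE)
  structure(list(
    n_max = as.integer(n_max),
    vlf = vlf, lf = lf, hf = hf,
    entropy_m = as.integer(entropy_m),
    entropy_r_frac = entropy_r_frac,
    dfa_scales1 = as.integer(dfa_scales1),
    dfa_scales2 = as.integer(dfa_scales2),
    tri_bin_width = tri_bin_width,
    sd_type = match.arg(sd_type),
    pnn_denominator = match.arg(pnn_denominator),
    kurtosis_type = match.arg(kurtosis_type),
    psd_ofac = psd_ofac
  ), class = "hrnv_config")
}

#' @export
print.hrnv_config <- function(x, ...) {
  cat("<hrnv_config>\n")
  cat(sprintf("  n_max %d | bands VLF (%g,%g] LF (%g,%g] HF (%g,%g] Hz\n",
              x$n_max, x$vlf[1], x$vlf[2], x$lf[1], x$lf[2], x$hf[1], x$hf[2]))
  cat(sprintf("  entropy m=%d r=%.2f*SD | DFA scales %d-%d / %d-%d | tri bin %.4f ms\n",
              x$entropy_m, x$entropy_r_frac,
              min(x$dfa_scales1), max(x$dfa_scales1),
              min(x$dfa_scales2), max(x$dfa_scales2), x$tri_bin_width))
  cat(sprintf("  SD type %s | pNN denominator %s | kurtosis %s\n",
              x$sd_type, x$pnn_denominator, x$kurtosis_type))
  invisible(x)
}

seq_intervals <- function(seq) {
  if (is_rr_series(seq)) seq$intervals else as.numeric(seq)
}
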