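param_panel_names <- function(n) {
  base <- c("MeanNN", "SDNN", "RMSSD", "Skewness", "Kurtosis",
            "TriangularIndex", "NN50", "pNN50")
  scaled <- c("NN50n", "pNN50n")
  freq <- c("TotalPower", "VLFPower", "LFPower", "HFPower",
            "LFPowerNorm", "HFPowerNorm", "LF_HF")
  nl <- c("SD1", "SD2", "SampEn", "ApEn", "DFA_alpha1", "DFA_alpha2")
  if (n == 1L) c(base, freq, nl) else c(base, scaled, freq, nl)
}

#' Full HRnV parameter panel for one sequence
#'
#' Computes the complete time-domain, frequency-domain and nonlinear panel on
#' one (possibly composite) interval sequence: 21 parameters for the
#' conventional series (n = 1) and 23 for composite sequences, which add the
#' scaled NN50n/pNN50n pair.
#'
#' @param seq an `hrnv_series` (or an [rr_series()], treated as n = 1).
#' @param cfg an [hrnv_config()].
#' @return Named numeric vector; attribute `flags` is a character vector of
#'   quality flags (currently `"sampen_undefined"` when sample entropy had no
#'   template matches).
#' @examples
#' rr <- simulate_rr(seed = 1)
#' p <- hrnv_params(rr_ni(rr, 2))
#' head(p)
#' @export
hrnv_params <- function(seq, cfg = hrnv_config()) {
  n <- if (inherits(seq, "hrnv_series")) seq$n else 1L
  td <- time_domain(seq, cfg)
  fd <- freq_domain(seq, cfg)
  nl <- nonlinear_domain(seq, cfg)
  all <- c(td, fd, nl)
  keep <- param_panel_names(n)
  out <- unlist(all[keep])
  flags <- character(0)
  if (isTRUE(attr(nl, "sampen_undefined"))) flags <- c(flags, "sampen_undefined")
  attr(out, "flags") <- flags
  out
}

#' Wide HRnV parameter profile of a record
#'
#' Enumerates every sequence up to `cfg$n_max` with [hrnv_sequences()] and
#' computes the full panel on each, returning one wide row with columns named
#' `{label}_{parameter}` (e.g. `HR2V1_SampEn`). With `n_max = 3` this is the
#' six-sequence family and 21 + 5 x 23 = 136 parameter columns. Parameters
#' that are undefined on a record are `NA` and the reason is recorded in the
#' `flags` column (semicolon-separated).
#'
#' @param rr an [rr_series()].
#' @param cfg an [hrnv_config()].
#' @return One-row `data.frame` with `source_id`, all parameter columns, and
#'   a trailing `flags` character column.
#' @export
hrnv_profile <- function(rr, cfg = hrnv_config()) {
  stopifnot(is_rr_series(rr))
  seqs <- hrnv_sequences(rr, cfg$n_max)
  cols <- list()
  flags <- character(0)
  for (s in seqs) {
    p <- hrnv_params(s, cfg)
    fl <- attr(p, "flags")
    if (length(fl)) flags <- c(flags, paste0(s$label, ":", fl))
    names(p) <- paste0(s$label, "_", names(p))
    cols <- c(cols, as.list(p))
  }
  out <- data.frame(source_id = rr$source_id, cols,
                    flags = paste(flags, collapse = ";"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out
}
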