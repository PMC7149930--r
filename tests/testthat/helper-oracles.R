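# Independent brute-force oracles, deliberately written as naive loops so
# they share no code path with the package implementations.

bf_rrnim <- function(x, n, m) {
  out <- numeric(0)
  start <- 1
  while (start + n - 1 <= length(x)) {
    out <- c(out, sum(x[start:(start + n - 1)]))
    start <- start + m
  }
  out
}

bf_sampen <- function(x, m, r) {
  N <- length(x)
  k <- N - m
  countm <- 0; countm1 <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r)
        countm <- countm + 1
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r)
        countm1 <- countm1 + 1
    }
  }
  if (countm1 == 0 || countm == 0) return(NA_real_)
  -log(countm1 / countm)
}

bf_apen <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    k <- N - mm + 1
    acc <- 0
    for (i in seq_len(k)) {
      cnt <- 0
      for (j in seq_len(k)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) cnt <- cnt + 1
      }
      acc <- acc + log(cnt / k)
    }
    acc / k
  }
  phi(m) - phi(m + 1)
}

# AUC as the Mann-Whitney concordance probability by exhaustive pair counting
bf_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

bf_moment <- function(x, k) mean((x - mean(x))^k)

# spectrally synthesized 1/f^beta noise (for DFA slope checks)
synth_powerlaw <- function(n, beta) {
  f <- seq_len(n %/% 2)
  amp <- f^(-beta / 2)
  phase <- runif(length(f), 0, 2 * pi)
  spec <- complex(modulus = c(0, amp, rev(amp[seq_len(n - length(f) - 1)])),
                  argument = c(0, phase, -rev(phase[seq_len(n - length(f) - 1)])))
  Re(fft(spec, inverse = TRUE))
}

random_rr_intervals <- function(len, lo = 400, hi = 1200) {
  runif(len, lo, hi)
}
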