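match_beats <- function(detected, truth, tol = 0.05) {
  hits <- vapply(truth, function(b) any(abs(detected - b) <= tol), TRUE)
  fp <- vapply(detected, function(b) all(abs(truth - b) > tol), TRUE)
  list(recall = mean(hits), n_fp = sum(fp))
}

test_that("beat detection recovers a clean fixed-rate rhythm", {
  rr <- rr_series(rep(60000 / 75, 420))  # 75 bpm, ~5.6 min
  ecg <- simulate_ecg(rr, fs = 250)
  beats <- detect_beats(ecg)
  bpm <- 60 / mean(diff(beats))
  expect_equal(bpm, 75, tolerance = 1 / 75)  # within 1 bpm
})

test_that("detector F1 is high across 50-120 bpm on clean signal", {
  for (bpm in c(50, 80, 120)) {
    rr <- simulate_rr(mean_nn = 60000 / bpm, lf_amp = 15, hf_amp = 10,
                      jitter_sd = 5, duration = 120, seed = bpm)
    ecg <- simulate_ecg(rr)
    truth <- attr(ecg, "beat_times")
    det <- detect_beats(ecg)
    m <- match_beats(det, truth)
    precision <- 1 - m$n_fp / length(det)
    f1 <- 2 * precision * m$recall / (precision + m$recall)
    expect_gte(f1, 0.98)
  }
})

test_that("detection survives additive noise at 10 dB SNR", {
  rr <- simulate_rr(duration = 120, seed = 41)
  ecg <- simulate_ecg(rr, fs = 250, snr_db = 10, seed = 42)
  truth <- attr(ecg, "beat_times")
  det <- detect_beats(ecg)
  expect_gte(match_beats(det, truth, tol = 0.05)$recall, 0.95)
})

test_that("flat or saturated traces are rejected", {
  expect_error(detect_beats(ecg_trace(rep(0, 5000), 250)), "unusable")
  expect_error(detect_beats(ecg_trace(rep(1, 5000), 250)), "unusable")
  rr <- rr_series(rep(800, 20))
  expect_error(detect_beats(ecg_trace(simulate_ecg(rr)$samples, 50)), "fs")
})

test_that("ECG synthesis round-trips through the detector within 2 samples", {
  for (fs in c(250, 500)) {
    rr <- simulate_rr(duration = 60, jitter_sd = 15, seed = 43)
    ecg <- simulate_ecg(rr, fs = fs)
    det <- detect_beats(ecg)
    truth <- attr(ecg, "beat_times")
    # every true beat matched within 2 samples
    err <- vapply(truth, function(b) min(abs(det - b)), 0)
    expect_lte(max(err), 2 / fs + 1e-9)
  }
})

test_that("interval recovery is sampling-rate independent", {
  rr <- simulate_rr(duration = 60, seed = 44)
  iv250 <- diff(detect_beats(simulate_ecg(rr, fs = 250))) * 1000
  iv500 <- diff(detect_beats(simulate_ecg(rr, fs = 500))) * 1000
  n <- min(length(iv250), length(iv500))
  expect_lt(max(abs(iv250[1:n] - iv500[1:n])), 10)  # ms
})

test_that("clean_nn keeps clean series intact and excises ectopic couplets", {
  rr <- simulate_rr(duration = 300, seed = 45)
  beats <- c(0, rr$t_end) / 1000
  nn <- clean_nn(beats)
  expect_equal(attr(nn, "fraction_removed"), 0)
  expect_equal(nn$intervals, rr$intervals)

  ect <- simulate_rr(duration = 300, ectopic_rate = 1, seed = 46)
  idx <- attr(ect, "ground_truth")$ectopic_index
  nn2 <- clean_nn(c(0, ect$t_end) / 1000)
  expect_gt(attr(nn2, "fraction_removed"), 0)
  # both members of each short-long couplet are gone
  near <- function(a, b) vapply(a, function(v) any(abs(b - v) < 1e-6), TRUE)
  bad <- ect$intervals[sort(c(idx, idx + 1L))]
  expect_false(any(near(bad, nn2$intervals)))
  # the surviving intervals are a subset of the original normal ones
  expect_true(all(near(nn2$intervals, ect$intervals[-c(idx, idx + 1L)])))
})

test_that("clean_nn is idempotent and rejects heavy corruption", {
  ect <- simulate_rr(duration = 300, ectopic_rate = 2, seed = 47)
  nn <- clean_nn(c(0, ect$t_end) / 1000)
  again <- clean_nn(c(0, cumsum(nn$intervals)) / 1000)
  expect_equal(again$intervals, nn$intervals)
  expect_equal(attr(again, "fraction_removed"), 0)

  set.seed(48)
  x <- rep(800, 200)
  corrupt <- sample(200, 60)
  x[corrupt] <- runif(60, 100, 3000)
  expect_error(clean_nn(c(0, cumsum(x)) / 1000), "non-sinus")
})
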