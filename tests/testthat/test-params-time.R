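toy <- c(800, 810, 790, 805, 795, 820)

test_that("mean, SDNN and RMSSD match hand-computed values", {
  expect_equal(mean_nn(c(1610, 1595, 1615)), 4820 / 3)
  expect_equal(mean_nn(800), 800)
  expect_equal(sdnn(toy), 10.80123, tolerance = 1e-6)
  expect_equal(sdnn(rep(700, 10)), 0)
  expect_equal(rmssd(toy), sqrt((100 + 400 + 225 + 100 + 625) / 5),
               tolerance = 1e-12)
  expect_equal(rmssd(c(640, 700)), 60)
  expect_error(sdnn(800), ">= 2")
  expect_error(mean_nn(numeric(0)), "empty")
})

test_that("mean/SDNN/RMSSD are absolutely homogeneous under scaling", {
  set.seed(21)
  x <- random_rr_intervals(60)
  for (k in c(0.5, 2, 3.7)) {
    expect_equal(mean_nn(k * x), k * mean_nn(x))
    expect_equal(sdnn(k * x), k * sdnn(x))
    expect_equal(rmssd(k * x), k * rmssd(x))
  }
})

test_that("NN50 family counts thresholded successive differences", {
  r <- nn50_stats(c(1610, 1500, 1615, 1612), n = 2)
  expect_equal(r$nn50, 2)          # |-110| and |115| exceed 50; |-3| does not
  expect_equal(r$pnn50, 100 * 2 / 4)
  expect_equal(r$nn50n, 2)         # threshold 100 ms
  expect_equal(r$pnn50n, 50)
  const <- nn50_stats(rep(900, 10), n = 3)
  expect_equal(unlist(const), c(nn50 = 0, pnn50 = 0, nn50n = 0, pnn50n = 0))
  # n = 1: scaled variants are not reported
  r1 <- nn50_stats(toy, n = 1)
  expect_true(is.na(r1$nn50n) && is.na(r1$pnn50n))
  # pairs denominator option
  rp <- nn50_stats(c(1610, 1500, 1615, 1612), n = 2, pnn_denominator = "pairs")
  expect_equal(rp$pnn50, 100 * 2 / 3)
  # threshold is strictly "exceeds"
  expect_equal(nn50_stats(c(800, 850, 800), n = 1)$nn50, 0)
  expect_equal(nn50_stats(c(800, 850.01, 800), n = 1)$nn50, 2)
})

test_that("NN50n never exceeds NN50 and pNN50 stays within [0,100]", {
  set.seed(22)
  for (rep in 1:50) {
    x <- random_rr_intervals(sample(10:200, 1))
    n <- sample(2:4, 1)
    r <- nn50_stats(x, n = n)
    expect_lte(r$nn50n, r$nn50)
    expect_gte(r$pnn50, 0); expect_lte(r$pnn50, 100)
    expect_gte(r$pnn50n, 0); expect_lte(r$pnn50n, 100)
  }
})

test_that("skewness and kurtosis use standardized central moments", {
  expect_equal(hrnv:::skewness_p(c(790, 800, 810)), 0)
  x <- c(1, 1, 1, 10)
  m2 <- bf_moment(x, 2)
  expect_equal(hrnv:::skewness_p(x), bf_moment(x, 3) / m2^1.5)
  expect_equal(hrnv:::kurtosis_p(x), bf_moment(x, 4) / m2^2)      # Pearson
  expect_equal(hrnv:::kurtosis_p(x, "excess"), bf_moment(x, 4) / m2^2 - 3)
  set.seed(23)
  z <- rnorm(2e5)
  expect_equal(hrnv:::kurtosis_p(z), 3, tolerance = 0.05)
  expect_warning(out <- hrnv:::skewness_p(rep(5, 10)), "undefined")
  expect_true(is.na(out))
})

test_that("triangular index is count over modal bin occupancy", {
  expect_equal(triangular_index(rep(800, 7)), 1)          # all in one bin
  # 10 elements, modal bin holds 4
  x <- c(rep(800, 4), 850, 870, 890, 910, 930, 950)
  expect_equal(triangular_index(x), 10 / 4)
  # uniform spread, one per bin
  x2 <- seq(500, 500 + 9 * 50, by = 50)
  expect_equal(triangular_index(x2), 10)
})

test_that("time-domain panel agrees with naive loops on random series", {
  set.seed(24)
  for (rep in 1:100) {
    x <- random_rr_intervals(sample(5:100, 1))
    expect_equal(mean_nn(x), sum(x) / length(x), tolerance = 1e-9)
    expect_equal(sdnn(x), sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
                 tolerance = 1e-9)
    d <- x[-1] - x[-length(x)]
    expect_equal(rmssd(x), sqrt(sum(d * d) / length(d)), tolerance = 1e-9)
    expect_equal(nn50_stats(x, n = 1)$nn50, sum(abs(d) > 50))
  }
})

test_that("parameters ignore a constant time offset", {
  rr <- rr_series(toy)
  shifted <- rr_series(toy, t_end = rr$t_end + 5000)
  expect_equal(time_domain(rr), time_domain(shifted))
})
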