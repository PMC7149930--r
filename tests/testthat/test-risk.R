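test_that("troponin encoding is the 0/1/2 step function on ng/mL", {
  expect_identical(encode_troponin(0.02), 0L)
  expect_identical(encode_troponin(0.03), 0L)   # boundary inclusive
  expect_identical(encode_troponin(0.05), 1L)
  expect_identical(encode_troponin(0.09), 1L)   # exactly 3x the limit
  expect_identical(encode_troponin(0.10), 2L)
  expect_error(encode_troponin(-0.01), ">= 0")
  # total and monotone on a grid
  grid <- seq(0, 1, by = 0.001)
  codes <- vapply(grid, encode_troponin, 0L)
  expect_true(all(diff(codes) >= 0))
})

test_that("univariable screen reproduces the 2x2 cross-product odds ratio", {
  # reference cohort male-sex split: 188/247 events vs 354/548 non-events
  sex <- c(rep(1, 188), rep(0, 59), rep(1, 354), rep(0, 194))
  mace <- c(rep(1, 247), rep(0, 548))
  res <- univariable_screen(data.frame(sex = sex, mace = mace),
                            "mace", "sex")
  or_direct <- (188 * 194) / (59 * 354)
  expect_equal(res$table$or, or_direct, tolerance = 1e-6)
  expect_equal(or_direct, 1.746, tolerance = 1e-3)
  expect_true("sex" %in% res$selected)
})

test_that("screen flags separation and passes null predictors through", {
  set.seed(61)
  y <- rbinom(300, 1, 0.3)
  d <- data.frame(mace = y, perfect = y, noise = rnorm(300))
  expect_warning(res <- univariable_screen(d, "mace", c("perfect", "noise")),
                 "separation")
  expect_true("perfect" %in% res$separated)
  expect_false("perfect" %in% res$selected)
  # under the null the OR is near 1 for large n
  set.seed(62)
  d2 <- data.frame(mace = rbinom(5000, 1, 0.3), x = rnorm(5000))
  r2 <- univariable_screen(d2, "mace", "x")
  expect_equal(r2$table$or, 1, tolerance = 0.1)
  expect_error(univariable_screen(data.frame(mace = y, k = rep(1, 300)),
                                  "mace", "k"), "distinct")
})

test_that("backward stepwise retains signal and prunes noise", {
  set.seed(63)
  n <- 3000
  d <- data.frame(x_true = rnorm(n), replicate(6, rnorm(n)))
  names(d)[-1] <- paste0("null", 1:6)
  lp <- -1 + 1.2 * d$x_true
  d$mace <- rbinom(n, 1, plogis(lp))
  sw <- stepwise_backward(d, "mace", setdiff(names(d), "mace"))
  expect_true("x_true" %in% sw$selected)
  # retained nulls must individually pass the stopping threshold
  cf <- summary(sw$fit)$coefficients
  pv <- cf[setdiff(rownames(cf), "(Intercept)"), "Pr(>|z|)"]
  expect_true(all(pv <= 0.05 + 1e-12))
  # empty candidate set: intercept-only model
  sw0 <- stepwise_backward(d, "mace", character(0))
  expect_equal(length(coef(sw0$fit)), 1L)
  expect_equal(plogis(coef(sw0$fit)[[1]]), mean(d$mace), tolerance = 1e-6)
})

test_that("stepwise false-retention under the all-null model is modest", {
  set.seed(64)
  keeps <- replicate(40, {
    d <- data.frame(replicate(5, rnorm(400)))
    names(d) <- paste0("x", 1:5)
    d$mace <- rbinom(400, 1, 0.3)
    length(stepwise_backward(d, "mace", paste0("x", 1:5))$selected)
  })
  # with alpha = 0.05 and 5 null candidates, expect ~0.25 kept per run
  expect_lt(mean(keeps), 0.8)
})

test_that("LOOCV probabilities equal manual refits on a tiny dataset", {
  d <- data.frame(x = c(0.1, 0.5, 0.9, 0.3, 0.7, 0.2, 0.8, 0.4),
                  mace = c(0, 1, 1, 0, 1, 0, 1, 0))
  probs <- loocv_probs(d, "mace", "x")
  for (i in seq_len(nrow(d))) {
    fit <- glm(mace ~ x, family = binomial(), data = d[-i, ])
    expect_equal(probs[i],
                 unname(predict(fit, d[i, ], type = "response")),
                 tolerance = 1e-6)
  }
})

test_that("LOOCV separates separable data and is null on shuffled outcomes", {
  set.seed(65)
  n <- 400
  d <- data.frame(x = rnorm(n))
  d$mace <- as.integer(d$x > 0)
  p <- suppressWarnings(loocv_probs(d, "mace", "x"))
  expect_gt(roc_analysis(p, d$mace)$auc, 0.99)
  d$shuffled <- sample(d$mace)
  p0 <- loocv_probs(d, "shuffled", "x")
  auc0 <- roc_analysis(p0, d$shuffled)$auc
  expect_gt(auc0, 0.4); expect_lt(auc0, 0.6)
})

test_that("ROC analysis matches exhaustive pair counting and scans", {
  scores <- c(0.1, 0.2, 0.4, 0.35, 0.8, 0.7)
  y <- c(0, 0, 1, 0, 1, 1)
  r <- roc_analysis(scores, y)
  expect_equal(r$auc, bf_auc(scores, y), tolerance = 1e-12)
  # one discordant positive-negative pair out of nine
  scores2 <- c(0.1, 0.2, 0.3, 0.35, 0.8, 0.7)
  r2 <- roc_analysis(scores2, y)
  expect_equal(r2$auc, 8 / 9, tolerance = 1e-12)
  expect_equal(r2$auc, bf_auc(scores2, y), tolerance = 1e-12)
  # degenerate and error cases
  expect_error(roc_analysis(scores, rep(1, 6)), "both classes")
  perfect <- roc_analysis(y, y)
  expect_equal(perfect$auc, 1)
  op <- perfect$operating_points$optimal
  expect_equal(unname(op$sensitivity["p"]), 1)
  expect_equal(unname(op$specificity["p"]), 1)

  set.seed(66)
  for (rep in 1:100) {
    n <- sample(6:25, 1)
    s <- round(runif(n), 2)           # ties on purpose
    yy <- rbinom(n, 1, 0.5)
    if (length(unique(yy)) < 2) next
    rr <- roc_analysis(s, yy)
    expect_equal(rr$auc, bf_auc(s, yy), tolerance = 1e-12)
    # optimal cut-off minimizes distance to (0,1) over an exhaustive scan
    d2 <- vapply(rr$thresholds, function(ct) {
      sens <- sum(s >= ct & yy == 1) / sum(yy == 1)
      spec <- sum(s < ct & yy == 0) / sum(yy == 0)
      (1 - sens)^2 + (1 - spec)^2
    }, 0)
    opt_d2 <- {
      sens <- sum(s >= rr$optimal_cutoff & yy == 1) / sum(yy == 1)
      spec <- sum(s < rr$optimal_cutoff & yy == 0) / sum(yy == 0)
      (1 - sens)^2 + (1 - spec)^2
    }
    expect_equal(opt_d2, min(d2), tolerance = 1e-12)
  }
})

test_that("random scores give chance-level AUC with a covering DeLong CI", {
  set.seed(67)
  s <- runif(2000); y <- rbinom(2000, 1, 0.4)
  r <- roc_analysis(s, y)
  expect_equal(r$auc, 0.5, tolerance = 0.05)
  expect_true(r$auc_ci["lo"] < 0.5 && r$auc_ci["hi"] > 0.5)
})

test_that("DeLong CI agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(68)
  s <- rnorm(300); y <- rbinom(300, 1, plogis(s))
  r <- roc_analysis(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(unname(r$auc_ci["lo"]), ci[1], tolerance = 1e-6)
  expect_equal(unname(r$auc_ci["hi"]), ci[3], tolerance = 1e-6)
})

test_that("the full pipeline discriminates with signal and not without", {
  coh <- simulate_cohort(n_patients = 600, seed = 69)
  m <- fit_mace_model(coh)
  expect_gt(m$roc$auc, 0.85)
  expect_s3_class(m, "mace_model")
  expect_true(all(m$stepwise$selected %in% m$screen$selected))
  # CI brackets the OR for every reported variable
  tb <- m$stepwise$table
  expect_true(all(tb$ci_lo <= tb$or & tb$or <= tb$ci_hi))
  # predict method round-trips
  pr <- predict(m, coh[1:5, ])
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("strict per-fold selection runs and reports a valid AUC", {
  set.seed(70)
  d <- data.frame(x1 = rnorm(60), x2 = rnorm(60))
  d$mace <- rbinom(60, 1, plogis(-0.5 + 1.5 * d$x1))
  m <- suppressWarnings(
    fit_mace_model(d, candidates = c("x1", "x2"), cv = "strict"))
  expect_true(m$roc$auc >= 0 && m$roc$auc <= 1)
  expect_length(m$cv_probs, length(m$rows))
})

test_that("entropy missingness is imputed or dropped as configured", {
  coh <- simulate_cohort(n_patients = 800, missingness = 0.05, seed = 71)
  m <- fit_mace_model(coh)
  expect_true("hr2v_sampen" %in% m$imputed ||
              "hr2v_sampen" %in% m$dropped_missing)
  coh2 <- simulate_cohort(n_patients = 800, missingness = 0.2, seed = 72)
  m2 <- fit_mace_model(coh2)
  expect_true("hr2v_sampen" %in% m2$dropped_missing)
})
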