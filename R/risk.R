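#' Encode a troponin value into the 0/1/2 risk code
#'
#' High-sensitivity troponin-T with normal limit 0.03 ng/mL: code 0 when the
#' value is <= 0.03, code 1 when it is between one and three times the limit
#' (0.03, 0.09], and code 2 above three times the limit (> 0.09).
#'
#' @param value troponin concentration (ng/mL), >= 0.
#' @param normal_limit upper limit of normal (ng/mL).
#' @return integer code 0, 1 or 2.
#' @examples
#' encode_troponin(0.02)  # 0
#' encode_troponin(0.10)  # 2
#' @export
encode_troponin <- function(value, normal_limit = 0.03) {
  if (!is.finite(value) || value < 0)
    stop("troponin value must be >= 0", call. = FALSE)
  if (value <= normal_limit) 0L
  else if (value <= 3 * normal_limit) 1L
  else 2L
}

wald_or_row <- function(fit, var) {
  cf <- summary(fit)$coefficients
  if (!var %in% rownames(cf)) return(NULL)
  est <- cf[var, "Estimate"]; se <- cf[var, "Std. Error"]
  data.frame(variable = var, or = exp(est),
             ci_lo = exp(est - qnorm(0.975) * se),
             ci_hi = exp(est + qnorm(0.975) * se),
             p = cf[var, "Pr(>|z|)"],
             stringsAsFactors = FALSE)
}

#' Univariable logistic screening
#'
#' Fits one single-predictor logistic regression per candidate and reports
#' the Wald odds ratio, 95% CI and p-value. Candidates with p below
#' `alpha_in` (default 0.2) are passed forward. Variables exhibiting
#' (quasi-)complete separation are flagged and excluded with a warning.
#'
#' @param data cohort `data.frame`.
#' @param outcome name of the binary 0/1 outcome column.
#' @param candidates character vector of predictor column names.
#' @param alpha_in inclusion threshold on the univariable p-value.
#' @return list with `table` (one row per candidate: OR, CI, p, flag),
#'   `selected` (names with p < alpha_in) and `separated` (flagged names).
#' @export
univariable_screen <- function(data, outcome, candidates, alpha_in = 0.2) {
  stopifnot(outcome %in% names(data), all(candidates %in% names(data)))
  y <- data[[outcome]]
  if (!all(y %in% 0:1)) stop("outcome must be binary 0/1", call. = FALSE)
  rows <- list(); separated <- character(0)
  for (v in candidates) {
    x <- data[[v]]
    ok <- complete.cases(x, y)
    if (length(unique(x[ok])) < 2L)
      stop("candidate '", v, "' has < 2 distinct values", call. = FALSE)
    fit <- suppressWarnings(glm(y[ok] ~ x[ok], family = binomial()))
    row <- wald_or_row(fit, "x[ok]")
    row$variable <- v
    sep <- !fit$converged || abs(coef(fit)[2]) > 15 ||
      summary(fit)$coefficients[2, "Std. Error"] > 100
    row$separation <- sep
    if (sep) {
      separated <- c(separated, v)
      warning("separation detected for '", v, "'; excluded", call. = FALSE)
    }
    rows[[v]] <- row
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  keep <- tab$variable[!tab$separation & tab$p < alpha_in]
  list(table = tab, selected = keep, separated = separated)
}

#' Backward stepwise logistic regression
#'
#' Starts from the full model over `candidates` and repeatedly removes the
#' variable with the largest Wald p-value while that p-value exceeds
#' `alpha_out` (default 0.05). An AIC-based alternative
#' (`criterion = "aic"`, via [stats::step()]) is available. The procedure is
#' deterministic given the data.
#'
#' @param data cohort `data.frame` (complete cases over the used columns are
#'   taken).
#' @param outcome binary outcome column name.
#' @param candidates candidate predictor names; may be empty, giving the
#'   intercept-only model.
#' @param alpha_out removal threshold for the p-based criterion.
#' @param criterion `"p"` (default) or `"aic"`.
#' @param forced names always kept in the model.
#' @return list of class `stepwise_fit`: `fit` (the final `glm`), `table`
#'   (OR/CI/p per retained variable), `selected`, `dropped` (in removal
#'   order), `converged`.
#' @export
stepwise_backward <- function(data, outcome, candidates,
                              alpha_out = 0.05,
                              criterion = c("p", "aic"),
                              forced = character(0)) {
  criterion <- match.arg(criterion)
  stopifnot(outcome %in% names(data))
  vars <- union(candidates, forced)
  df <- data[c(outcome, vars)]
  df <- df[complete.cases(df), , drop = FALSE]
  fit_with <- function(v) {
    fml <- if (length(v)) paste(outcome, "~", paste(v, collapse = " + "))
    else paste(outcome, "~ 1")
    glm(as.formula(fml), family = binomial(), data = df)
  }
  dropped <- character(0)
  if (criterion == "aic") {
    full <- fit_with(vars)
    if (!full$converged) stop("full model did not converge", call. = FALSE)
    low <- fit_with(forced)
    fit <- step(full, direction = "backward", trace = 0,
                scope = list(lower = formula(low), upper = formula(full)))
    keep <- setdiff(attr(terms(fit), "term.labels"), character(0))
    dropped <- setdiff(vars, keep)
  } else {
    keep <- vars
    repeat {
      fit <- fit_with(keep)
      if (!fit$converged)
        stop("stepwise fit did not converge with variables: ",
             paste(keep, collapse = ", "), call. = FALSE)
      droppable <- setdiff(keep, forced)
      if (!length(droppable)) break
      cf <- summary(fit)$coefficients
      pv <- cf[match(droppable, rownames(cf)), "Pr(>|z|)"]
      if (all(is.na(pv))) break
      worst <- droppable[which.max(pv)]
      if (max(pv, na.rm = TRUE) <= alpha_out) break
      keep <- setdiff(keep, worst)
      dropped <- c(dropped, worst)
    }
  }
  tab <- do.call(rbind, lapply(keep, function(v) wald_or_row(fit, v)))
  structure(list(fit = fit, table = tab, selected = keep, dropped = dropped,
                 converged = fit$converged, n = nrow(df)),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("<stepwise_fit> %d of %d candidates retained (n = %d)\n",
              length(x$selected), length(x$selected) + length(x$dropped), x$n))
  if (!is.null(x$table)) {
    tb <- x$table
    tb$or <- sprintf("%.3f", tb$or)
    tb$ci <- sprintf("%.3f-%.3f", tb$ci_lo, tb$ci_hi)
    tb$p <- sprintf("%.4g", tb$p)
    print(tb[c("variable", "or", "ci", "p")], row.names = FALSE)
  }
  invisible(x)
}

#' Leave-one-out cross-validated predicted probabilities
#'
#' For a fixed variable list (selection done once on the full data), refits
#' the logistic model without each patient in turn and predicts that
#' patient's outcome probability. Non-convergent folds are flagged.
#'
#' @param data cohort `data.frame` (complete cases over the used columns).
#' @param outcome binary outcome column name.
#' @param variables model predictor names.
#' @return numeric vector of out-of-fold probabilities (one per retained
#'   row); attributes `rows` (row indices used) and `bad_folds` (indices of
#'   non-convergent folds, normally empty).
#' @export
loocv_probs <- function(data, outcome, variables) {
  df <- data[c(outcome, variables)]
  rows <- which(complete.cases(df))
  df <- df[rows, , drop = FALSE]
  n <- nrow(df)
  y <- df[[outcome]]
  X <- cbind(`(Intercept)` = 1, as.matrix(df[variables]))
  storage.mode(X) <- "double"
  probs <- numeric(n)
  bad <- integer(0)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(
      glm.fit(X[-i, , drop = FALSE], y[-i], family = binomial()))
    if (!fit$converged) bad <- c(bad, i)
    probs[i] <- plogis(drop(X[i, ] %*% fit$coefficients))
  }
  attr(probs, "rows") <- rows
  attr(probs, "bad_folds") <- bad
  probs
}

delong_ci <- function(scores, y, auc, level = 0.95) {
  xs <- scores[y == 1]; ys <- scores[y == 0]
  n1 <- length(xs); n0 <- length(ys)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(xs, function(a) mean(psi(a, ys)), 0)
  v01 <- vapply(ys, function(b) mean(psi(xs, b)), 0)
  se <- sqrt(var(v10) / n1 + var(v01) / n0)
  z <- qnorm(1 - (1 - level) / 2)
  c(lo = max(0, auc - z * se), hi = min(1, auc + z * se), se = se)
}

prop_ci <- function(k, n, level = 0.95) {
  p <- k / n
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(p = p, lo = max(0, p - half), hi = min(1, p + half))
}

operating_point <- function(scores, y, cutoff) {
  pos <- scores >= cutoff
  tp <- sum(pos & y == 1); fp <- sum(pos & y == 0)
  fn <- sum(!pos & y == 1); tn <- sum(!pos & y == 0)
  list(cutoff = cutoff,
       sensitivity = prop_ci(tp, tp + fn),
       specificity = prop_ci(tn, tn + fp),
       ppv = if (tp + fp > 0) prop_ci(tp, tp + fp) else c(p = NA, lo = NA, hi = NA),
       npv = if (tn + fn > 0) prop_ci(tn, tn + fn) else c(p = NA, lo = NA, hi = NA))
}

#' ROC analysis with AUC, DeLong CI and operating-point metrics
#'
#' Builds the empirical ROC curve over all distinct score thresholds
#' (prediction positive when score >= threshold). The AUC is the trapezoidal
#' area, which equals the Mann-Whitney concordance probability; its 95% CI
#' uses the DeLong variance estimator. The optimal cut-off minimizes the
#' Euclidean distance to the perfect-classifier corner (0, 1) in
#' (1 - specificity, sensitivity) space. Sensitivity, specificity, PPV and
#' NPV with Wald binomial CIs are reported at the optimal cut-off and at any
#' additionally requested cut-offs.
#'
#' @param scores real-valued risk scores or probabilities.
#' @param outcome binary 0/1 outcomes, same length; both classes must be
#'   present.
#' @param cutoffs optional extra cut-offs at which to report operating
#'   points.
#' @return Object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity` (curve arrays), `auc`, `auc_ci` (DeLong), `optimal_cutoff`
#'   and `operating_points` (list, first entry at the optimal cut-off).
#' @export
roc_analysis <- function(scores, outcome, cutoffs = NULL) {
  scores <- as.numeric(scores)
  y <- as.integer(outcome)
  ok <- complete.cases(scores, y)
  scores <- scores[ok]; y <- y[ok]
  if (!all(y %in% 0:1) || length(unique(y)) < 2L)
    stop("outcome must contain both classes", call. = FALSE)
  thr <- c(sort(unique(scores)), Inf)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  sens <- vapply(thr, function(ct) sum(scores >= ct & y == 1) / n1, 0)
  spec <- vapply(thr, function(ct) sum(scores < ct & y == 0) / n0, 0)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  xs <- fpr[ord]; ys <- sens[ord]
  auc <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  ci <- delong_ci(scores, y, auc)
  d2 <- (1 - sens)^2 + fpr^2
  opt <- thr[which.min(d2)]
  pts <- lapply(c(opt, cutoffs), function(ct) operating_point(scores, y, ct))
  names(pts) <- c("optimal", if (length(cutoffs)) paste0("cutoff_", cutoffs))
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, auc_ci = ci, optimal_cutoff = opt,
                 operating_points = pts, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$auc_ci["lo"], x$auc_ci["hi"], x$n_pos, x$n_neg))
  op <- x$operating_points$optimal
  cat(sprintf("  optimal cut-off %.4g: sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
              op$cutoff, 100 * op$sensitivity["p"], 100 * op$specificity["p"],
              100 * op$ppv["p"], 100 * op$npv["p"]))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(1 - x$specificity, x$sensitivity, type = "l",
       xlab = "1 - specificity", ylab = "Sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}
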