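impute_candidates <- function(df, candidates, max_missing = 0.1) {
  dropped <- character(0); imputed <- character(0)
  for (v in candidates) {
    miss <- mean(is.na(df[[v]]))
    if (miss == 0) next
    if (miss > max_missing) {
      dropped <- c(dropped, v)
    } else {
      ind <- paste0(v, "_missing")
      df[[ind]] <- as.integer(is.na(df[[v]]))
      df[[v]][is.na(df[[v]])] <- mean(df[[v]], na.rm = TRUE)
      imputed <- c(imputed, v)
    }
  }
  list(data = df, candidates = setdiff(candidates, dropped),
       dropped = dropped, imputed = imputed)
}

#' Fit the chest-pain MACE risk model
#'
#' End-to-end risk-stratification pipeline on a patient feature table:
#' univariable logistic screening (keep p < `alpha_in`), backward stepwise
#' multivariable logistic regression (drop while max Wald p > `alpha_out`),
#' leave-one-out cross-validated predicted probabilities for the selected
#' model, and ROC analysis of those probabilities against the outcome.
#'
#' Candidate columns with missing values (e.g. sample entropy undefined on a
#' short record) are mean-imputed with a missingness indicator when less than
#' 10% missing, and excluded otherwise.
#'
#' In the default `cv = "fixed"` mode, variable selection is performed once
#' on the full data and only the coefficients are re-estimated in each
#' leave-one-out fold; `cv = "strict"` repeats the whole selection inside
#' every fold (slower, optimism-free) and reports that ROC instead.
#'
#' @param data cohort `data.frame` with a binary 0/1 outcome column.
#' @param outcome outcome column name (default `"mace"`).
#' @param candidates candidate predictor names; default: every numeric
#'   column except the outcome.
#' @param alpha_in univariable inclusion threshold (default 0.2).
#' @param alpha_out stepwise removal threshold (default 0.05).
#' @param criterion stepwise criterion, `"p"` or `"aic"`.
#' @param cv `"fixed"` or `"strict"` (see Details), or `"none"` to skip
#'   cross-validation (ROC is then computed on in-sample fitted values).
#' @return Object of class `mace_model` with components `screen`
#'   (univariable table), `stepwise` (the [stepwise_backward()] result),
#'   `fit` (final full-data `glm`), `cv_probs`, `roc` (a
#'   [roc_analysis()] result) and bookkeeping fields.
#' @examples
#' coh <- simulate_cohort(n_patients = 400, seed = 7)
#' m <- fit_mace_model(coh, candidates = c("age", "troponin", "hrv_nn50"))
#' m
#' @export
fit_mace_model <- function(data, outcome = "mace", candidates = NULL,
                           alpha_in = 0.2, alpha_out = 0.05,
                           criterion = c("p", "aic"),
                           cv = c("fixed", "strict", "none")) {
  criterion <- match.arg(criterion)
  cv <- match.arg(cv)
  stopifnot(outcome %in% names(data))
  if (is.null(candidates)) {
    num <- vapply(data, is.numeric, TRUE)
    candidates <- setdiff(names(data)[num], c(outcome, "troponin_ngml"))
  }
  imp <- impute_candidates(data, candidates)
  data <- imp$data
  candidates <- c(imp$candidates, paste0(imp$imputed, "_missing"))
  candidates <- intersect(unique(candidates), names(data))

  screen <- univariable_screen(data, outcome, candidates, alpha_in)
  sw <- stepwise_backward(data, outcome, screen$selected,
                          alpha_out = alpha_out, criterion = criterion)
  y <- data[[outcome]]
  if (cv == "none") {
    probs <- predict(sw$fit, type = "response")
    rows <- as.integer(names(probs))
    if (!length(rows) || anyNA(rows)) rows <- seq_along(probs)
  } else if (cv == "fixed") {
    probs <- loocv_probs(data, outcome, sw$selected)
    rows <- attr(probs, "rows")
  } else {
    df <- data[c(outcome, candidates)]
    rows <- which(complete.cases(df))
    probs <- numeric(length(rows))
    for (k in seq_along(rows)) {
      tr <- data[rows[-k], , drop = FALSE]
      sc <- univariable_screen(tr, outcome, candidates, alpha_in)
      swk <- stepwise_backward(tr, outcome, sc$selected,
                               alpha_out = alpha_out, criterion = criterion)
      probs[k] <- predict(swk$fit, newdata = data[rows[k], , drop = FALSE],
                          type = "response")
    }
  }
  roc <- roc_analysis(as.numeric(probs), y[rows])
  structure(list(screen = screen, stepwise = sw, fit = sw$fit,
                 cv = cv, cv_probs = as.numeric(probs), rows = rows,
                 roc = roc, outcome = outcome,
                 candidates = candidates,
                 dropped_missing = imp$dropped, imputed = imp$imputed),
            class = "mace_model")
}

#' @export
print.mace_model <- function(x, ...) {
  cat("30-day MACE risk model (logistic, backward stepwise)\n")
  cat(sprintf("  %d candidates -> %d screened in -> %d selected\n",
              length(x$candidates), length(x$screen$selected),
              length(x$stepwise$selected)))
  cat(sprintf("  %s cross-validation: AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$cv, x$roc$auc, x$roc$auc_ci["lo"], x$roc$auc_ci["hi"]))
  invisible(x)
}

#' @export
summary.mace_model <- function(object, ...) {
  cat("Selected model (adjusted odds ratios):\n")
  print(object$stepwise)
  cat("\nROC of", object$cv, "cross-validated probabilities:\n")
  print(object$roc)
  invisible(object)
}

#' @export
coef.mace_model <- function(object, ...) coef(object$fit)

#' Predict MACE probabilities for new patients
#'
#' @param object a fitted `mace_model`.
#' @param newdata `data.frame` with the selected predictor columns.
#' @param ... unused.
#' @return numeric vector of predicted probabilities.
#' @export
predict.mace_model <- function(object, newdata, ...) {
  predict(object$fit, newdata = newdata, type = "response")
}
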