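# Downstream risk models and their evaluation.
#
# The classifier is an L2-regularised logistic regression on (St, X2); the
# survival model is a ridge-penalised Cox proportional hazards fit on
# Z = (St, X2) after feature screening, h(t|Z) = h0(t) exp(beta'Z). Their
# validation performance is both the reported outcome and the reward signal
# of the querying agent.

#' Fit the downstream logistic classifier
#'
#' L2-regularised logistic regression of the outcome on the current phenotype
#' vector St plus structured covariates X2. Retrained from scratch at each
#' querying iteration.
#'
#' @param s_current Phenotype feature per patient (binary Strue for labeled,
#'   continuous proxy for unlabeled patients).
#' @param x2 Covariate matrix.
#' @param y Binary outcome (both classes required).
#' @param lambda L2 penalty (default 1).
#' @return Object of class `releap_classifier`.
#' @export
fit_classifier <- function(s_current, x2, y, lambda = 1) {
  x2 <- as.matrix(x2)
  if (length(unique(y)) < 2) stop("outcome has a single class; cannot fit classifier")
  X <- cbind(phenotype = as.numeric(s_current), x2)
  fit <- ridge_logistic(X, y, lambda = lambda)
  structure(list(coef = fit$coef, lambda = lambda,
                 feature_names = colnames(X)), class = "releap_classifier")
}

#' Predict event probabilities from a fitted classifier
#'
#' @param object A `releap_classifier`.
#' @param s_current Phenotype feature of the prediction set.
#' @param x2 Covariates of the prediction set.
#' @param ... Unused.
#' @return Probabilities in [0,1].
#' @export
predict.releap_classifier <- function(object, s_current, x2, ...) {
  X <- cbind(as.numeric(s_current), as.matrix(x2))
  stats::plogis(drop(cbind(1, X) %*% object$coef))
}

#' Specification of the penalized Cox model
#'
#' @param penalty_strength Ridge penalty theta (>= 0).
#' @param screening `"zero-variance"` (drop constant columns only) or
#'   `"univariate"` (additionally cap dimension by univariate Cox score
#'   statistics).
#' @param max_features Dimension cap applied under `"univariate"` screening.
#' @return Object of class `cox_spec`.
#' @export
cox_spec <- function(penalty_strength = 0.1,
                     screening = c("zero-variance", "univariate"),
                     max_features = 50L) {
  stopifnot(penalty_strength >= 0, max_features >= 1)
  structure(list(penalty_strength = penalty_strength,
                 screening = match.arg(screening),
                 max_features = as.integer(max_features)), class = "cox_spec")
}

#' Fit the penalized Cox survival model
#'
#' Ridge-penalised partial-likelihood fit (via [survival::coxph()] with a
#' `ridge()` term) of event times on Z = (St, X2) after the configured
#' feature screening. Returns a risk-score predictor (linear predictor;
#' higher = higher hazard).
#'
#' @param s_current Phenotype feature per patient.
#' @param x2 Covariate matrix.
#' @param t_event Positive event/censoring times.
#' @param event_flag 1 = event observed, 0 = censored (at least one event
#'   required).
#' @param spec A [cox_spec()].
#' @return Object of class `releap_cox` with elements `coef` (named by kept
#'   features) and `kept`.
#' @export
fit_cox <- function(s_current, x2, t_event, event_flag, spec = cox_spec()) {
  stopifnot(inherits(spec, "cox_spec"))
  if (any(t_event <= 0)) stop("event times must be positive")
  if (sum(event_flag) < 1) stop("no observed events; cannot fit Cox model")
  Z <- cbind(phenotype = as.numeric(s_current), as.matrix(x2))
  if (is.null(colnames(Z)) || any(colnames(Z) == "")) {
    colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  }
  keep <- apply(Z, 2, function(col) stats::sd(col) > 1e-12)
  if (!any(keep)) stop("all covariates are constant after screening")
  Z <- Z[, keep, drop = FALSE]
  if (spec$screening == "univariate" && ncol(Z) > spec$max_features) {
    stat <- vapply(seq_len(ncol(Z)), function(j) {
      f <- survival::coxph(survival::Surv(t_event, event_flag) ~ Z[, j])
      abs(f$coefficients[1] / sqrt(f$var[1, 1]))
    }, numeric(1))
    Z <- Z[, order(stat, decreasing = TRUE)[seq_len(spec$max_features)],
           drop = FALSE]
  }
  fit <- survival::coxph(
    survival::Surv(t_event, event_flag) ~
      survival::ridge(Z, theta = spec$penalty_strength, scale = FALSE))
  beta <- stats::setNames(as.numeric(fit$coefficients), colnames(Z))
  structure(list(coef = beta, kept = colnames(Z), spec = spec),
            class = "releap_cox")
}

#' Predict Cox risk scores
#'
#' @param object A `releap_cox`.
#' @param s_current Phenotype feature of the prediction set.
#' @param x2 Covariates of the prediction set.
#' @param ... Unused.
#' @return Real-valued risk score per patient (higher = higher hazard).
#' @export
predict.releap_cox <- function(object, s_current, x2, ...) {
  Z <- cbind(phenotype = as.numeric(s_current), as.matrix(x2))
  if (is.null(colnames(Z)) || any(colnames(Z) == "")) {
    colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  }
  drop(Z[, object$kept, drop = FALSE] %*% object$coef)
}

#' Classification metrics at a fixed false-positive rate
#'
#' Computes AUC by the rank (Mann-Whitney) formulation with midrank tie
#' correction, probability MSE (`mean((p - y)^2)`, a Brier-type calibration
#' score), and threshold metrics at an operating point fixed by the false
#' positive rate: the cutoff is the smallest observed probability whose
#' empirical FPR is <= 0.1 (no interpolation), i.e. the threshold achieving
#' the largest attainable FPR not exceeding 0.1. TPR, PPV and F1 are
#' evaluated there; if no cutoff keeps FPR <= 0.1, no patient is called
#' positive and TPR = PPV = F1 = 0.
#'
#' @param probs Predicted probabilities.
#' @param y Binary outcomes (both classes required).
#' @param iteration Iteration index stored in the report.
#' @param fpr_cap Maximum allowed empirical false positive rate (default 0.1).
#' @return Object of class `metrics_report`: fields `auc`, `f1`,
#'   `tpr_at_fpr10`, `ppv_at_fpr10`, `prob_mse`, `c_index` (NA here),
#'   `iteration`.
#' @export
evaluate_classification <- function(probs, y, iteration = 0L, fpr_cap = 0.1) {
  y <- as.integer(y)
  if (length(probs) != length(y)) stop("probs and y lengths differ")
  if (length(unique(y)) < 2) stop("y has a single class; metrics undefined")
  np <- sum(y == 1); nn <- sum(y == 0)
  r <- rank(probs)  # midranks handle ties
  auc <- (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
  prob_mse <- mean((probs - y)^2)

  neg <- probs[y == 0]
  cand <- sort(unique(probs))
  fpr <- vapply(cand, function(c) mean(neg >= c), numeric(1))
  ok <- which(fpr <= fpr_cap)
  if (length(ok)) {
    thr <- cand[min(ok)]
    pred <- probs >= thr
  } else {
    pred <- rep(FALSE, length(probs))
  }
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  tpr <- tp / np
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (ppv + tpr > 0) 2 * ppv * tpr / (ppv + tpr) else 0
  structure(list(auc = auc, f1 = f1, tpr_at_fpr10 = tpr, ppv_at_fpr10 = ppv,
                 prob_mse = prob_mse, c_index = NA_real_,
                 iteration = as.integer(iteration)),
            class = "metrics_report")
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs (the patient with the earlier observed event
#' versus a patient with a later time) in which the earlier-event patient has
#' the higher predicted risk; risk ties count 0.5. Computed with
#' [survival::concordance()].
#'
#' @param risk_scores Real-valued risk per patient (higher = higher hazard).
#' @param t_event Event/censoring times.
#' @param event_flag Event indicator.
#' @return C-index in [0,1].
#' @export
evaluate_survival <- function(risk_scores, t_event, event_flag) {
  cf <- survival::concordance(
    survival::Surv(t_event, event_flag) ~ risk_scores, reverse = TRUE)
  pairs <- sum(cf$count[c("concordant", "discordant", "tied.x")])
  if (!is.finite(cf$concordance) || pairs == 0) {
    stop("no comparable pairs; C-index undefined")
  }
  unname(cf$concordance)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "iter %d | AUC %.4f | F1 %.4f | TPR@FPR0.1 %.4f | PPV@FPR0.1 %.4f | MSE %.4f | C %.4f\n",
    x$iteration, x$auc, x$f1, x$tpr_at_fpr10, x$ppv_at_fpr10, x$prob_mse,
    x$c_index))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(iteration = x$iteration, auc = x$auc, f1 = x$f1,
             tpr_at_fpr10 = x$tpr_at_fpr10, ppv_at_fpr10 = x$ppv_at_fpr10,
             prob_mse = x$prob_mse, c_index = x$c_index)
}
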