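# Synthetic cohort simulator.
#
# Generates patient-level cohorts with the generative structure
#   X1 -> Strue -> S*   and   (Strue, X2) -> Y,
# i.e. structured features X1 drive a binary reference phenotype Strue, the
# observable proxy score S* is a degraded readout of the same X1 signal, and
# the clinical outcome Y (with a parallel event time T) depends on the true
# phenotype plus additional covariates X2. The proxy degradation is one-sided:
# a fraction (1 - proxy_sensitivity) of true-positive patients have their X1
# signal hidden before scoring, mimicking code-based under-ascertainment of
# behavioural phenotypes (e.g. ~30% self-reported smokers vs ~10% of patients
# carrying any smoking diagnosis code).

#' Configuration for a synthetic cohort
#'
#' @param n_patients Number of patients (>= 100).
#' @param dim_x1 Number of proxy-signal features X1.
#' @param dim_x2 Number of outcome covariates X2.
#' @param outcome_prevalence Target marginal P(Y = 1), strictly in (0,1).
#' @param phenotype_prevalence Target marginal P(Strue = 1), strictly in (0,1).
#' @param proxy_sensitivity Fraction of true-positive patients whose X1 signal
#'   is visible to the proxy score; in (0, 1]. Values below 1 create one-sided
#'   label noise (under-ascertainment).
#' @param proxy_noise_sd SD of additive Gaussian noise on the proxy logit.
#' @param effect_strue_on_y Log-odds effect of the true phenotype on the
#'   outcome (also used as the log-hazard effect for event times).
#' @param censoring_rate Fraction of patients administratively censored,
#'   in [0, 1).
#' @param seed Master integer seed; every random field draws from an
#'   independent sub-stream derived from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 20000L,
                          dim_x1 = 5L,
                          dim_x2 = 4L,
                          outcome_prevalence = 0.10,
                          phenotype_prevalence = 0.30,
                          proxy_sensitivity = 1 / 3,
                          proxy_noise_sd = 0.5,
                          effect_strue_on_y = 1.5,
                          censoring_rate = 0.7,
                          seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 100) {
    stop("n_patients must be >= 100")
  }
  stopifnot(dim_x1 >= 1, dim_x2 >= 1)
  stopifnot_scalar_prob(outcome_prevalence, "outcome_prevalence")
  stopifnot_scalar_prob(phenotype_prevalence, "phenotype_prevalence")
  stopifnot_scalar_prob(proxy_sensitivity, "proxy_sensitivity", open_right = FALSE)
  stopifnot(is.numeric(proxy_noise_sd), proxy_noise_sd >= 0)
  stopifnot(is.numeric(effect_strue_on_y), is.finite(effect_strue_on_y))
  stopifnot_scalar_prob(censoring_rate, "censoring_rate", open_left = FALSE)
  structure(list(
    n_patients = as.integer(n_patients),
    dim_x1 = as.integer(dim_x1),
    dim_x2 = as.integer(dim_x2),
    outcome_prevalence = outcome_prevalence,
    phenotype_prevalence = phenotype_prevalence,
    proxy_sensitivity = proxy_sensitivity,
    proxy_noise_sd = proxy_noise_sd,
    effect_strue_on_y = effect_strue_on_y,
    censoring_rate = censoring_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Preset cohort configurations over the prevalence sweep
#'
#' Convenience presets at outcome prevalences 1%, 10%, and 30%.
#'
#' @param preset One of `"rare"` (1%), `"mid"` (10%), `"common"` (30%).
#' @param ... Further arguments passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
cohort_preset <- function(preset = c("rare", "mid", "common"), ...) {
  preset <- match.arg(preset)
  prev <- c(rare = 0.01, mid = 0.10, common = 0.30)[[preset]]
  cohort_config(outcome_prevalence = prev, ...)
}

#' Calibrate a logistic intercept to a target prevalence
#'
#' Finds the intercept `a` such that `mean(plogis(a + linear_predictor))`
#' equals `target_prevalence`, by monotone root finding.
#'
#' @param target_prevalence Target marginal probability, strictly in (0,1).
#' @param linear_predictor Finite numeric vector of per-patient predictors.
#' @return The calibrated intercept (scalar); achieved prevalence is within
#'   1e-6 of the target.
#' @examples
#' calibrate_intercept(0.5, rep(0, 10))   # 0
#' calibrate_intercept(0.1, rep(0, 10))   # log(1/9)
#' @export
calibrate_intercept <- function(target_prevalence, linear_predictor) {
  stopifnot_scalar_prob(target_prevalence, "target_prevalence")
  if (!is.numeric(linear_predictor) || length(linear_predictor) == 0 ||
      any(!is.finite(linear_predictor))) {
    stop("linear_predictor must be a nonempty finite numeric vector")
  }
  f <- function(a) mean(stats::plogis(a + linear_predictor)) - target_prevalence
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) {
    stop(sprintf(
      "intercept calibration failed: cannot bracket target prevalence %.6g",
      target_prevalence))
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  if (abs(f(root)) > 1e-6) {
    stop(sprintf(
      "intercept calibration failed: residual %.3g at target prevalence %.6g",
      f(root), target_prevalence))
  }
  root
}

# Internal: exponential event times with administrative censoring at the
# empirical quantile achieving the configured censoring rate.
simulate_survival <- function(eta, censoring_rate, seed, base_rate = 0.01) {
  t_raw <- with_seed(seed, stats::rexp(length(eta), rate = base_rate * exp(eta)))
  horizon <- stats::quantile(t_raw, probs = 1 - censoring_rate, names = FALSE)
  event_flag <- as.integer(t_raw <= horizon)
  if (all(event_flag == 0)) stop("degenerate cohort: all patients censored")
  list(t_event = pmin(t_raw, horizon), event_flag = event_flag,
       horizon = horizon)
}

# Internal: alternating-sign covariate effects for X2, declared once.
x2_effects <- function(dim_x2) 0.5 * (-1)^(seq_len(dim_x2) + 1)

#' Generate a synthetic cohort
#'
#' Draws a cohort under the structure `X1 -> Strue -> S*`,
#' `(Strue, X2) -> Y`:
#' * `X1` i.i.d. standard normal;
#' * `Strue ~ Bernoulli(plogis(a1 + u'X1))` with `a1` calibrated so the
#'   empirical phenotype prevalence matches the target;
#' * `S*` follows the chain `Strue -> S*`: an observable code signal equals
#'   the phenotype for a `proxy_sensitivity` fraction of true positives and
#'   is absent otherwise (one-sided under-ascertainment, never for true
#'   negatives); the proxy is `plogis` of a calibrated intercept plus the
#'   signal plus Gaussian logit noise, so the noiseless fully sensitive limit
#'   separates `Strue` perfectly;
#' * `Y ~ Bernoulli(plogis(a2 + effect*Strue + b'X2))` with `a2` calibrated to
#'   the outcome prevalence;
#' * `T` exponential with log-hazard `effect*Strue + b'X2`, administratively
#'   censored at the empirical quantile giving `censoring_rate`.
#'
#' Fully reproducible: each random field uses an independent sub-stream of the
#' config seed.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort`: a list with `patient_id`, matrices
#'   `x1`, `x2`, and vectors `s_proxy`, `s_true`, `y`, `t_event`,
#'   `event_flag`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  d1 <- config$dim_x1
  d2 <- config$dim_x2
  seed <- config$seed

  x1 <- with_seed(substream_seed(seed, "x1"),
                  matrix(stats::rnorm(n * d1), n, d1))
  x2 <- with_seed(substream_seed(seed, "x2"),
                  matrix(stats::rnorm(n * d2), n, d2))
  colnames(x1) <- paste0("x1_", seq_len(d1) - 1L)
  colnames(x2) <- paste0("x2_", seq_len(d2) - 1L)

  # Phenotype: logit linear in X1 with unit direction u, slope 1.5.
  u <- rep(1.5 / sqrt(d1), d1)
  lp_phen <- drop(x1 %*% u)
  a1 <- calibrate_intercept(config$phenotype_prevalence, lp_phen)
  s_true <- with_seed(substream_seed(seed, "strue"),
                      stats::rbinom(n, 1, stats::plogis(a1 + lp_phen)))

  # Proxy: the observable signal is the phenotype as seen through recorded
  # codes — visible for a proxy_sensitivity fraction of true positives, never
  # for true negatives (one-sided under-ascertainment) — scored with additive
  # logit noise and an intercept calibrated to the phenotype prevalence.
  visible <- with_seed(substream_seed(seed, "mask"),
                       stats::runif(n) < config$proxy_sensitivity)
  signal <- 4 * as.numeric(s_true == 1 & visible)
  noise <- if (config$proxy_noise_sd > 0) {
    with_seed(substream_seed(seed, "noise"),
              stats::rnorm(n, 0, config$proxy_noise_sd))
  } else rep(0, n)
  ap <- calibrate_intercept(config$phenotype_prevalence, signal)
  s_proxy <- stats::plogis(ap + signal + noise)

  # Outcome: logit linear in (Strue, X2).
  b2 <- x2_effects(d2)
  lp_out <- config$effect_strue_on_y * s_true + drop(x2 %*% b2)
  a2 <- calibrate_intercept(config$outcome_prevalence, lp_out)
  y <- with_seed(substream_seed(seed, "y"),
                 stats::rbinom(n, 1, stats::plogis(a2 + lp_out)))

  surv <- simulate_survival(lp_out, config$censoring_rate,
                            substream_seed(seed, "t"))

  structure(list(
    patient_id = seq_len(n),
    x1 = x1, x2 = x2,
    s_proxy = s_proxy,
    s_true = as.integer(s_true),
    y = as.integer(y),
    t_event = surv$t_event,
    event_flag = surv$event_flag,
    config = config,
    horizon = surv$horizon
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d+%d features\n",
              length(x$patient_id), ncol(x$x1), ncol(x$x2)))
  cat(sprintf("  phenotype prevalence %.3f | outcome prevalence %.4f | events %.3f\n",
              mean(x$s_true), mean(x$y), mean(x$event_flag)))
  invisible(x)
}

#' Synthetic fixture cohort with published health-system marginals
#'
#' A small synthetic cohort whose marginals are calibrated to published
#' summary statistics of a large US academic health-system lung-cancer
#' cohort: outcome (incident lung cancer) prevalence 0.78%, fraction of
#' patients carrying at least one smoking-related diagnosis code 9.0%, and
#' never-smoker fraction 52.7% (so the reference phenotype "ever smoker" has
#' prevalence 47.3%). `X1` columns are sparse binary code indicators; the
#' proxy score is the fitted probability of an in-cohort L2 logistic
#' regression of the reference phenotype on the code indicators, mirroring a
#' code-only proxy model. This is a synthetic stand-in: no real patient data
#' are used or reproduced.
#'
#' @param seed Integer seed.
#' @param n Number of patients (default 20000).
#' @param dim_x1 Number of code-indicator columns.
#' @param dim_x2 Number of additional covariates.
#' @return A `cohort` object.
#' @export
ehr_fixture_cohort <- function(seed = 1L, n = 20000L, dim_x1 = 5L, dim_x2 = 4L) {
  stopifnot(n >= 1000)
  never_frac <- 0.527     # never-smoker fraction
  icd_cov <- 0.090        # any smoking code, overall
  out_prev <- 0.0078      # incident lung cancer
  p_true <- 1 - never_frac
  p0 <- 0.005             # false-positive code rate among never-smokers
  p1 <- (icd_cov - (1 - p_true) * p0) / p_true  # code coverage among smokers

  s_true <- with_seed(substream_seed(seed, "fix_strue"),
                      stats::rbinom(n, 1, p_true))
  any_code <- with_seed(substream_seed(seed, "fix_code"),
                        stats::rbinom(n, 1, ifelse(s_true == 1, p1, p0)))
  x1 <- matrix(0L, n, dim_x1, dimnames = list(NULL, paste0("x1_", seq_len(dim_x1) - 1L)))
  coded <- which(any_code == 1)
  if (length(coded)) {
    x1[cbind(coded, with_seed(substream_seed(seed, "fix_primary"),
                              sample.int(dim_x1, length(coded), replace = TRUE)))] <- 1L
    extra <- with_seed(substream_seed(seed, "fix_extra"),
                       matrix(stats::rbinom(length(coded) * dim_x1, 1, 0.3),
                              length(coded), dim_x1))
    x1[coded, ] <- pmax(x1[coded, , drop = FALSE], extra)
  }

  # Code-only proxy model, applied to all patients.
  fit <- ridge_logistic(x1, s_true, lambda = 1)
  s_proxy <- predict_ridge_logistic(fit, x1)

  x2 <- with_seed(substream_seed(seed, "fix_x2"),
                  matrix(stats::rnorm(n * dim_x2), n, dim_x2))
  colnames(x2) <- paste0("x2_", seq_len(dim_x2) - 1L)

  b2 <- x2_effects(dim_x2)
  eff <- 2.0  # log-odds of the phenotype on the outcome
  lp_out <- eff * s_true + drop(x2 %*% b2)
  a2 <- calibrate_intercept(out_prev, lp_out)
  y <- with_seed(substream_seed(seed, "fix_y"),
                 stats::rbinom(n, 1, stats::plogis(a2 + lp_out)))
  surv <- simulate_survival(lp_out, censoring_rate = 1 - out_prev,
                            seed = substream_seed(seed, "fix_t"))

  structure(list(
    patient_id = seq_len(n),
    x1 = x1, x2 = x2,
    s_proxy = s_proxy,
    s_true = as.integer(s_true),
    y = as.integer(y),
    t_event = surv$t_event,
    event_flag = surv$event_flag,
    config = NULL,
    horizon = surv$horizon
  ), class = "cohort")
}

#' Convert a cohort to a flat data frame
#'
#' @param x A `cohort`.
#' @param ... Unused.
#' @return Data frame with one row per patient and columns `patient_id`,
#'   `x1_*`, `x2_*`, `s_proxy`, `s_true`, `y`, `t_event`, `event_flag`.
#' @export
as.data.frame.cohort <- function(x, ...) {
  data.frame(patient_id = x$patient_id, x$x1, x$x2,
             s_proxy = x$s_proxy, s_true = x$s_true, y = x$y,
             t_event = x$t_event, event_flag = x$event_flag)
}

#' Write a cohort to a delimited file
#'
#' @param cohort A `cohort`.
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from a delimited file
#'
#' Inverse of [write_cohort()]: expects a header row with columns
#' `patient_id`, `x1_*`, `x2_*`, `s_proxy`, `s_true`, `y`, `t_event`,
#' `event_flag`.
#'
#' @param path CSV path.
#' @return A `cohort` object.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  need <- c("patient_id", "s_proxy", "s_true", "y", "t_event", "event_flag")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort file missing columns: ", paste(miss, collapse = ", "))
  x1_cols <- grep("^x1_", names(df), value = TRUE)
  x2_cols <- grep("^x2_", names(df), value = TRUE)
  if (!length(x1_cols) || !length(x2_cols)) {
    stop("cohort file must contain x1_* and x2_* feature columns")
  }
  structure(list(
    patient_id = df$patient_id,
    x1 = as.matrix(df[x1_cols]),
    x2 = as.matrix(df[x2_cols]),
    s_proxy = df$s_proxy,
    s_true = as.integer(df$s_true),
    y = as.integer(df$y),
    t_event = df$t_event,
    event_flag = as.integer(df$event_flag),
    config = NULL,
    horizon = max(df$t_event)
  ), class = "cohort")
}
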