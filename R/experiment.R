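# Benchmark harness: comparator arms, replications, aggregation, subgroups.
#
# Within a replication every method receives the identical outcome-stratified
# split and balanced seed set (a paired design), so differences between arms
# are not attributable to split variation. Replication r derives all of its
# seeds from master_seed XOR r.

#' Experiment configuration
#'
#' @param cohort A `cohort`, a [cohort_config()] (the cohort is generated
#'   once and shared by all replications, which re-split it), or a path to a
#'   cohort CSV.
#' @param methods Comparator arms, a subset of `proxy_only`, `oracle`,
#'   `random`, `uncertainty`, `diversity`, `qbc`, `releap`. The name
#'   `aphrodite` is reserved for a weak-supervision comparator that requires
#'   clinical notes and NLP concept extraction; requesting it raises an
#'   explanatory error.
#' @param n_replications Number of independent replications (default 10);
#'   each re-splits the cohort with a different seed.
#' @param budget_total Total reference labels queried per replication
#'   (excluding the seed set).
#' @param batch_size_k Labels queried per iteration.
#' @param seed_set_size Size of the initial balanced seed set (even).
#' @param train_fraction Training fraction of the outcome-stratified split.
#' @param run_mode `"classification"`, `"survival"`, or `"both"`.
#' @param mirror_validation Mirror replacement dynamics on the validation
#'   set.
#' @param subgroup Optional name of a grouping variable for subgroup
#'   reporting (resolved against the cohort data frame by [run_method()]
#'   consumers; see [subgroup_evaluate()]).
#' @param master_seed Master integer seed.
#' @param classifier_lambda L2 penalty of the downstream classifier.
#' @param cox A [cox_spec()].
#' @param qbc A [qbc_config()].
#' @param ppo A [ppo_config()].
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              methods = c("proxy_only", "oracle", "random",
                                          "uncertainty", "diversity", "qbc",
                                          "releap"),
                              n_replications = 10L,
                              budget_total = 4000L,
                              batch_size_k = 200L,
                              seed_set_size = 200L,
                              train_fraction = 0.8,
                              run_mode = c("classification", "survival",
                                           "both"),
                              mirror_validation = TRUE,
                              subgroup = NULL,
                              master_seed = 1L,
                              classifier_lambda = 1,
                              cox = cox_spec(),
                              qbc = qbc_config(),
                              ppo = ppo_config()) {
  run_mode <- match.arg(run_mode)
  if (length(methods) == 0) stop("methods must be nonempty")
  known <- c("proxy_only", "oracle", "random", "uncertainty", "diversity",
             "qbc", "releap", "aphrodite")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown methods: ", paste(bad, collapse = ", "))
  stopifnot(n_replications >= 1, budget_total >= 1, batch_size_k >= 1,
            seed_set_size >= 2)
  structure(list(cohort = cohort, methods = methods,
                 n_replications = as.integer(n_replications),
                 budget_total = as.integer(budget_total),
                 batch_size_k = as.integer(batch_size_k),
                 seed_set_size = as.integer(seed_set_size),
                 train_fraction = train_fraction, run_mode = run_mode,
                 mirror_validation = mirror_validation, subgroup = subgroup,
                 master_seed = as.integer(master_seed),
                 classifier_lambda = classifier_lambda, cox = cox, qbc = qbc,
                 ppo = ppo), class = "experiment_config")
}

#' Desk-scale preset configuration
#'
#' A benchmark configuration sized for a single workstation: cohort of
#' 20 000 patients, budget 4000 queried in batches of 200 over a balanced
#' seed set of 200, 5 replications — preserving roughly the same ~43%
#' training-pool budget fraction as a full-scale run with a 238k cohort and
#' an 82k budget.
#'
#' @param ... Overrides passed to [experiment_config()].
#' @return An `experiment_config`.
#' @export
desk_preset <- function(...) {
  args <- list(...)
  defaults <- list(cohort = cohort_config(n_patients = 20000L),
                   n_replications = 5L, budget_total = 4000L,
                   batch_size_k = 200L, seed_set_size = 200L)
  do.call(experiment_config, utils::modifyList(defaults, args))
}

resolve_cohort <- function(cohort) {
  if (inherits(cohort, "cohort")) return(cohort)
  if (inherits(cohort, "cohort_config")) return(generate_cohort(cohort))
  if (is.character(cohort) && length(cohort) == 1) return(read_cohort(cohort))
  stop("cohort must be a cohort, a cohort_config, or a file path")
}

#' Run a single comparator arm
#'
#' Executes one method for one replication: `proxy_only` fits the downstream
#' models once on S0 = S* with zero queries; `oracle` fits once with Strue
#' everywhere (a fully supervised upper bound, invariant to the budget);
#' `random` queries uniformly without replacement; `uncertainty`,
#' `diversity`, and `qbc` run the episode loop with the corresponding
#' one-hot mixture; `releap` runs the policy-learning loop. All arms share
#' the replication's split and seed set.
#'
#' @param method Arm name (see [experiment_config()]).
#' @param cohort A `cohort` (or config/path, resolved once).
#' @param config An `experiment_config`.
#' @param replication Replication number (>= 1); seeds derive from
#'   `master_seed XOR replication`.
#' @param frozen_weights Optional simplex 3-vector freezing the `releap`
#'   policy (diagnostic use).
#' @return List of class `replication_result` with `method`, `replication`,
#'   `metrics` (per-iteration data frame), `final` (last row), `queries`,
#'   `trajectory`, `predictions`.
#' @export
run_method <- function(method, cohort, config, replication = 1L,
                       frozen_weights = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (identical(method, "aphrodite")) {
    stop("the 'aphrodite' comparator requires clinical notes and NLP concept ",
         "features, which synthetic cohorts do not contain; it is excluded")
  }
  if (!method %in% c("proxy_only", "oracle", "random", "uncertainty",
                     "diversity", "qbc", "releap")) {
    stop("unknown method: ", method)
  }
  cohort <- resolve_cohort(cohort)
  rep_seed <- bitwXor(config$master_seed, as.integer(replication))
  split <- stratified_split(cohort, config$train_fraction, seed = rep_seed)
  fit_survival <- config$run_mode != "classification"

  if (method %in% c("proxy_only", "oracle")) {
    tr <- split$train; va <- split$validation
    s_tr <- if (method == "oracle") cohort$s_true[tr] else cohort$s_proxy[tr]
    s_va <- if (method == "oracle") cohort$s_true[va] else cohort$s_proxy[va]
    model <- fit_classifier(s_tr, cohort$x2[tr, , drop = FALSE], cohort$y[tr],
                            lambda = config$classifier_lambda)
    probs <- predict(model, s_va, cohort$x2[va, , drop = FALSE])
    rep0 <- evaluate_classification(probs, cohort$y[va], iteration = 0L)
    risk <- NULL
    if (fit_survival) {
      cx <- fit_cox(s_tr, cohort$x2[tr, , drop = FALSE], cohort$t_event[tr],
                    cohort$event_flag[tr], spec = config$cox)
      risk <- predict(cx, s_va, cohort$x2[va, , drop = FALSE])
      rep0$c_index <- evaluate_survival(risk, cohort$t_event[va],
                                        cohort$event_flag[va])
    }
    metrics <- as.data.frame(rep0)
    res <- list(metrics = metrics, trajectory = NULL, queries = list(),
                label_state = NULL, params = NULL,
                predictions = list(probs = probs, risk = risk,
                                   y = cohort$y[va], val_idx = va,
                                   val_upgraded = rep(method == "oracle",
                                                      length(va))))
  } else {
    state <- init_seed_set(cohort, split$train, config$seed_set_size,
                           config$budget_total, config$batch_size_k,
                           seed = rep_seed)
    res <- run_episode(cohort, split, state, method = method,
                       frozen_weights = frozen_weights,
                       qbc_cfg = config$qbc, ppo_cfg = config$ppo,
                       run_mode = config$run_mode,
                       mirror_validation = config$mirror_validation,
                       classifier_lambda = config$classifier_lambda,
                       cox = config$cox, seed = rep_seed)
  }
  metrics <- res$metrics
  metrics$method <- method
  metrics$replication <- as.integer(replication)
  structure(list(method = method, replication = as.integer(replication),
                 metrics = metrics, final = metrics[nrow(metrics), ],
                 queries = res$queries, trajectory = res$trajectory,
                 predictions = res$predictions, label_state = res$label_state,
                 params = res$params),
            class = "replication_result")
}

#' Run all configured methods over all replications
#'
#' Replication r re-splits the cohort (seeds derived from
#' `master_seed XOR r`); all methods within a replication share the split
#' and seed set.
#'
#' @param config An `experiment_config`.
#' @param progress Print a line per completed arm.
#' @return List of class `experiment_results` with `results` (list of
#'   `replication_result`), `metrics` (combined data frame), and `config`.
#' @export
run_replications <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- resolve_cohort(config$cohort)
  results <- list()
  for (r in seq_len(config$n_replications)) {
    for (m in config$methods) {
      res <- run_method(m, cohort, config, replication = r)
      results[[length(results) + 1]] <- res
      if (progress) {
        message(sprintf("replication %d | %-12s | final AUC %.4f", r, m,
                        res$final$auc))
      }
    }
  }
  structure(list(results = results,
                 metrics = do.call(rbind, lapply(results, `[[`, "metrics")),
                 config = config),
            class = "experiment_results")
}

#' Aggregate replication metrics with 95% confidence intervals
#'
#' Per method and iteration, reports the mean of each metric across
#' replications with a normal-approximation 95% CI
#' (`mean +/- 1.96 * SD / sqrt(R)`). With a single replication the CI is
#' reported as `NA` rather than fabricated.
#'
#' @param results An `experiment_results`, or the combined metrics data
#'   frame.
#' @return Long-format data frame: `method`, `iteration`, `metric`, `mean`,
#'   `ci_low`, `ci_high`, `n`.
#' @export
aggregate_results <- function(results) {
  df <- if (inherits(results, "experiment_results")) results$metrics else results
  stopifnot(is.data.frame(df), all(c("method", "iteration") %in% names(df)))
  metric_cols <- intersect(
    c("auc", "f1", "tpr_at_fpr10", "ppv_at_fpr10", "prob_mse", "c_index"),
    names(df))
  out <- list()
  for (key in split(df, list(df$method, df$iteration), drop = TRUE)) {
    for (mc in metric_cols) {
      vals <- key[[mc]][is.finite(key[[mc]])]
      if (!length(vals)) next
      n <- length(vals)
      se <- if (n >= 2) stats::sd(vals) / sqrt(n) else NA_real_
      out[[length(out) + 1]] <- data.frame(
        method = key$method[1], iteration = key$iteration[1], metric = mc,
        mean = mean(vals),
        ci_low = if (n >= 2) mean(vals) - 1.96 * se else NA_real_,
        ci_high = if (n >= 2) mean(vals) + 1.96 * se else NA_real_,
        n = n)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$method, res$iteration, res$metric), , drop = FALSE]
}

#' Recompute validation metrics within subgroups
#'
#' Uses the stored final validation predictions of a `replication_result` to
#' recompute metrics within each level of a grouping vector. Groups whose
#' outcome has a single class are skipped with a warning.
#'
#' @param result A `replication_result`.
#' @param group_labels Grouping vector, either one value per validation
#'   patient or one per cohort patient (indexed by the stored validation
#'   indices).
#' @return Data frame with one row per evaluable group.
#' @export
subgroup_evaluate <- function(result, group_labels) {
  stopifnot(inherits(result, "replication_result"))
  pred <- result$predictions
  if (is.null(pred)) stop("result carries no stored predictions")
  n_val <- length(pred$y)
  g <- if (length(group_labels) == n_val) group_labels
       else group_labels[pred$val_idx]
  if (length(g) != n_val || anyNA(g)) {
    stop("every validation patient needs a non-missing group label")
  }
  rows <- list()
  for (lev in unique(g)) {
    sel <- g == lev
    if (length(unique(pred$y[sel])) < 2) {
      warning(sprintf("subgroup '%s' has a single outcome class; skipped", lev))
      next
    }
    rep <- evaluate_classification(pred$probs[sel], pred$y[sel],
                                   iteration = result$final$iteration)
    row <- as.data.frame(rep)
    row$group <- lev
    row$n <- sum(sel)
    rows[[length(rows) + 1]] <- row
  }
  if (!length(rows)) stop("no evaluable subgroups")
  do.call(rbind, rows)
}
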