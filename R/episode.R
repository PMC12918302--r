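# The query-episode loop.
#
# Each iteration performs, in order: strategy scoring on the unlabeled pool,
# state construction, action selection (policy sample, frozen mixture, or
# random), label acquisition for the top-k composite, downstream retraining,
# validation evaluation, and reward computation. Episodes terminate when the
# labeling budget is exhausted (H = ceil(budget / k) iterations, the final
# batch possibly short). The same weighting scheme is mirrored on the
# validation set: at every iteration a proportional number of validation
# patients (k_val = round(k * |val| / |train|)), ranked by the same composite
# score, have their phenotype feature upgraded from the proxy to the
# reference value, so training and validation evolve under comparable
# replacement dynamics.

#' Run one querying episode
#'
#' @param cohort A `cohort`.
#' @param split List with `train` and `validation` cohort indices
#'   (see [stratified_split()]).
#' @param label_state Initial `label_state` (see [init_seed_set()]).
#' @param method One of `"releap"` (policy-driven), `"uncertainty"`,
#'   `"diversity"`, `"qbc"` (fixed one-hot mixtures), or `"random"`.
#' @param frozen_weights Optional fixed simplex 3-vector overriding the
#'   policy (used for the fixed-strategy arms and for freezing the agent).
#' @param params Policy parameters for `method = "releap"`; initialised
#'   automatically when `NULL`.
#' @param qbc_cfg Committee configuration ([qbc_config()]); its seed is
#'   re-derived per iteration from `seed`.
#' @param ppo_cfg PPO configuration ([ppo_config()]).
#' @param run_mode `"classification"`, `"survival"`, or `"both"`; selects
#'   which downstream models are fit and which validation metric drives the
#'   reward (AUC for classification/both, C-index for survival).
#' @param mirror_validation Mirror the replacement dynamics on the validation
#'   set (disable for sensitivity analysis: evaluation then uses proxy
#'   features throughout).
#' @param classifier_lambda L2 penalty of the downstream classifier.
#' @param cox A [cox_spec()].
#' @param seed Episode seed; every stochastic step draws from a sub-stream.
#' @return List with `metrics` (data frame, iterations 0..H), `trajectory`
#'   (iteration, weights, reward, metric), `queries` (list of queried
#'   training-pool positions per iteration), `label_state`, `params`, and
#'   `predictions` (final validation probabilities/risks with outcomes).
#' @export
run_episode <- function(cohort, split, label_state,
                        method = c("releap", "uncertainty", "diversity",
                                   "qbc", "random"),
                        frozen_weights = NULL, params = NULL,
                        qbc_cfg = qbc_config(), ppo_cfg = ppo_config(),
                        run_mode = c("classification", "survival", "both"),
                        mirror_validation = TRUE, classifier_lambda = 1,
                        cox = cox_spec(), seed = 1L) {
  method <- match.arg(method)
  run_mode <- match.arg(run_mode)
  stopifnot(inherits(cohort, "cohort"), inherits(label_state, "label_state"))
  if (!is.null(frozen_weights)) {
    if (length(frozen_weights) != 3 || any(frozen_weights < 0) ||
        abs(sum(frozen_weights) - 1) > 1e-8) {
      stop("frozen_weights must lie on the probability simplex")
    }
  }
  one_hot <- c(uncertainty = 1L, diversity = 2L, qbc = 3L)
  if (method %in% names(one_hot) && is.null(frozen_weights)) {
    frozen_weights <- as.numeric(seq_len(3) == one_hot[[method]])
  }
  learn <- method == "releap" && is.null(frozen_weights)
  need_all_scores <- method == "releap"  # state construction needs all three
  if (learn && is.null(params)) params <- policy_init(cfg = ppo_cfg)

  tr <- split$train; va <- split$validation
  x1tr <- cohort$x1[tr, , drop = FALSE]; x2tr <- cohort$x2[tr, , drop = FALSE]
  x1va <- cohort$x1[va, , drop = FALSE]; x2va <- cohort$x2[va, , drop = FALSE]
  ytr <- cohort$y[tr]; yva <- cohort$y[va]
  n_tr <- length(tr); n_va <- length(va)
  k <- label_state$batch_size_k
  budget <- label_state$budget_total
  H <- ceiling(budget / k)

  val_s <- cohort$s_proxy[va]
  val_upgraded <- logical(n_va)
  fit_survival <- run_mode != "classification"

  evaluate_now <- function(state, iteration) {
    model <- fit_classifier(state$s_current, x2tr, ytr,
                            lambda = classifier_lambda)
    probs_val <- predict(model, val_s, x2va)
    rep <- evaluate_classification(probs_val, yva, iteration = iteration)
    risk_val <- NULL
    if (fit_survival) {
      cx <- fit_cox(state$s_current, x2tr, cohort$t_event[tr],
                    cohort$event_flag[tr], spec = cox)
      risk_val <- predict(cx, val_s, x2va)
      rep$c_index <- evaluate_survival(risk_val, cohort$t_event[va],
                                       cohort$event_flag[va])
    }
    list(model = model, report = rep, probs_val = probs_val,
         risk_val = risk_val,
         metric = if (run_mode == "survival") rep$c_index else rep$auc)
  }

  ev <- evaluate_now(label_state, 0L)
  metric_hist <- ev$metric
  metrics <- list(as.data.frame(ev$report))
  trajectory <- list()
  queries <- list()
  pending <- list()

  flush_pending <- function(params, bootstrap_value) {
    traj <- list(
      states = do.call(rbind, lapply(pending, `[[`, "state")),
      logits = do.call(rbind, lapply(pending, `[[`, "logits")),
      rewards = vapply(pending, `[[`, numeric(1), "reward"),
      logprobs = vapply(pending, `[[`, numeric(1), "logprob"),
      bootstrap_value = bootstrap_value
    )
    ppo_update(traj, params, ppo_cfg)
  }

  for (t in seq_len(H)) {
    unl <- which(!label_state$labeled_mask)
    lab <- which(label_state$labeled_mask)
    k_t <- min(k, budget - label_state$n_queried, length(unl))
    if (k_t < 1) break

    zero <- numeric(length(unl))
    raw_unc <- raw_div <- raw_qbc <- zero
    Xs <- NULL
    if (need_all_scores || method == "uncertainty") {
      p_unl <- predict(ev$model, label_state$s_current[unl],
                       x2tr[unl, , drop = FALSE])
      raw_unc <- uncertainty_scores(p_unl)
    }
    if (need_all_scores || method == "diversity") {
      Xs <- zscore_standardize(cbind(label_state$s_current, x1tr, x2tr), lab)
      raw_div <- diversity_scores(Xs[unl, , drop = FALSE],
                                  Xs[lab, , drop = FALSE])
    }
    qbc_t <- NULL
    if (need_all_scores || method == "qbc") {
      Xq <- zscore_standardize(cbind(x1tr, x2tr), lab)
      qbc_t <- qbc_config(committee_size = qbc_cfg$committee_size,
                          l2_jitter_sd = qbc_cfg$l2_jitter_sd,
                          dropout_prob = qbc_cfg$dropout_prob,
                          lambda_stabilizer = qbc_cfg$lambda_stabilizer,
                          base_penalty = qbc_cfg$base_penalty,
                          seed = substream_seed(seed, "qbc_iter", t))
      raw_qbc <- as.numeric(qbc_scores(Xq[lab, , drop = FALSE],
                                       label_state$s_current[lab],
                                       Xq[unl, , drop = FALSE], qbc_t))
    }
    scores <- strategy_scores(raw_unc, raw_div, raw_qbc)

    if (method == "random") {
      weights <- rep(NA_real_, 3)
      ids <- unl[with_seed(substream_seed(seed, "random_pick", t),
                           sample.int(length(unl), k_t))]
    } else if (!is.null(frozen_weights)) {
      weights <- frozen_weights
      ids <- unl[composite_rank(scores, weights, k_t,
                                seed = substream_seed(seed, "rank", t))]
    } else {
      state_vec <- build_state(scores, label_state, metric_hist, H, t,
                               window = ppo_cfg$reward_window)
      if (length(pending) >= ppo_cfg$update_period) {
        boot <- value_forward(params, matrix(state_vec, 1))$v
        params <- flush_pending(params, boot)
        pending <- list()
      }
      act <- policy_act(state_vec, params,
                        seed = substream_seed(seed, "act", t))
      weights <- act$weights
      ids <- unl[composite_rank(scores, weights, k_t,
                                seed = substream_seed(seed, "rank", t))]
    }

    label_state <- apply_queries(label_state, ids, cohort)
    queries[[t]] <- ids

    if (mirror_validation) {
      cand <- which(!val_upgraded)
      k_val <- min(round(k_t * n_va / n_tr), length(cand))
      if (!any(!label_state$labeled_mask)) k_val <- length(cand)  # pool exhausted
      if (k_val >= 1 && length(cand)) {
        if (method == "random") {
          chosen <- cand[with_seed(substream_seed(seed, "mirror_rand", t),
                                   sample.int(length(cand), k_val))]
        } else {
          v_unc <- v_div <- v_qbc <- numeric(length(cand))
          if (need_all_scores || method == "uncertainty") {
            v_unc <- uncertainty_scores(
              predict(ev$model, val_s[cand], x2va[cand, , drop = FALSE]))
          }
          if (need_all_scores || method == "diversity") {
            ref <- cbind(label_state$s_current, x1tr, x2tr)
            Xv <- cbind(val_s, x1va, x2va)[cand, , drop = FALSE]
            Zall <- zscore_standardize(rbind(ref, Xv), lab)
            v_div <- diversity_scores(
              Zall[n_tr + seq_len(length(cand)), , drop = FALSE],
              Zall[lab, , drop = FALSE])
          }
          if (need_all_scores || method == "qbc") {
            Xq_all <- zscore_standardize(rbind(cbind(x1tr, x2tr),
                                               cbind(x1va, x2va)), lab)
            v_qbc <- as.numeric(qbc_scores(
              Xq_all[lab, , drop = FALSE], label_state$s_current[lab],
              Xq_all[n_tr + cand, , drop = FALSE], qbc_t %||% qbc_cfg))
          }
          vs <- strategy_scores(v_unc, v_div, v_qbc)
          chosen <- cand[composite_rank(
            vs, weights, k_val, seed = substream_seed(seed, "mirror", t))]
        }
        val_s[chosen] <- cohort$s_true[va[chosen]]
        val_upgraded[chosen] <- TRUE
      }
    }

    ev <- evaluate_now(label_state, t)
    metric_hist <- c(metric_hist, ev$metric)
    metrics[[t + 1]] <- as.data.frame(ev$report)

    budget_frac <- 1 - label_state$n_queried / budget
    reward <- compute_reward(metric_hist, budget_frac,
                             window = ppo_cfg$reward_window,
                             budget_coef = ppo_cfg$reward_budget_coef)
    trajectory[[t]] <- data.frame(
      iteration = t, w_unc = weights[1], w_div = weights[2],
      w_qbc = weights[3], reward = reward, metric = ev$metric)
    if (learn) {
      pending[[length(pending) + 1]] <- list(
        state = state_vec, logits = act$logits, reward = reward,
        logprob = act$logprob)
    }
  }
  if (learn && length(pending)) {
    params <- flush_pending(params, 0)  # terminal: no bootstrap
  }

  list(
    metrics = do.call(rbind, metrics),
    trajectory = if (length(trajectory)) do.call(rbind, trajectory) else NULL,
    queries = queries,
    label_state = label_state,
    params = params,
    predictions = list(probs = ev$probs_val, risk = ev$risk_val, y = yva,
                       val_idx = va, val_upgraded = val_upgraded)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
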