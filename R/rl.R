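# Policy learning over strategy mixtures.
#
# The querying problem is treated as a POMDP: at each iteration the agent
# observes a fixed-length summary state, emits an action on the probability
# simplex (mixture weights over the three strategies), and receives a shaped
# reward derived from the change in downstream validation performance. The
# policy is a small tanh network producing unconstrained logits with a
# learned state-independent log-SD (a diagonal-Gaussian head); sampled logits
# are mapped through a softmax, so the softmax acts on mixture logits, never
# on the raw per-patient strategy scores. Optimisation uses proximal policy
# optimization (clipped importance-ratio surrogate) with generalized
# advantage estimation and a value-function baseline, maximising the
# discounted return E[sum gamma^(t-1) R_t].

#' PPO configuration
#'
#' @param discount Discount factor gamma in (0,1].
#' @param clip_epsilon Clipping half-width of the importance ratio (> 0).
#' @param learning_rate Adam step size.
#' @param update_period Iterations between policy updates (1 = update from
#'   the trailing segment after every iteration).
#' @param gae_lambda Generalized-advantage-estimation lambda.
#' @param entropy_bonus Coefficient of the Gaussian entropy bonus.
#' @param hidden_size Width of the single tanh hidden layer.
#' @param epochs Full-batch gradient epochs per update.
#' @param value_coef Weight of the value-function loss.
#' @param reward_window Moving-baseline window w of the shaped reward.
#' @param reward_budget_coef Budget-aware scaling coefficient c of the shaped
#'   reward.
#' @param seed Integer seed for policy initialisation and action sampling.
#' @return Object of class `ppo_config`.
#' @export
ppo_config <- function(discount = 0.99, clip_epsilon = 0.2,
                       learning_rate = 0.02, update_period = 1L,
                       gae_lambda = 0.95, entropy_bonus = 0,
                       hidden_size = 8L, epochs = 8L, value_coef = 0.5,
                       reward_window = 3L, reward_budget_coef = 0.5,
                       seed = 1L) {
  stopifnot(discount > 0, discount <= 1, clip_epsilon > 0, learning_rate > 0,
            update_period >= 1, gae_lambda >= 0, gae_lambda <= 1,
            entropy_bonus >= 0, hidden_size >= 1, epochs >= 1,
            value_coef >= 0, reward_window >= 1, reward_budget_coef >= 0)
  structure(list(discount = discount, clip_epsilon = clip_epsilon,
                 learning_rate = learning_rate,
                 update_period = as.integer(update_period),
                 gae_lambda = gae_lambda, entropy_bonus = entropy_bonus,
                 hidden_size = as.integer(hidden_size),
                 epochs = as.integer(epochs), value_coef = value_coef,
                 reward_window = as.integer(reward_window),
                 reward_budget_coef = reward_budget_coef,
                 seed = as.integer(seed)), class = "ppo_config")
}

#' Initialise policy and value parameters
#'
#' Policy: state -> tanh hidden layer -> 3 mean logits, plus a learned
#' state-independent log-SD per logit. Value net: same architecture with a
#' scalar head, zero-initialised so initial value predictions (and hence
#' initial advantages for zero rewards) are exactly zero.
#'
#' @param state_dim Length of the summary state (13 by default, see
#'   [build_state()]).
#' @param n_actions Number of strategies (3).
#' @param cfg A [ppo_config()].
#' @return Parameter list of class `releap_policy`.
#' @export
policy_init <- function(state_dim = 13L, n_actions = 3L, cfg = ppo_config()) {
  h <- cfg$hidden_size
  with_seed(substream_seed(cfg$seed, "policy_init"), {
    structure(list(
      W1 = matrix(stats::rnorm(h * state_dim, 0, 0.2), h, state_dim),
      b1 = numeric(h),
      W2 = matrix(stats::rnorm(n_actions * h, 0, 0.2), n_actions, h),
      b2 = numeric(n_actions),
      log_std = rep(log(0.5), n_actions),
      V1 = matrix(0, h, state_dim),
      vb1 = numeric(h),
      V2 = matrix(0, 1, h),
      vb2 = 0,
      state_dim = as.integer(state_dim),
      n_actions = as.integer(n_actions),
      opt = NULL
    ), class = "releap_policy")
  })
}

# Forward passes; S is a T x state_dim matrix.
policy_forward <- function(params, S) {
  H <- tanh(S %*% t(params$W1) + rep(params$b1, each = nrow(S)))
  mu <- H %*% t(params$W2) + rep(params$b2, each = nrow(S))
  list(mu = mu, H = H)
}

value_forward <- function(params, S) {
  H <- tanh(S %*% t(params$V1) + rep(params$vb1, each = nrow(S)))
  list(v = drop(H %*% t(params$V2)) + params$vb2, H = H)
}

#' Sample or evaluate the policy at a state
#'
#' In stochastic mode the action logits are drawn from the diagonal Gaussian
#' `N(mu(state), diag(sd^2))` and mapped through the softmax; in
#' deterministic mode the mean logits are used directly. Output weights are
#' nonnegative and sum to 1.
#'
#' @param state Summary state vector (see [build_state()]).
#' @param params A `releap_policy`.
#' @param deterministic Use mean logits instead of sampling.
#' @param seed Optional seed for the sampling draw.
#' @return List with `weights` (simplex 3-vector), `logits` (the sampled or
#'   mean logits), and `logprob` (Gaussian log-density of the logits;
#'   NA in deterministic mode).
#' @export
policy_act <- function(state, params, deterministic = FALSE, seed = NULL) {
  stopifnot(inherits(params, "releap_policy"))
  if (any(!is.finite(state))) stop("non-finite entries in policy state")
  mu <- drop(policy_forward(params, matrix(state, 1))$mu)
  if (any(!is.finite(mu))) stop("non-finite policy logits")
  if (deterministic) {
    return(list(weights = softmax(mu), logits = mu, logprob = NA_real_))
  }
  sd <- exp(params$log_std)
  eps <- if (is.null(seed)) stats::rnorm(length(mu)) else
    with_seed(seed, stats::rnorm(length(mu)))
  z <- mu + sd * eps
  list(weights = softmax(z), logits = z,
       logprob = sum(stats::dnorm(z, mu, sd, log = TRUE)))
}

#' Shaped reward from the validation-metric trajectory
#'
#' `R_t = (m_t - baseline) * (1 + c * budget_fraction_remaining)` where the
#' baseline is the mean of the `window` metric values preceding the current
#' one (a short moving baseline) and `c` applies mild budget-aware scaling:
#' the same raw improvement is worth more while most of the budget remains.
#'
#' @param metric_history Validation metrics up to and including the current
#'   iteration (last element = current value); at least one prior value
#'   required.
#' @param budget_fraction_remaining Fraction of the query budget still
#'   unspent, in [0,1].
#' @param window Moving-baseline window w (default 3).
#' @param budget_coef Budget-scaling coefficient c (default 0.5).
#' @return Finite scalar reward.
#' @export
compute_reward <- function(metric_history, budget_fraction_remaining,
                           window = 3L, budget_coef = 0.5) {
  if (length(metric_history) < 2) {
    stop("reward needs at least one prior metric value")
  }
  if (any(!is.finite(metric_history))) stop("non-finite metric history")
  m_t <- metric_history[length(metric_history)]
  prior <- metric_history[-length(metric_history)]
  baseline <- mean(utils::tail(prior, window))
  (m_t - baseline) * (1 + budget_coef * budget_fraction_remaining)
}

#' Assemble the fixed-length summary state
#'
#' 13 components, in order: mean and max of each normalised strategy score on
#' the unlabeled pool (6); labeled fraction and labeled-positive fraction
#' (2); last validation metric, its change over the previous step, and its
#' moving average over `window` (3); remaining-budget fraction (1); and
#' iteration fraction t/H (1).
#'
#' @param scores A `strategy_scores` over the current unlabeled pool.
#' @param label_state A `label_state`.
#' @param metric_history Validation metrics recorded so far (seed-set model
#'   first; at least one value).
#' @param horizon Total number of iterations H in the episode.
#' @param iteration Current iteration t (1-based).
#' @param window Moving-average window.
#' @return Numeric state vector of length 13.
#' @export
build_state <- function(scores, label_state, metric_history, horizon,
                        iteration, window = 3L) {
  stopifnot(inherits(scores, "strategy_scores"),
            inherits(label_state, "label_state"))
  if (length(metric_history) < 1 || any(!is.finite(metric_history))) {
    stop("metric history must contain at least one finite value")
  }
  m <- length(metric_history)
  last <- metric_history[m]
  delta <- if (m >= 2) last - metric_history[m - 1] else 0
  mov <- mean(utils::tail(metric_history, window))
  labeled <- label_state$labeled_mask
  state <- c(
    mean(scores$norm_uncertainty), max(scores$norm_uncertainty),
    mean(scores$norm_diversity), max(scores$norm_diversity),
    mean(scores$norm_qbc), max(scores$norm_qbc),
    mean(labeled),
    mean(label_state$s_current[labeled]),
    last, delta, mov,
    1 - label_state$n_queried / label_state$budget_total,
    iteration / horizon
  )
  if (any(!is.finite(state))) stop("non-finite entries in assembled state")
  state
}

# Adam step over a named list of gradients (ascent direction).
adam_step <- function(params, grads, lr) {
  if (is.null(params$opt)) {
    params$opt <- list(m = lapply(grads, function(g) g * 0),
                       v = lapply(grads, function(g) g * 0), t = 0)
  }
  params$opt$t <- params$opt$t + 1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(grads)) {
    g <- grads[[nm]]
    params$opt$m[[nm]] <- b1 * params$opt$m[[nm]] + (1 - b1) * g
    params$opt$v[[nm]] <- b2 * params$opt$v[[nm]] + (1 - b2) * g^2
    mhat <- params$opt$m[[nm]] / (1 - b1^params$opt$t)
    vhat <- params$opt$v[[nm]] / (1 - b2^params$opt$t)
    params[[nm]] <- params[[nm]] + lr * mhat / (sqrt(vhat) + eps)
  }
  params
}

#' PPO update from a trajectory segment
#'
#' Performs clipped-surrogate policy-gradient ascent with generalized
#' advantage estimation and a value-function baseline. The trajectory is a
#' list with `states` (T x state_dim matrix), `logits` (T x 3 sampled action
#' logits), `rewards` (length T), `logprobs` (behaviour log-densities), and
#' optional `bootstrap_value` (value of the state following the segment;
#' 0 at episode end). The update is deterministic given the trajectory, and
#' parameters change only through this function.
#'
#' @param trajectory Trajectory segment as described above.
#' @param params A `releap_policy`.
#' @param cfg A [ppo_config()].
#' @return Updated `releap_policy`.
#' @export
ppo_update <- function(trajectory, params, cfg = ppo_config()) {
  stopifnot(inherits(params, "releap_policy"), inherits(cfg, "ppo_config"))
  S <- trajectory$states
  if (is.null(S) || NROW(S) == 0) stop("empty trajectory batch")
  S <- matrix(S, ncol = params$state_dim)
  Z <- matrix(trajectory$logits, ncol = params$n_actions)
  R <- as.numeric(trajectory$rewards)
  lp_old <- as.numeric(trajectory$logprobs)
  Tn <- nrow(S)
  boot <- if (is.null(trajectory$bootstrap_value)) 0 else trajectory$bootstrap_value

  # GAE advantages and discounted-return targets
  v <- value_forward(params, S)$v
  v_next <- c(v[-1], boot)
  delta <- R + cfg$discount * v_next - v
  adv <- numeric(Tn)
  acc <- 0
  for (t in rev(seq_len(Tn))) {
    acc <- delta[t] + cfg$discount * cfg$gae_lambda * acc
    adv[t] <- acc
  }
  ret <- adv + v
  if (Tn > 1 && stats::sd(adv) > 0) adv <- (adv - mean(adv)) / (stats::sd(adv) + 1e-8)

  for (epoch in seq_len(cfg$epochs)) {
    fw <- policy_forward(params, S)
    sd_vec <- exp(params$log_std)
    resid <- sweep(Z - fw$mu, 2, sd_vec, "/")
    lp_new <- rowSums(stats::dnorm(resid, log = TRUE)) - sum(params$log_std) * 1
    # dnorm(resid) is standard-normal density of the scaled residual; the
    # change of variables contributes -sum(log sd).
    ratio <- exp(lp_new - lp_old)
    clipped_out <- (adv > 0 & ratio > 1 + cfg$clip_epsilon) |
      (adv < 0 & ratio < 1 - cfg$clip_epsilon)
    coef <- ifelse(clipped_out, 0, ratio * adv) / Tn

    dmu <- sweep(sweep(Z - fw$mu, 2, sd_vec^2, "/"), 1, coef, "*")
    gW2 <- t(dmu) %*% fw$H
    gb2 <- colSums(dmu)
    dH <- dmu %*% params$W2
    dpre <- dH * (1 - fw$H^2)
    gW1 <- t(dpre) %*% S
    gb1 <- colSums(dpre)
    g_log_std <- colSums(
      sweep(sweep((Z - fw$mu)^2, 2, sd_vec^2, "/") - 1, 1, coef, "*")) +
      cfg$entropy_bonus

    # value loss (descent folded into the ascent direction)
    vf <- value_forward(params, S)
    dv <- -cfg$value_coef * 2 * (vf$v - ret) / Tn
    gV2 <- matrix(dv, 1) %*% vf$H
    gvb2 <- sum(dv)
    dHv <- matrix(dv, ncol = 1) %*% params$V2
    dprev <- dHv * (1 - vf$H^2)
    gV1 <- t(dprev) %*% S
    gvb1 <- colSums(dprev)

    params <- adam_step(params, list(
      W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, log_std = g_log_std,
      V1 = gV1, vb1 = gvb1, V2 = gV2, vb2 = gvb2
    ), cfg$learning_rate)
  }
  params
}
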