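# Policy head, shaped reward, state assembly, PPO mechanics.

make_state_fixture <- function(seed = 1) {
  co <- small_cohort(n = 600, seed = seed)
  sp <- stratified_split(co, 0.8, seed = seed)
  st <- init_seed_set(co, sp$train, 40, budget_total = 100, batch_size_k = 50,
                      seed = seed)
  n_unl <- sum(!st$labeled_mask)
  sc <- strategy_scores(runif(n_unl), runif(n_unl), runif(n_unl))
  list(cohort = co, split = sp, state = st, scores = sc)
}

test_that("the summary state has fixed length and correct accounting", {
  fx <- make_state_fixture()
  s1 <- build_state(fx$scores, fx$state, metric_history = 0.7, horizon = 2,
                    iteration = 1)
  expect_length(s1, 13)
  expect_equal(s1[12], 1)        # full budget remaining
  expect_equal(s1[13], 1 / 2)    # iteration fraction t/H
  st2 <- fx$state
  st2$n_queried <- 50L           # half the budget spent
  s2 <- build_state(fx$scores, st2, metric_history = c(0.7, 0.72),
                    horizon = 2, iteration = 2)
  expect_length(s2, 13)
  expect_equal(s2[12], 0.5)
  expect_equal(s2[10], 0.02)     # metric delta
  expect_error(build_state(fx$scores, fx$state, NaN, 2, 1), "finite")
})

test_that("the policy head maps logits onto the simplex", {
  expect_equal(softmax(c(0, 0, 0)), rep(1, 3) / 3)
  expect_equal(softmax(c(log(2), 0, 0)), c(0.5, 0.25, 0.25))
  cfg <- ppo_config(seed = 2)
  par <- policy_init(cfg = cfg)
  # symmetric head: zero weights give the uniform mixture deterministically
  par0 <- par
  par0$W2[] <- 0; par0$b2[] <- 0
  a0 <- policy_act(rnorm(13), par0, deterministic = TRUE)
  expect_equal(a0$weights, rep(1, 3) / 3)
  for (i in 1:10) {
    a <- policy_act(rnorm(13), par, seed = i)
    expect_simplex(a$weights)
    expect_true(is.finite(a$logprob))
  }
  expect_error(policy_act(c(NA, rep(0, 12)), par), "finite")
})

test_that("the shaped reward uses a moving baseline and budget scaling", {
  expect_equal(compute_reward(c(0.7, 0.7, 0.7, 0.7), 0.5), 0)
  expect_equal(compute_reward(c(0.70, 0.71), 1), 0.01 * 1.5)
  # strictly increasing in the current metric
  r <- vapply(c(0.70, 0.72, 0.74),
              function(m) compute_reward(c(0.6, 0.65, 0.7, m), 0.3),
              numeric(1))
  expect_true(all(diff(r) > 0))
  expect_error(compute_reward(0.7, 1), "prior")
})

test_that("zero-advantage batches leave all parameters exactly unchanged", {
  cfg <- ppo_config(seed = 3)
  par <- policy_init(cfg = cfg)
  S <- matrix(rnorm(3 * 13), 3, 13)
  acts <- lapply(1:3, function(t) policy_act(S[t, ], par, seed = t))
  traj <- list(states = S,
               logits = do.call(rbind, lapply(acts, `[[`, "logits")),
               rewards = rep(0, 3),
               logprobs = vapply(acts, `[[`, numeric(1), "logprob"))
  par2 <- ppo_update(traj, par, cfg)
  for (nm in c("W1", "b1", "W2", "b2", "log_std", "V1", "vb1", "V2", "vb2")) {
    expect_identical(par2[[nm]], par[[nm]], label = nm)
  }
  expect_error(ppo_update(list(states = NULL), par, cfg), "empty")
})

test_that("the importance ratio is clipped in the surrogate", {
  cfg <- ppo_config(seed = 4, value_coef = 0)
  par <- policy_init(cfg = cfg)
  s <- rnorm(13)
  a <- policy_act(s, par, seed = 9)
  base <- list(states = matrix(s, 1), logits = matrix(a$logits, 1),
               rewards = 1)  # positive advantage (zero-init value net)
  # behaviour logprob far below current: ratio >> 1 + eps, so the clipped
  # branch is active and no policy gradient flows
  clipped <- ppo_update(c(base, list(logprobs = a$logprob - log(10))), par, cfg)
  for (nm in c("W1", "b1", "W2", "b2")) {
    expect_identical(clipped[[nm]], par[[nm]], label = nm)
  }
  # ratio of 1 is inside the clip band: the policy moves
  unclipped <- ppo_update(c(base, list(logprobs = a$logprob)), par, cfg)
  expect_false(identical(unclipped$b2, par$b2))
})
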