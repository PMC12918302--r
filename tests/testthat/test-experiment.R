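# Episode loop, comparator arms, replications, aggregation, subgroups, CLI.

tiny_setup <- function(n = 800, budget = 60, k = 25, n_seed = 20, seed = 7,
                       prev = 0.2) {
  co <- small_cohort(n = n, prev = prev, seed = seed)
  sp <- stratified_split(co, 0.8, seed = seed)
  st <- init_seed_set(co, sp$train, n_seed, budget, k, seed = seed)
  list(co = co, sp = sp, st = st)
}

test_that("episodes run ceil(budget/k) iterations with a final short batch", {
  fx <- tiny_setup(budget = 10, k = 4)
  res <- run_episode(fx$co, fx$sp, fx$st, method = "random", seed = 1)
  expect_equal(lengths(res$queries), c(4L, 4L, 2L))
  expect_equal(res$label_state$n_queried, 10L)
  expect_equal(nrow(res$metrics), 4)  # seed-set model + 3 iterations

  fx2 <- tiny_setup(budget = 60, k = 25)
  res2 <- run_episode(fx2$co, fx2$sp, fx2$st, method = "releap", seed = 1)
  expect_equal(nrow(res2$trajectory), ceiling(60 / 25))
  expect_true(all(is.finite(res2$trajectory$reward)))
  for (t in seq_len(nrow(res2$trajectory))) {
    expect_simplex(unlist(res2$trajectory[t, c("w_unc", "w_div", "w_qbc")]))
  }
})

test_that("within a replication all arms share split and seed set", {
  fx <- tiny_setup()
  cfg <- experiment_config(cohort = fx$co, n_replications = 1,
                           budget_total = 40, batch_size_k = 20,
                           seed_set_size = 20, master_seed = 5)
  ra <- run_method("random", fx$co, cfg, replication = 2)
  rb <- run_method("uncertainty", fx$co, cfg, replication = 2)
  expect_identical(ra$predictions$val_idx, rb$predictions$val_idx)
  # proxy-only consumes zero reference labels
  rp <- run_method("proxy_only", fx$co, cfg, replication = 2)
  expect_length(rp$queries, 0)
  # oracle is invariant to the budget
  cfg2 <- experiment_config(cohort = fx$co, n_replications = 1,
                            budget_total = 200, batch_size_k = 20,
                            seed_set_size = 20, master_seed = 5)
  ro1 <- run_method("oracle", fx$co, cfg, replication = 2)
  ro2 <- run_method("oracle", fx$co, cfg2, replication = 2)
  expect_identical(ro1$metrics, ro2$metrics)
  expect_error(run_method("aphrodite", fx$co, cfg), "notes")
  expect_error(run_method("nonsense", fx$co, cfg), "unknown")
})

test_that("replications are reproducible and seed-sensitive", {
  co <- small_cohort(n = 600, seed = 9)
  cfg <- experiment_config(cohort = co, methods = c("proxy_only", "random"),
                           n_replications = 2, budget_total = 40,
                           batch_size_k = 20, seed_set_size = 10,
                           master_seed = 3)
  a <- run_replications(cfg)
  b <- run_replications(cfg)
  expect_identical(a$metrics, b$metrics)
  expect_equal(sum(vapply(a$results, function(r) r$method == "random",
                          logical(1))), 2)
  # different replications produce different random query sequences
  q <- lapply(Filter(function(r) r$method == "random", a$results),
              `[[`, "queries")
  expect_false(identical(q[[1]], q[[2]]))
})

test_that("aggregation reports normal-approximation confidence intervals", {
  df <- data.frame(method = "m", iteration = 0L,
                   auc = c(0.70, 0.72, 0.74), replication = 1:3)
  agg <- aggregate_results(df)
  expect_equal(agg$mean, 0.72)
  expect_equal(agg$ci_low, 0.72 - 1.96 * 0.02 / sqrt(3), tolerance = 1e-10)
  expect_equal(agg$ci_high, 0.72 + 1.96 * 0.02 / sqrt(3), tolerance = 1e-10)
  # degenerate spread: zero-width interval
  dfc <- data.frame(method = "m", iteration = 0L, auc = rep(0.7, 3),
                    replication = 1:3)
  aggc <- aggregate_results(dfc)
  expect_equal(aggc$ci_low, aggc$ci_high)
  # permutation invariance
  expect_equal(aggregate_results(df[c(3, 1, 2), ]), agg)
  # single replication: CI absent, not fabricated
  agg1 <- aggregate_results(df[1, ])
  expect_true(is.na(agg1$ci_low) && is.na(agg1$ci_high))
})

test_that("subgroup evaluation recomputes metrics per group", {
  fx <- tiny_setup(n = 1200)
  cfg <- experiment_config(cohort = fx$co, n_replications = 1,
                           budget_total = 40, batch_size_k = 20,
                           seed_set_size = 20, master_seed = 2)
  res <- run_method("proxy_only", fx$co, cfg)
  # degenerate stratification: the whole cohort reproduces overall metrics
  whole <- subgroup_evaluate(res, rep("all", length(fx$co$patient_id)))
  expect_equal(whole$auc, res$final$auc)
  expect_equal(whole$prob_mse, res$final$prob_mse)
  expect_error(subgroup_evaluate(res, rep(NA, length(fx$co$patient_id))),
               "non-missing")
})

test_that("group-dependent proxy noise shows up in subgroup discrimination", {
  co <- small_cohort(n = 4000, prev = 0.2, seed = 15)
  clean <- co$patient_id %% 2 == 0
  co$s_proxy[clean] <- co$s_true[clean]  # one subgroup gets a noiseless proxy
  cfg <- experiment_config(cohort = co, n_replications = 1, budget_total = 40,
                           batch_size_k = 20, seed_set_size = 20,
                           master_seed = 4)
  res <- run_method("proxy_only", co, cfg)
  sg <- subgroup_evaluate(res, ifelse(clean, "clean", "noisy"))
  expect_gt(sg$auc[sg$group == "clean"], sg$auc[sg$group == "noisy"])
})

test_that("the CLI simulates, compares, and reports", {
  dir <- withr::local_tempdir()
  cohort_path <- file.path(dir, "cohort.csv")
  expect_equal(cli_main(c("simulate", "--preset", "rare", "--n", "1000",
                          "--seed", "1", "--out", cohort_path)), 0L)
  df <- read.csv(cohort_path)
  expect_equal(nrow(df), 1000)
  expect_true(all(c("patient_id", "s_proxy", "s_true", "y", "t_event",
                    "event_flag") %in% names(df)))

  cfg_path <- file.path(dir, "cfg.yaml")
  writeLines(c(
    sprintf("cohort: %s", cohort_path),
    "methods: [proxy_only, random]",
    "n_replications: 2",
    "budget_total: 40",
    "batch_size_k: 20",
    "seed_set_size: 10",
    "master_seed: 3"), cfg_path)
  out_dir <- file.path(dir, "out")
  expect_equal(cli_main(c("compare", "--config", cfg_path, "--out", out_dir)),
               0L)
  expect_true(file.exists(file.path(out_dir, "summary.csv")))
  expect_true(file.exists(file.path(out_dir, "resolved_config.yaml")))
  expect_length(list.files(out_dir, pattern = "^metrics_"), 4)

  expect_equal(cli_main(c("report", "--in", out_dir)), 0L)
  summary <- read.csv(file.path(out_dir, "summary.csv"))
  expect_setequal(unique(summary$method), c("proxy_only", "random"))
  # malformed input fails with a nonzero status, not an R error
  expect_equal(suppressMessages(cli_main(c("compare", "--config",
                                           "/nonexistent.yaml"))), 1L)
  expect_equal(suppressMessages(cli_main("frobnicate")), 1L)
})
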