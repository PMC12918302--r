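# Downstream models and metrics.

test_that("the ridge classifier matches glmnet at matched penalty", {
  skip_if_not_installed("glmnet")
  set.seed(21)
  n <- 600
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rbinom(n, 1, plogis(X %*% c(1, -0.5, 0.25, 0)))
  lam <- 2
  mine <- releap:::ridge_logistic(X, y, lambda = lam)
  ref <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lam / n, standardize = FALSE,
                        thresh = 1e-14)
  expect_equal(mine$coef,
               as.numeric(coef(ref)), tolerance = 1e-4)
})

test_that("classifier orders a separable feature and is null on permuted labels", {
  s <- c(rep(0, 20), rep(1, 20))
  x2 <- matrix(0, 40, 1)
  y <- as.integer(s == 1)
  fit <- fit_classifier(s, x2, y)
  p <- predict(fit, s, x2)
  expect_equal(auc_oracle(p, y), 1.0)
  expect_error(fit_classifier(s, x2, rep(1L, 40)), "single class")

  set.seed(3)
  n <- 5000
  X <- matrix(rnorm(n * 3), n, 3)
  yr <- rbinom(n, 1, 0.3)  # independent of features
  tr <- 1:2500
  fit0 <- fit_classifier(X[tr, 1], X[tr, -1], yr[tr])
  p0 <- predict(fit0, X[-tr, 1], X[-tr, -1])
  expect_lt(abs(auc_oracle(p0, yr[-tr]) - 0.5), 0.03)
})

test_that("oracle phenotype features dominate proxy features on average", {
  diffs <- vapply(1:10, function(s) {
    co <- small_cohort(n = 3000, prev = 0.15, seed = 100 + s)
    sp <- stratified_split(co, 0.8, seed = s)
    tr <- sp$train; va <- sp$validation
    fo <- fit_classifier(co$s_true[tr], co$x2[tr, ], co$y[tr])
    fp <- fit_classifier(co$s_proxy[tr], co$x2[tr, ], co$y[tr])
    auc_oracle(predict(fo, co$s_true[va], co$x2[va, ]), co$y[va]) -
      auc_oracle(predict(fp, co$s_proxy[va], co$x2[va, ]), co$y[va])
  }, numeric(1))
  expect_gte(mean(diffs), -0.005)
})

test_that("classification metrics match enumerated toy cases", {
  r <- evaluate_classification(c(0.9, 0.8, 0.2), c(1, 0, 0))
  expect_equal(r$auc, 1.0)
  r2 <- evaluate_classification(c(0, 1, 1, 0), c(0, 1, 1, 0))
  expect_equal(r2$prob_mse, 0)
  expect_equal(r2$tpr_at_fpr10, 1)
  expect_equal(r2$ppv_at_fpr10, 1)
  expect_equal(r2$f1, 1)
  y <- rep(c(0, 1), 500)
  r3 <- evaluate_classification(rep(0.5, 1000), y)
  expect_equal(r3$auc, 0.5)
  expect_error(evaluate_classification(runif(5), rep(1, 5)), "single class")
})

test_that("AUC is invariant to monotone transforms and FPR cap is respected", {
  set.seed(8)
  p <- runif(400)
  y <- rbinom(400, 1, p)
  r <- evaluate_classification(p, y)
  rt <- evaluate_classification(qlogis(p * 0.98 + 0.01), y)
  expect_equal(r$auc, rt$auc, tolerance = 1e-12)
  # chosen operating point: FPR <= 0.1 and equal to the largest attainable
  neg <- p[y == 0]
  fprs <- vapply(sort(unique(p)), function(c) mean(neg >= c), numeric(1))
  best <- max(fprs[fprs <= 0.1])
  thr_fpr <- mean(neg >= sort(unique(p))[min(which(fprs <= 0.1))])
  expect_lte(thr_fpr, 0.1)
  expect_equal(thr_fpr, best)
})

test_that("Cox fitting recovers ordering and rejects degenerate inputs", {
  expect_equal(evaluate_survival(c(2, 1), c(1, 2), c(1, 1)), 1.0)
  expect_equal(evaluate_survival(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1.0)
  expect_equal(evaluate_survival(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0.0)
  set.seed(2)
  risk <- rnorm(2000)
  t <- rexp(2000)
  expect_lt(abs(evaluate_survival(risk, t, rep(1, 2000)) - 0.5), 0.03)
  # negation flips concordance on event-complete data
  expect_equal(evaluate_survival(risk, t, rep(1, 2000)),
               1 - evaluate_survival(-risk, t, rep(1, 2000)),
               tolerance = 1e-12)

  co <- small_cohort(n = 2000, seed = 12)
  expect_error(fit_cox(co$s_true, co$x2, co$t_event, rep(0, 2000)),
               "no observed events")
  expect_error(fit_cox(co$s_true, co$x2, c(-1, co$t_event[-1]),
                       co$event_flag), "positive")
})

test_that("package C-index equals brute-force pair enumeration under censoring", {
  set.seed(14)
  n <- 120
  risk <- rnorm(n)
  t <- rexp(n)
  e <- rbinom(n, 1, 0.6)
  expect_equal(evaluate_survival(risk, t, e), cindex_brute(risk, t, e),
               tolerance = 1e-12)
})

test_that("Cox screening drops constants and caps dimension", {
  co <- small_cohort(n = 2000, seed = 13)
  x2 <- cbind(co$x2, const = 1)
  fit <- fit_cox(co$s_true, x2, co$t_event, co$event_flag)
  expect_false("const" %in% fit$kept)
  fit2 <- fit_cox(co$s_true, co$x2, co$t_event, co$event_flag,
                  spec = cox_spec(screening = "univariate", max_features = 2))
  expect_length(fit2$kept, 2)
  risk <- predict(fit, co$s_true, x2)
  expect_length(risk, 2000)
})
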