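# L2-penalised logistic regression by damped Newton iterations.
#
# Minimises  -loglik(beta) + lambda/2 * ||beta[-1]||^2  (intercept unpenalised).
# Used for the downstream classifier, the committee members, and the fixture's
# code-only proxy model. The design dimension is small throughout, so a dense
# Newton solve is both exact and fast; the same fit at matched penalty is
# cross-checked against glmnet in the test suite.

ridge_logistic <- function(x, y, lambda = 1, max_iter = 100, tol = 1e-10) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y dimensions disagree")
  if (length(unique(y)) < 2) stop("ridge_logistic: outcome has a single class")
  X <- cbind(1, x)
  p <- ncol(X)
  pen <- c(0, rep(lambda, p - 1L))
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(drop(X %*% beta))
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + pen
    step <- drop(solve(H, grad))
    # step damping guards against overshoot near separation
    slen <- sqrt(sum(step^2))
    if (slen > 10) step <- step * (10 / slen)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(coef = beta, lambda = lambda, iterations = it)
}

predict_ridge_logistic <- function(fit, x) {
  x <- as.matrix(x)
  stats::plogis(drop(cbind(1, x) %*% fit$coef))
}
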