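# Shared fixture builders; everything is generated in code at test time.

small_cohort <- function(n = 1000, prev = 0.2, seed = 5, ...) {
  generate_cohort(cohort_config(n_patients = n, outcome_prevalence = prev,
                                seed = seed, ...))
}

# Independent rank-based AUC oracle (Mann-Whitney), used to check package
# metrics without routing through the implementation under test.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  grid <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(grid)
}

# Brute-force Harrell concordance over all ordered pairs (continuous times
# assumed, so no tied-time handling is needed).
cindex_brute <- function(risk, t, e) {
  n <- length(risk)
  num <- den <- 0
  for (i in seq_len(n)) {
    if (e[i] != 1) next
    for (j in seq_len(n)) {
      if (i == j || t[i] >= t[j]) next
      den <- den + 1
      num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    }
  }
  num / den
}

# Hand-rolled simplex check.
expect_simplex <- function(w, tol = 1e-8) {
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = tol)
}
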