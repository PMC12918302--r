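# Active-learning strategy scores over the unlabeled pool.
#
# Three complementary notions of informativeness are computed per candidate
# patient: predictive-entropy uncertainty, distance-based diversity, and
# query-by-committee disagreement. Each raw score vector is min-max
# normalised to [0,1] per iteration, combined under mixture weights on the
# probability simplex, and the top-k composites are selected with a tiny
# seeded jitter (~1e-6) to break ties.

#' Z-score standardisation against a reference row set
#'
#' Centers and scales each column by the mean and population standard
#' deviation (divide by n) of the reference rows — in the query loop the
#' reference is the current labeled set. Zero-variance columns are centered
#' only, so constant features pass through as zeros rather than NaN.
#'
#' @param features Numeric matrix.
#' @param reference_rows Nonempty integer vector of reference row indices.
#' @return Matrix of the same shape.
#' @export
zscore_standardize <- function(features, reference_rows) {
  features <- as.matrix(features)
  if (length(reference_rows) == 0) stop("reference row set is empty")
  ref <- features[reference_rows, , drop = FALSE]
  mu <- colMeans(ref)
  sd_pop <- sqrt(colMeans(ref^2) - mu^2)
  sd_pop[sd_pop < 1e-12] <- 1  # zero-variance: center only
  sweep(sweep(features, 2, mu, "-"), 2, sd_pop, "/")
}

#' Binary-entropy uncertainty scores
#'
#' `H(p) = -p log p - (1-p) log(1-p)` in nats, with `0 log 0 := 0`. Highest
#' for patients about whom the current downstream model is least confident
#' (p = 0.5 gives `log 2`).
#'
#' @param probs Predicted probabilities in [0,1].
#' @return Nonnegative entropy per patient.
#' @export
uncertainty_scores <- function(probs) {
  if (!is.numeric(probs) || any(!is.finite(probs)) ||
      any(probs < 0 | probs > 1)) {
    stop("probs must be finite values in [0,1]")
  }
  h <- function(p) ifelse(p <= 0 | p >= 1, 0, -p * log(p) - (1 - p) * log(1 - p))
  h(probs)
}

#' Distance-based diversity scores
#'
#' Euclidean distance from each unlabeled patient to its nearest labeled
#' neighbour; larger distances mean poorer coverage of that region by the
#' labeled set. With `adjustment = "mean-variance"` the distance is divided
#' by `1 + mean per-dimension variance of the labeled features`, a bounded,
#' order-preserving variance adjustment for numerical stability.
#'
#' @param unlabeled_features,labeled_features Numeric matrices with the same
#'   number of columns.
#' @param adjustment `"mean-variance"` (default) or `"none"`.
#' @return Nonnegative score per unlabeled patient.
#' @export
diversity_scores <- function(unlabeled_features, labeled_features,
                             adjustment = c("mean-variance", "none")) {
  adjustment <- match.arg(adjustment)
  U <- as.matrix(unlabeled_features)
  L <- as.matrix(labeled_features)
  if (nrow(L) == 0) stop("labeled set is empty")
  if (ncol(U) != ncol(L)) stop("feature dimension mismatch between pools")
  l_sq <- rowSums(L^2)
  u_sq <- rowSums(U^2)
  nn <- numeric(nrow(U))
  chunk <- 2048L  # bounds the n x m Gram block held in memory
  for (start in seq(1L, nrow(U), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(U))
    G <- tcrossprod(U[idx, , drop = FALSE], L)
    nn[idx] <- sqrt(pmax(.rowmin_d2(G, l_sq) + u_sq[idx], 0))
  }
  if (adjustment == "mean-variance") {
    mu <- colMeans(L)
    nn <- nn / (1 + mean(colMeans(L^2) - mu^2))
  }
  nn
}

#' Query-by-committee configuration
#'
#' @param committee_size Number of committee members M (>= 2; default 7).
#' @param l2_jitter_sd SD of the log-normal jitter multiplying each member's
#'   L2 penalty (penalty * exp(N(0, sd^2))).
#' @param dropout_prob Per-feature dropout probability for each member,
#'   in [0,1).
#' @param lambda_stabilizer Weight of the entropy stabiliser added to the
#'   committee variance.
#' @param base_penalty Baseline L2 penalty of each member.
#' @param seed Integer seed for resampling, jitter, and dropout.
#' @return An object of class `qbc_config`.
#' @export
qbc_config <- function(committee_size = 7L, l2_jitter_sd = 0.1,
                       dropout_prob = 0.1, lambda_stabilizer = 0.1,
                       base_penalty = 1, seed = 1L) {
  if (committee_size < 2) stop("committee_size must be >= 2")
  stopifnot(l2_jitter_sd >= 0, dropout_prob >= 0, dropout_prob < 1,
            lambda_stabilizer >= 0, base_penalty > 0)
  structure(list(committee_size = as.integer(committee_size),
                 l2_jitter_sd = l2_jitter_sd, dropout_prob = dropout_prob,
                 lambda_stabilizer = lambda_stabilizer,
                 base_penalty = base_penalty, seed = as.integer(seed)),
            class = "qbc_config")
}

#' Query-by-committee disagreement scores
#'
#' Trains a committee of M L2-penalised logistic regressions on bootstrap
#' resamples of the labeled set. Each member perturbs its fit with a
#' log-normal jitter on the L2 penalty and feature dropout (each column
#' zeroed with probability `dropout_prob`, at least one column kept). The
#' score is the population variance of member probabilities plus
#' `lambda_stabilizer * H(mean probability)`, an entropy stabiliser that
#' keeps borderline regions attractive even under committee agreement.
#'
#' @param labeled_features Feature matrix of the labeled set.
#' @param labeled_labels Binary labels of the labeled set (both classes
#'   required).
#' @param unlabeled_features Feature matrix of the scoring pool.
#' @param cfg A [qbc_config()].
#' @return Nonnegative score per unlabeled patient, with attribute
#'   `committee_probs` (M x n matrix).
#' @export
qbc_scores <- function(labeled_features, labeled_labels, unlabeled_features,
                       cfg = qbc_config()) {
  stopifnot(inherits(cfg, "qbc_config"))
  L <- as.matrix(labeled_features)
  U <- as.matrix(unlabeled_features)
  yl <- as.numeric(labeled_labels)
  if (length(unique(yl)) < 2) stop("labeled set contains a single class")
  if (ncol(L) != ncol(U)) stop("feature dimension mismatch between pools")
  nl <- nrow(L); M <- cfg$committee_size
  probs <- with_seed(substream_seed(cfg$seed, "qbc_members"), {
    pm <- matrix(NA_real_, M, nrow(U))
    for (m in seq_len(M)) {
      repeat {  # redraw a bootstrap that lost one class (rare)
        rows <- sample.int(nl, nl, replace = TRUE)
        if (length(unique(yl[rows])) == 2) break
      }
      keep <- stats::runif(ncol(L)) >= cfg$dropout_prob
      if (!any(keep)) keep[sample.int(ncol(L), 1)] <- TRUE
      lam <- cfg$base_penalty * exp(stats::rnorm(1, 0, cfg$l2_jitter_sd))
      fit <- ridge_logistic(L[rows, keep, drop = FALSE], yl[rows], lambda = lam)
      pm[m, ] <- predict_ridge_logistic(fit, U[, keep, drop = FALSE])
    }
    pm
  })
  mean_p <- colMeans(probs)
  var_p <- colMeans(probs^2) - mean_p^2
  score <- pmax(var_p, 0) + cfg$lambda_stabilizer * uncertainty_scores(mean_p)
  attr(score, "committee_probs") <- probs
  score
}

#' Min-max normalisation to [0,1]
#'
#' `(x - min) / (max - min)`; a constant vector maps to all zeros, so a
#' degenerate strategy contributes nothing to the composite that round.
#'
#' @param scores Nonempty finite numeric vector.
#' @return Vector in [0,1].
#' @export
minmax_normalize <- function(scores) {
  if (!is.numeric(scores) || length(scores) == 0 || any(!is.finite(scores))) {
    stop("scores must be a nonempty finite numeric vector")
  }
  rng <- range(scores)
  if (rng[2] - rng[1] < .Machine$double.eps) return(rep(0, length(scores)))
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' Bundle raw and normalised strategy scores
#'
#' @param raw_uncertainty,raw_diversity,raw_qbc Raw score vectors over the
#'   same unlabeled pool.
#' @return Object of class `strategy_scores` holding raw and min-max
#'   normalised versions of each.
#' @export
strategy_scores <- function(raw_uncertainty, raw_diversity, raw_qbc) {
  n <- length(raw_uncertainty)
  if (length(raw_diversity) != n || length(raw_qbc) != n) {
    stop("strategy score vectors must share the unlabeled-pool length")
  }
  structure(list(
    raw_uncertainty = raw_uncertainty,
    raw_diversity = raw_diversity,
    raw_qbc = as.numeric(raw_qbc),
    norm_uncertainty = minmax_normalize(raw_uncertainty),
    norm_diversity = minmax_normalize(raw_diversity),
    norm_qbc = minmax_normalize(as.numeric(raw_qbc))
  ), class = "strategy_scores")
}

#' Rank the pool under mixture weights and select the top-k
#'
#' Composite score = `w_unc * norm_unc + w_div * norm_div + w_qbc * norm_qbc`
#' plus a seeded uniform(0, 1e-6) jitter used purely as a tie-break. Returns
#' the positions (within the scored pool) of the k largest composites,
#' without replacement; `k` is truncated to the pool size, so a final short
#' batch selects whatever remains.
#'
#' @param scores A `strategy_scores`.
#' @param weights Nonnegative 3-vector `(w_unc, w_div, w_qbc)` summing to 1
#'   (tolerance 1e-8).
#' @param k Number of patients to select.
#' @param seed Integer seed for the tie-break jitter.
#' @return Integer vector of k selected pool positions.
#' @export
composite_rank <- function(scores, weights, k, seed = 1L) {
  stopifnot(inherits(scores, "strategy_scores"))
  if (length(weights) != 3 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be a nonnegative 3-vector summing to 1")
  }
  n <- length(scores$norm_uncertainty)
  k <- min(as.integer(k), n)
  if (k < 1) stop("k must be positive")
  composite <- weights[1] * scores$norm_uncertainty +
    weights[2] * scores$norm_diversity +
    weights[3] * scores$norm_qbc
  jitter <- with_seed(substream_seed(seed, "rank_jitter"),
                      stats::runif(n, 0, 1e-6))
  order(composite + jitter, decreasing = TRUE)[seq_len(k)]
}
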