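# Internal numeric and RNG helpers shared across modules.

#' Softmax transform
#'
#' Maps a vector of unconstrained real logits onto the probability simplex.
#' Numerically stabilised by subtracting the maximum before exponentiating.
#'
#' @param x Numeric vector of finite logits.
#' @return Nonnegative vector of the same length summing to 1.
#' @examples
#' softmax(c(log(2), 0, 0))  # c(0.5, 0.25, 0.25)
#' @export
softmax <- function(x) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x))) {
    stop("softmax() requires a nonempty finite numeric vector")
  }
  z <- exp(x - max(x))
  z / sum(z)
}

# Deterministic 31-bit hash of a character tag; basis of sub-stream seeds.
hash_tag <- function(tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  h
}

# Derive an independent sub-stream seed from a master seed, a field tag, and an
# optional integer index (e.g. iteration number). All randomness in the package
# flows through these so that replications are reproducible field-by-field.
# Result always lies in [1, 2^31 - 2], a valid set.seed() input.
substream_seed <- function(seed, tag, index = 0L) {
  s <- (abs(as.numeric(seed)) %% 2147483647)
  v <- (s * 48271 + hash_tag(tag) + 1103 * as.numeric(index)) %% 2147483646
  as.integer(v + 1)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Population variance (divide by n); the convention used for committee
# disagreement and z-scoring.
pop_var <- function(x) mean((x - mean(x))^2)

stopifnot_scalar_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (open_left) x > 0 else x >= 0) &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) stop(sprintf("'%s' must be a single real in %s0,1%s (got %s)",
                        name, if (open_left) "(" else "[",
                        if (open_right) ")" else "]",
                        format(x)[1]), call. = FALSE)
  invisible(x)
}

#' Labeling budget as a percentage of a cohort
#'
#' Expresses an absolute label budget as a percentage of the full cohort size,
#' rounded to one decimal (the convention used when reporting budgets both as
#' counts and proportions).
#'
#' @param budget Number of reference labels queried.
#' @param n_total Full cohort size.
#' @return Percentage (scalar), rounded to one decimal place.
#' @examples
#' budget_fraction_pct(82000, 238119)  # 34.4
#' @export
budget_fraction_pct <- function(budget, n_total) {
  stopifnot(budget >= 0, n_total > 0)
  round(100 * budget / n_total, 1)
}
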