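# Label-state management: the evolving phenotype vector St over the training
# pool, the labeled/unlabeled partition, and the query budget.
#
# St starts at the proxy score S* for every patient (S0 = S*) and is updated
# by replacing proxy values with the binary reference phenotype Strue for
# queried patients. Queried patients are labeled without replacement and are
# never re-queried.

#' Outcome-stratified train/validation split
#'
#' Splits a cohort into disjoint, exhaustive train and validation index sets,
#' stratified by the binary outcome so that event rates are preserved.
#' Per-stratum training counts use largest-remainder allocation, which keeps
#' each stratum's rate within one patient of proportional and makes the split
#' size deterministic: `|train| = round(train_fraction * n)`.
#'
#' @param cohort A `cohort`.
#' @param train_fraction Fraction of patients assigned to training, in (0,1).
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `validation` (cohort row
#'   indices).
#' @export
stratified_split <- function(cohort, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  stopifnot_scalar_prob(train_fraction, "train_fraction")
  y <- cohort$y
  n <- length(y)
  strata <- split(seq_len(n), y)
  if (any(lengths(strata) < 2)) {
    stop("each outcome class needs at least 2 patients to stratify")
  }
  n_train <- round(train_fraction * n)
  quota <- vapply(strata, length, 1L) * train_fraction
  base <- floor(quota)
  rem <- n_train - sum(base)
  # largest-remainder allocation; ties broken by stratum order
  frac_order <- order(quota - base, decreasing = TRUE)
  take <- base
  if (rem > 0) take[frac_order[seq_len(rem)]] <- take[frac_order[seq_len(rem)]] + 1
  train <- with_seed(substream_seed(seed, "split"), {
    unlist(Map(function(idx, k) sample(idx, k), strata, take), use.names = FALSE)
  })
  train <- sort(train)
  list(train = train, validation = setdiff(seq_len(n), train))
}

#' Initialise the label state with a balanced seed set
#'
#' Labels exactly `n_seed` training patients, half from each reference
#' phenotype class, sampled uniformly without replacement within class. Their
#' phenotype value is set to `Strue`; all other patients keep the continuous
#' proxy `S*` (the S0 = S* initialisation).
#'
#' @param cohort A `cohort`.
#' @param train_idx Training-pool cohort indices (from [stratified_split()]).
#' @param n_seed Positive even seed-set size.
#' @param budget_total Total number of reference labels the episode may query
#'   (excluding the seed set).
#' @param batch_size_k Labels queried per iteration.
#' @param seed Integer seed.
#' @return An object of class `label_state` with fields `train_idx`,
#'   `s_current`, `labeled_mask`, `n_queried`, `budget_total`,
#'   `batch_size_k`, `n_seed`.
#' @export
init_seed_set <- function(cohort, train_idx, n_seed, budget_total,
                          batch_size_k, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  if (n_seed < 2 || n_seed %% 2 != 0) stop("n_seed must be a positive even integer")
  stopifnot(budget_total >= 1, batch_size_k >= 1)
  s_true_tr <- cohort$s_true[train_idx]
  per_class <- n_seed / 2
  pos <- which(s_true_tr == 1)
  neg <- which(s_true_tr == 0)
  if (length(pos) < per_class) {
    stop(sprintf("insufficient phenotype-positive patients in the training pool (%d < %d)",
                 length(pos), per_class))
  }
  if (length(neg) < per_class) {
    stop(sprintf("insufficient phenotype-negative patients in the training pool (%d < %d)",
                 length(neg), per_class))
  }
  picked <- with_seed(substream_seed(seed, "seedset"),
                      c(sample(pos, per_class), sample(neg, per_class)))
  labeled <- logical(length(train_idx))
  labeled[picked] <- TRUE
  s_current <- cohort$s_proxy[train_idx]
  s_current[labeled] <- s_true_tr[labeled]
  structure(list(
    train_idx = train_idx,
    s_current = s_current,
    labeled_mask = labeled,
    n_queried = 0L,
    budget_total = as.integer(budget_total),
    batch_size_k = as.integer(batch_size_k),
    n_seed = as.integer(n_seed)
  ), class = "label_state")
}

#' Reveal reference labels for a batch of queried patients
#'
#' For each queried patient the phenotype value is overwritten with `Strue`
#' and the labeled mask set; the query counter is incremented by the batch
#' size. Patients are labeled without replacement: re-querying a labeled
#' patient is an error, as is exceeding the remaining budget.
#'
#' @param state A `label_state`.
#' @param ids Positions within the training pool (indices into
#'   `state$train_idx`) to query; may be empty.
#' @param cohort The `cohort` the state was built from.
#' @return The updated `label_state`.
#' @export
apply_queries <- function(state, ids, cohort) {
  stopifnot(inherits(state, "label_state"), inherits(cohort, "cohort"))
  if (length(ids) == 0) return(state)
  ids <- as.integer(ids)
  if (any(ids < 1 | ids > length(state$train_idx))) stop("query ids out of range")
  if (anyDuplicated(ids)) stop("duplicate query ids")
  if (any(state$labeled_mask[ids])) {
    stop("cannot re-query already-labeled patients (labels are revealed without replacement)")
  }
  if (state$n_queried + length(ids) > state$budget_total) {
    stop(sprintf("query of %d patients exceeds remaining budget %d",
                 length(ids), state$budget_total - state$n_queried))
  }
  state$s_current[ids] <- cohort$s_true[state$train_idx[ids]]
  state$labeled_mask[ids] <- TRUE
  state$n_queried <- state$n_queried + length(ids)
  state
}

#' @export
print.label_state <- function(x, ...) {
  cat(sprintf("Label state: %d/%d labeled (seed %d + %d queried of budget %d)\n",
              sum(x$labeled_mask), length(x$labeled_mask), x$n_seed,
              x$n_queried, x$budget_total))
  invisible(x)
}

#' Write a label-state snapshot for audit
#'
#' @param state A `label_state`.
#' @param path Output CSV path.
#' @param iteration Iteration number recorded in the snapshot.
#' @export
write_label_state <- function(state, path, iteration = NA_integer_) {
  utils::write.csv(data.frame(
    patient_id = state$train_idx,
    s_current = state$s_current,
    labeled_mask = as.integer(state$labeled_mask),
    iteration = iteration
  ), path, row.names = FALSE)
  invisible(path)
}
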