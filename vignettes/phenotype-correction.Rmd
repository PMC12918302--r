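---
title: "Budget-constrained phenotype correction with a reinforcement-guided query policy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Budget-constrained phenotype correction with a reinforcement-guided query policy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(releap)
```

## The problem

EHR-based risk models often depend on intermediate phenotypes — smoking
status is the canonical example — that are not observed directly. A cheap
proxy is always available (for smoking, a score built from diagnosis codes),
but it is noisy in a characteristic, one-sided way: codes under-ascertain
the behaviour, so a large fraction of true positives look like negatives.
A high-fidelity reference label exists but is expensive to reveal, so only a
limited number of patients can be "upgraded" from proxy to reference. The
question this package addresses is *which* patients to upgrade, when the
goal is not label accuracy per se but the downstream risk model's validation
performance.

## The procedure

The agent maintains a phenotype vector \(S_t\) over the training pool,
initialised to the continuous proxy score (\(S_0 = S^*\)). A balanced seed
set (half reference-positive, half reference-negative) is revealed up front.
Then, for \(H = \lceil \text{budget}/k \rceil\) iterations:

1. **Score** every unlabeled patient with three strategies:
   - *uncertainty*: binary entropy
     \(H(\hat p) = -\hat p\log\hat p - (1-\hat p)\log(1-\hat p)\) of the
     current downstream model's predicted outcome probability;
   - *diversity*: Euclidean distance to the nearest labeled patient in the
     z-scored feature space, divided by one plus the mean per-dimension
     variance of the labeled features (a bounded, order-preserving variance
     adjustment);
   - *query-by-committee*: disagreement (population variance of predicted
     probabilities, plus a small entropy stabiliser) across \(M = 7\)
     logistic models trained on bootstrap resamples of the labeled set, each
     with a log-normally jittered L2 penalty and feature dropout at
     probability 0.1.
   Each raw score vector is min–max normalised to \([0,1]\) per iteration.
2. **Observe** a 13-component summary state: mean and max of each normalised
   score, labeled fraction and labeled-positive fraction, the last
   validation metric with its one-step change and short moving average, the
   remaining-budget fraction, and the iteration fraction \(t/H\).
3. **Act**: the policy network emits three unconstrained logits with a
   learned state-independent log-SD; sampled logits pass through a softmax
   to give mixture weights \(w_t = (w^{unc}, w^{div}, w^{qbc})\) on the
   probability simplex. The softmax acts on the mixture logits, never on the
   raw per-patient scores.
4. **Query** the top-\(k\) patients by the composite score
   \(w^{unc}\,\tilde u + w^{div}\,\tilde d + w^{qbc}\,\tilde q\) (plus a
   seeded uniform \((0, 10^{-6})\) jitter used purely as a tie-break), and
   overwrite their proxy values with the reference label. Patients are
   labeled without replacement and never re-queried; the final batch may be
   short.
5. **Retrain** the downstream model from scratch — an L2-regularised
   logistic regression of the outcome on \((S_t, X_2)\), and in survival
   mode a ridge-penalised Cox model
   \(h(t \mid Z) = h_0(t)\exp(\beta^\top Z)\) with \(Z = (S_t, X_2)\) after
   feature screening — and evaluate it on the validation set.
6. **Reward** the agent with
   \(R_t = (m_t - \bar m_{t-w:t-1})(1 + c \cdot b_t)\), where \(m_t\) is the
   validation metric (AUC in classification, C-index in survival),
   \(\bar m\) a moving baseline over the last \(w = 3\) values, \(b_t\) the
   remaining-budget fraction, and \(c = 0.5\). Transitions are stored and
   the policy is updated periodically with PPO (clipped importance-ratio
   surrogate, generalized advantage estimation, value-function baseline),
   maximising \(E[\sum_t \gamma^{t-1} R_t]\).

Fixed-strategy comparators (`uncertainty`, `diversity`, `qbc`) run the same
loop with the corresponding one-hot mixture; `random` replaces the ranking
by uniform sampling; `proxy_only` and `oracle` fit once with \(S^*\) or the
reference everywhere and bracket the achievable range.

## Validation mirroring

The evaluation protocol mirrors the replacement dynamics on the validation
set: at each iteration, \(k_{val} = \mathrm{round}(k \cdot
|\mathrm{val}|/|\mathrm{train}|)\) not-yet-upgraded validation patients —
ranked by the same composite score under the same weights, using the current
model and committee — have their phenotype feature upgraded from proxy to
reference for evaluation purposes. Two readings of "mirroring" are possible
(replacement by the training policy's ranking, or by an independent rule);
we adopt the former and expose `mirror_validation = FALSE` to evaluate with
proxy features throughout as a sensitivity analysis. When the training pool
is exhausted (budget at least the pool size) the remaining validation
patients are upgraded as well, which makes the full-budget run coincide
exactly with the oracle — a property the test suite exploits as a reduction
oracle.

## The synthetic cohort generator

No real patient data ship with (or were used to build) this package; the
generator is a first-class module that produces the study conditions.

* `X1` is i.i.d. standard normal; the reference phenotype is Bernoulli with
  a logit linear in `X1` (slope \(1.5/\sqrt{d_1}\) per column) and an
  intercept calibrated by monotone root-finding so the empirical prevalence
  matches the target to \(10^{-6}\).
* The proxy follows the chain `X1 -> Strue -> S*`: an observable code
  signal is present for a `proxy_sensitivity` fraction of true positives
  and never for true negatives — one-sided under-ascertainment, mirroring
  settings where roughly 30% of patients self-report a behaviour but only
  about 10% carry any related diagnosis code. The proxy score is the
  logistic transform of a calibrated intercept plus the signal plus
  Gaussian logit noise (`proxy_noise_sd`). In the noiseless, fully
  sensitive limit the proxy separates the phenotype perfectly, and any
  masking or noise strictly degrades it.
* The outcome is Bernoulli with logit \(\alpha +
  \beta_s S_{true} + \beta^\top X_2\) (default \(\beta_s = 1.5\),
  alternating \(\pm 0.5\) on `X2`), with \(\alpha\) calibrated to the
  outcome prevalence; presets expose the 1%, 10%, and 30% prevalence sweep.
* Event times are exponential with log-hazard equal to the same linear
  predictor, administratively censored at the empirical quantile giving the
  configured censoring rate — the simplest mechanism consistent with the
  downstream Cox form.
* All randomness flows from one integer seed through per-field sub-streams,
  so cohorts are reproducible field-by-field and replications differ only
  where they should.

`ehr_fixture_cohort()` is a separate, clearly synthetic fixture whose
marginals are calibrated to published summary statistics of a large US
academic health-system lung-cancer cohort — outcome prevalence 0.78%,
smoking-code coverage 9.0%, never-smoker fraction 52.7% — with sparse
binary code indicators and a code-only logistic proxy, for tests that need
realistic rare-event marginals.

What the generator does *not* emulate: clinical notes and NLP/LLM
extraction, missing-data mechanisms, site and temporal coding drift,
correlated covariates, or label noise in the reference itself. Passing
tests therefore demonstrate that the machinery behaves as specified under
the stated generative assumptions, not that the method attains any
particular performance on real EHR data.

## Numerical and design choices

* **Z-scores** use the population (divide-by-\(n\)) standard deviation of
  the current labeled set; zero-variance columns are centered only, so
  constants never produce NaN.
* **Degenerate min–max ranges** map to all zeros: a strategy with no spread
  contributes nothing that round.
* **Tie-breaking** adds a seeded uniform \((0, 10^{-6})\) jitter to the
  composite; with all scores constant the selection reduces to the jitter
  ordering, i.e. seeded random sampling.
* **Committee inputs**: strategy models use the reference label for labeled
  patients and the continuous proxy for unlabeled ones. The committee
  predicts the *phenotype* from the (z-scored) covariates, because the
  balanced seed set guarantees both phenotype classes from the first
  iteration — an outcome-targeted committee would be undefined for rare
  outcomes and small seed sets.
* **The ridge logistic fit** is a damped Newton iteration on the penalised
  log-likelihood (intercept unpenalised, default penalty 1.0, retrained
  from scratch each iteration); it is exact for these small dimensions and
  is cross-checked against `glmnet` at matched penalty in the tests. The
  Cox fit delegates to `survival::coxph` with a `ridge` term (default
  penalty 0.1) after screening (drop zero-variance columns; optionally cap
  dimension by univariate score statistics).
* **Operating point**: threshold metrics are computed at the smallest
  observed cutoff whose empirical false-positive rate is at most 0.1 — no
  interpolation, so the attained FPR is the largest achievable value not
  exceeding 0.1. If no cutoff qualifies, nothing is called positive and
  TPR/PPV/F1 are 0.
* **PPO defaults**: \(\gamma = 0.99\), clip 0.2, GAE \(\lambda = 0.95\),
  one update per iteration from the trailing segment (bootstrapping the
  value of the next observed state; zero at episode end), Adam at 0.02 for
  8 full-batch epochs, hidden width 8, initial policy SD 0.5, entropy bonus
  0 by default. The value network is zero-initialised so a zero-reward
  segment has exactly zero advantages and provably leaves all parameters
  unchanged. The state layout is fixed at the 13 components listed above.
* **Aggregation** uses the normal-approximation 95% CI
  (\(\bar x \pm 1.96\,s/\sqrt{R}\)) across replications, reported as absent
  for a single replication. Within a replication all methods share the
  split and seed set, so between-arm contrasts are paired.
* **Replication seeds** are `master_seed XOR r`; the cohort itself is
  generated once from its own seed and re-split per replication.

## Problem sizes

The package's benchmark preset (`desk_preset()`) uses a cohort of 20 000
patients, a budget of 4000 queried in batches of 200 over a balanced seed
set of 200, and 5 replications — preserving the ~25–43% relative budget
regime of a full-scale run (a 238k cohort with an 82k budget, i.e. 34.4% of
the cohort) at roughly one-hundredth the computation. The acceptance script
uses a further reduced 8000-patient cohort with a budget of 1600 over 3
replications. These sizes were chosen once as the package's reference
conditions; the same code runs unchanged at larger sizes.

## A worked example

```{r example, eval = FALSE}
cfg <- desk_preset(master_seed = 1)
out <- run_replications(cfg)
aggregate_results(out)
```

On the default synthetic cohort this prints, per method and iteration, mean
validation metrics with 95% CIs; the querying arms' final AUC lies between
the proxy-only baseline and the oracle, and the gap between strategies is
wider at 1% outcome prevalence than at 30%.

## Limitations

The agent optimises a single scalar reward; multi-metric rewards are out of
scope. The policy sees only the constructed summary state (the process is
partially observed by design). No off-policy algorithms, density-weighted
or core-set strategies, time-dependent covariates, or competing risks are
implemented. Synthetic validation cannot establish real-data performance;
it establishes correctness of the mechanism under known generative
conditions.
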