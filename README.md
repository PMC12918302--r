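# releap

Reinforcement-guided active learning for correcting noisy proxy phenotype
labels under a fixed query budget.

## The problem

Risk models built from electronic health records routinely condition on
intermediate phenotypes (smoking status is the motivating example) that are
observed only through a cheap, noisy proxy `S*` — e.g. a score built from
diagnosis codes, which under-ascertain the behaviour: in the motivating
setting roughly 30% of patients self-report smoking while only about 10%
carry any smoking-related code. A high-fidelity reference label `Strue`
exists but is costly, so only a budgeted number of patients can be upgraded
from `S*` to `Strue`. The question is which patients to upgrade so that the
*downstream* risk model — an L2-regularised logistic regression of the
outcome `Y` on `(St, X2)`, or a penalized Cox model
`h(t|Z) = h0(t) exp(beta'Z)` with `Z = (St, X2)` — gains the most
validation performance per label.

## The method

The package maintains a phenotype vector `St` (initialised `S0 = S*`) and,
at each of `H = ceil(budget/k)` iterations, scores every unlabeled patient
with three active-learning strategies:

* **uncertainty** — binary entropy `H(p) = -p log p - (1-p) log(1-p)` of
  the current model's predicted outcome probability;
* **diversity** — distance to the nearest labeled patient in z-scored
  feature space, with a variance adjustment;
* **query-by-committee** — disagreement across `M = 7` bootstrap logistic
  models with jittered L2 penalties and feature dropout 0.1.

Scores are min–max normalised per iteration and combined under mixture
weights `w = (w_unc, w_div, w_qbc)` on the probability simplex. A policy
network trained with proximal policy optimization (PPO) chooses `w` from a
13-component summary state (score summaries, labeled-set composition,
recent metric trajectory, remaining budget, iteration fraction); its reward
is the shaped improvement of the validation metric (AUC or C-index) over a
short moving baseline, with mild budget-aware scaling. Fixed one-hot
mixtures reproduce the classical single-strategy heuristics exactly;
`proxy_only` and `oracle` arms bracket the achievable range.

A seeded synthetic cohort simulator (structure `X1 -> Strue -> S*`,
`(Strue, X2) -> Y`, calibrated prevalences at 1/10/30%, one-sided proxy
under-ascertainment) makes the whole pipeline runnable and testable with no
data download. See the vignette in `vignettes/phenotype-correction.Rmd` for
the model, assumptions, and all numerical choices.

## A worked example

```r
library(releap)

cohort <- generate_cohort(cohort_config(n_patients = 8000,
                                        outcome_prevalence = 0.10, seed = 1))
cfg <- experiment_config(cohort = cohort,
                         methods = c("proxy_only", "uncertainty", "releap",
                                     "oracle"),
                         n_replications = 3, budget_total = 1600,
                         batch_size_k = 100, seed_set_size = 100,
                         master_seed = 1)
out <- run_replications(cfg)
agg <- aggregate_results(out)
subset(agg, metric == "auc" & iteration == 16)
```

Mean final-iteration validation AUC over the 3 replications:

```
proxy_only   0.757
uncertainty  0.767
releap       0.765
oracle       0.800
```

Reading: the zero-label proxy baseline reaches AUC 0.757; spending the
1600-label budget through uncertainty sampling or the adaptive agent
recovers roughly a quarter of the gap towards the fully supervised oracle
(0.800) on this cohort, and calibration MSE falls from 0.083 (proxy) towards
the oracle's 0.078. Larger budgets close more of the gap; with the budget at
the pool size the querying arms coincide with the oracle exactly.

There is also a command-line interface (installed under `exec/`):

```sh
Rscript inst/exec/releap simulate --preset rare --n 20000 --seed 1 --out cohort.csv
Rscript inst/exec/releap compare --config cfg.yaml --out results/
Rscript inst/exec/releap report --in results/ --plot
```

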