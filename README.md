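# ruleglass

Rule-based explanations and tailored interventions for clinical risk
predictions.

## The problem

Machine learning models are the most accurate way to predict rare bad
clinical outcomes — severe COPD or asthma exacerbations needing an
inpatient stay or an emergency-department visit — and health systems use
their risk scores to pick the top decile of patients for review and the top
few percent for care-management enrollment. But the best models do not
explain their predictions, and a care manager deciding whom to enroll, and
with which interventions, needs reasons, not just a score.

`ruleglass` implements the two-model answer: keep the predictive model
untouched, and mine a *second* model — class-based association rules — from
the training data, using it only to explain the first model's positive
predictions and to attach expert-curated interventions. Explanation then
costs no predictive performance, works for any risk model on tabular data,
and every explanation is a human-readable rule.

## The method in brief

Each rule is a conjunction of feature–value items implying the bad outcome
class *z*:

    p1 AND p2 AND ... AND pk -> z

with two training-set quality measures: **commonality**
`n(LHS & z) / n(z)` (within-class support — coverage of the bad-outcome
class) and **confidence** `n(LHS & z) / n(LHS)` (precision). Continuous
features are first discretized by supervised entropy/MDL splitting. Mining
is level-wise Apriori under five control parameters: the number of
top-importance features used to form rules (default 80), the maximum
left-hand-side length (5), the commonality floor (1%), the confidence floor
(50%), and a confidence-difference tolerance (0.15) for subsumption pruning
— a rule is dropped when a strictly more general rule has confidence within
the tolerance of it. A final filter keeps only rules built entirely from
items an expert labeled positively correlated with the bad outcome.

At prediction time the top fraction of risk scores (default 10%) is flagged
positive; each flagged patient's matching rules are ranked by a five-factor
score (confidence, commonality, rule length, actionability, redundancy
against higher-ranked rules) and the top 3 are presented with the
interventions attached to their actionable items. Coverage metrics report
the fraction of correctly predicted positives — and of all outcome
positives — that receive at least one explanation.

## Worked example

Real EHR cohorts of this kind cannot be shipped, so the package includes a
synthetic-cohort generator with planted rules of known confidence:

```r
library(ruleglass)

cfg0 <- sim_config(n_instances = 5000, n_features = 20, seed = 42)
sim  <- simulate_cohort(sim_config(n_instances = 5000, n_features = 20,
                                   planted_rules = default_planted_rules(cfg0),
                                   seed = 42))
scheme <- fit_discretization(sim$cohort)
kb     <- synthetic_kb(scheme, sim$cohort, sim$truth)

fit <- ruleglass(sim$cohort, kb = kb,
                 config = mining_config(top_k_features = 20, max_lhs_items = 3))
fit
#> Rule-based explanation model
#>   features used: 20 | items: 45
#>   rules mined: 4886 -> after subsumption pruning (tol 0.15): 98 -> final: 8
#>   thresholds: commonality >= 0.01, confidence >= 0.5, max LHS items: 3
```

4,886 rules cleared the commonality and confidence floors; subsumption
pruning at tolerance 0.15 left 98, and the positive-correlation filter left
8 final (all actionable) rules. Explaining the top-10% risk instances:

```r
pred <- predict(fit, sim$cohort, top_fraction = 0.10, n_top = 3)
summary(pred)
#> Explanation coverage
#>   correctly predicted positives: 100.0% (385/385)
#>   all outcome positives:         95.6% (2147/2245)
#>   matching actionable rules per explained TP: mean 1.43 (SD 0.50), median 1, max 2
#>   unique actionable items per explained TP:   mean 1.43 (SD 0.50), median 1, max 2
```

Every correctly predicted positive received at least one explanation, and
95.6% of all outcome-positive instances match at least one rule regardless
of the model's prediction. One flagged patient's report, in the
rule / interpretation / interventions layout:

```r
pred$explanations[[20]]
#> Explanation for instance inst000020 (predicted_bad)
#>   matching rules: 1 (1 actionable), unique actionable items: 1
#>
#>   Rank 1 (score 1.4332, confidence 0.884, commonality 0.098):
#>     x01 >= 6.5 -> bad outcome
#>       * x01 >= 6.5
#>         interpretation: Elevated risk indicator on feature x01 (synthetic annotation)
#>         intervention:  Review and address the driver behind x01 (synthetic intervention)
#>         intervention:  Schedule focused follow-up for x01 (synthetic intervention)
```

The planted ground truth is fully recovered by the miner:

```r
rc <- recovery_check(fit$rules_mined, sim$truth, sim$cohort, fit$scheme)
rc$recovery
#> [1] 1
```

A real deployment replaces the simulated cohort with `read_cohort()` on a
CSV export (plus a JSON feature schema carrying plausibility bounds and the
upstream model's importance ranking) and the synthetic annotations with a
curated knowledge base (`read_kb()`); see
`inst/extdata/copd_example_kb.json` for the annotation format and
`inst/scripts/ruleglass` for a command-line front end
(`validate` / `kb-validate` / `discretize` / `mine` / `prune` / `explain` /
`simulate`).

## Documentation

The methods vignette (`vignettes/ruleglass-methods.Rmd`) documents the
model and its assumptions, the five control parameters, the discretizer's
numerical conventions, the subsumption witness-policy choice, the ranking
score, what the synthetic generator does and does not emulate, and known
limitations.
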