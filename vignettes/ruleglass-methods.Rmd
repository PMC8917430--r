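---
title: "Rule-based explanation of clinical risk predictions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based explanation of clinical risk predictions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruleglass)
```

## The two-model idea

A machine learning risk model (XGBoost, a random forest, logistic
regression — anything producing a risk score over tabular features) is
typically the most accurate choice for predicting a rare bad clinical
outcome, but it does not explain its predictions. `ruleglass` implements the
two-model strategy for that problem: the predictive model is left untouched,
and a *second* model — a set of class-based association rules mined from the
training data — is used only to explain the first model's positive
predictions and to attach expert-curated interventions. Because the
explaining model is separate, explanation costs no predictive performance.

Every rule has the form

$$p_1 \wedge p_2 \wedge \dots \wedge p_k \rightarrow z,$$

where each item $p_i$ is a feature–value pair — either equality with a
categorical level or membership in a numeric interval — and $z$ is the bad
outcome class. Two quality measures summarize a rule on the training set:

* **commonality** $= n(\mathrm{LHS} \wedge z)\, /\, n(z)$ — the fraction of
  bad-outcome instances satisfying the left-hand side (within-class
  support; the rule's coverage);
* **confidence** $= n(\mathrm{LHS} \wedge z)\, /\, n(\mathrm{LHS})$ — the
  fraction of satisfying instances whose outcome is bad (the rule's
  precision).

A rule *matches* a patient when the patient satisfies every left-hand-side
item; a missing value satisfies nothing. A patient's positive prediction is
*explained* when at least one rule matches.

## The five control parameters

Mining and pruning are governed by five parameters
(`mining_config()`):

| parameter | default | meaning |
|---|---|---|
| `top_k_features` | 80 | only the features ranked most important by the upstream model form rules |
| `max_lhs_items` | 5 | upper limit on left-hand-side length |
| `min_commonality` | 0.01 | floor on within-class support |
| `min_confidence` | 0.5 | floor on precision |
| `conf_diff_upper` | 0.15 | tolerance of subsumption pruning |

The commonality and confidence floors are the values commonly used for
class-based association rules on imbalanced clinical data; the length cap
keeps rules legible; the feature cap is normally set to the largest value
the mining machine's memory tolerates (the miner fails fast with an
instructive error when its candidate budget is exceeded). The
confidence-difference tolerance is chosen from the remaining-rules curve
(`rule_count_curve()`, `plot()` on a fitted model): the count falls steeply
at small tolerances and flattens; the tolerance is set where further
increases stop mattering. `suggest_elbow()` formalizes that reading as the
maximum perpendicular distance to the chord joining the curve's endpoints;
it is advisory only, and the axes are deliberately left unnormalized so the
suggestion tracks the raw count drop.

## Supervised discretization

Continuous features are converted to interval items by recursive binary
splitting that minimizes class entropy, with the minimum-description-length
(MDL) stopping criterion (Fayyad–Irani). Numerical conventions, all of
which matter for reproducibility:

* candidate cuts sit at midpoints between adjacent distinct values;
* ties in information gain resolve to the lowest cut, so the procedure is
  deterministic;
* intervals are half-open $[a, b)$, unbounded at the extremes, so the bins
  partition the real line and every value maps to exactly one item
  ("at most one item per feature" per instance);
* a feature with no accepted cut contributes a single all-range item;
  categorical features contribute one equality item per level observed at
  fit time, and unseen levels at prediction time map to no item.

An unsupervised equal-frequency alternative (`method = "frequency"`) is
available for sensitivity analyses. One-sided threshold items beyond the
partition bins (e.g. nested intervals) are not auto-generated — they can be
supplied through the knowledge base — because auto-generating overlapping
items would break the one-item-per-feature matching semantics that the
miner and the explainer rely on.

## Mining and the three reduction techniques

Rules are enumerated level-wise (Apriori). Commonality is anti-monotone —
adding an item can only shrink within-class support — so candidate
generation prunes on the commonality floor using within-class instance
lists only; confidence is *never* used for candidate pruning, only as an
output filter, because it is not anti-monotone. Left-hand sides never
combine two bins of one feature (their conjunction is unsatisfiable under
the partition convention). Output order is canonical (size, then
lexicographic key), making runs bit-reproducible.

Three techniques keep the rule set small enough for sub-second retrieval at
prediction time:

1. **Feature restriction** — only the `top_k_features` highest-importance
   features form rules (ties broken by name, deterministically).
2. **Subsumption pruning** — a rule $r_1$ is dropped when a more general
   rule $r_2$ (proper-subset left-hand side, same right-hand side) has
   confidence $\ge$ confidence$(r_1)$ − tolerance.
3. **Positive-correlation filtering** — only rules whose every item was
   labeled by the expert as possibly positively correlated with the bad
   outcome are kept. The default pipeline order is mine → prune → filter;
   `prefilter_correlated = TRUE` restricts the allowed items at mining time
   instead, which is cheaper and yields the same final semantics up to
   pruning witnesses.

### The witness-policy choice

"Another rule $r_2$" in the subsumption condition can be read two ways, and
the readings have incompatible guarantees — a design point this package
surfaces explicitly rather than hiding:

* `witness = "any"` (default): $r_2$ ranges over the whole mined set. Each
  drop decision is then independent of the others, and the number of
  survivors is provably nonincreasing in the tolerance — the qualitative
  shape of the remaining-rules curve. Its cost: a dropped rule's witness
  may itself have been dropped (justified in turn by a still more general
  rule, in a chain).
* `witness = "retained"`: rules are processed smallest-first and only
  surviving rules act as witnesses, so every dropped rule has a *surviving*
  more general rule within the tolerance. Its cost: monotonicity of the
  curve can fail, because a larger tolerance can eliminate the witness that
  would have justified dropping a specialization.

No policy delivers both guarantees (a three-rule chain with confidences
0.5, 0.8, 0.9 at tolerance 0.3 separates them). The default follows the
plain reading of the drop condition and preserves the monotone curve from
which the tolerance is chosen.

## Explaining a prediction

At prediction time, instances are flagged positive at a top-fraction
operating point: exactly $\lceil f \cdot n \rceil$ instances with the
largest risk scores (default $f = 0.10$, the usual care-management
screening decile), boundary ties broken by instance id. For each flagged
instance the matching rules are ranked iteratively and the top 3 (by
default) are presented with the interventions attached to their actionable
items, in a three-part layout: the rule, each item's clinical
interpretation, and each item's interventions.

The ranking score combines five factors — confidence, commonality,
left-hand-side length, actionability, and information redundancy against
the already-selected rules:

$$\mathrm{score}(r) = w_c\,\mathrm{conf}(r) + w_m\,\mathrm{comm}(r)
 - w_l\,\frac{k - 1}{\max(1, K - 1)} + w_a\,[r\ \mathrm{actionable}]
 - w_r \max_{s \in \mathrm{selected}} J(\mathrm{lhs}(r), \mathrm{lhs}(s)),$$

with $J$ the Jaccard overlap of item sets and $K$ the configured maximum
length. Defaults $w = (1.0, 0.5, 0.25, 0.5, 1.0)$ put confidence first,
reward actionability, and penalize near-duplicate rules (matching rule sets
are dominated by rules differing in a single item) at the same scale as
confidence. The linear combination itself is this package's design choice:
the five factors and the greedy iterative scheme are fixed by the method,
their functional combination is not published, so the weights are exposed
as `ranking_weights()` and the form is kept deliberately simple and
monotone in each factor. Selection is greedy with deterministic tie-breaks
(confidence, then brevity, then lexicographic key), which makes the ranking
invariant to input order.

## Evaluation metrics

`explanation_coverage()` reports:

* **coverage over true positives** — the fraction of correctly predicted
  bad-outcome instances matched by ≥ 1 rule;
* **coverage over all outcome positives** — the same fraction over every
  bad-outcome instance regardless of the prediction. This is deliberately
  prediction-independent: it asks how much of the outcome the rule set can
  speak to at all;
* distributions (equal-width histograms, default bin width max/20, plus
  mean/SD/median/max) of the number of matching actionable rules and of
  unique actionable items per explained true positive. Rule counts are
  reported both for all matching rules and for actionable ones, since the
  two are often conflated in summaries.

With a strong upstream model, coverage over true positives typically
exceeds coverage over all positives — misclassified positives tend to be
the rare, hard cases for rules too — but that is a data property, not an
invariant, and the package asserts only that both are valid fractions.

## The synthetic cohort generator

Real EHR cohorts of this kind cannot be redistributed, so every claim the
package makes is exercised against `simulate_cohort()`, which emulates the
statistical shape that matters to the method:

* an imbalanced binary outcome — default background rate 5%, close to the
  mid-single-digit prevalences of severe-exacerbation cohorts;
* mixed continuous/categorical features (`continuous_fraction`, default
  one half);
* planted conjunctive rules of known carrier fraction and confidence.

Design decisions, each with a reason:

* **Planted continuous features are integer counts.** Carriers draw from a
  block of high integers, everyone else from a block of low integers, with
  an empty margin band between. Count-like features (visit counts,
  prescription counts) are typical of EHR data, and the blocked construction
  makes the informative cut decisively optimal for the entropy/MDL
  discretizer: a cut inside a block would have to move an entire integer's
  worth of instances. With continuous uniform clusters the optimal cut
  wobbles around the cluster edge by a handful of instances, and the
  recovered bin then differs from the planted item by those instances.
* **Carrier sets are disjoint across rules** (carrier fractions must sum
  below 1). With overlapping carriers and max-confidence outcome
  semantics, a low-confidence rule's carriers inherit higher-confidence
  outcomes and its realized confidence is biased upward (about +0.07 for a
  0.6-target rule in a five-rule default configuration); disjoint carriers
  make every planted rule's realized confidence an unbiased binomial draw
  at its own target, which is what the recovery study asserts.
* **Importance weights favor planted features** (uniform on (0.5, 1) vs
  (0, 0.5) for noise features), emulating an upstream model that found the
  real signal; top-feature selection then behaves as it would downstream of
  a competent classifier.
* **Risk scores** are a noisy logit-space perturbation of the generating
  outcome probability, giving an imperfect but informative upstream model,
  so the top-decile cutoff produces both true and false positives and
  negatives.
* **Missingness** (default off) is injected uniformly over feature cells
  only, after outcomes are drawn, so it dilutes rule support without
  biasing confidence.

`recovery_check()` asks, for every planted rule whose *realized*
commonality and confidence clear the mining floors, whether its exact
left-hand side was mined. Exactness is extensional: a mined item matches a
planted item when it sits on the same feature and is satisfied by exactly
the same instances. For interval items this is the only decidable reading —
the recovered cut lands at a data midpoint inside the planted margin band,
so endpoint equality is unattainable by construction while the item itself
is exactly right.

What passing these studies does *not* show about real data: the generator
plants axis-aligned, cleanly separated signals with independent noise
features; real EHR features are correlated, drifting, and systematically
missing, and real experts label items with judgment the synthetic knowledge
base (`synthetic_kb()`) only mimics. The studies validate the machinery —
counting, enumeration completeness, pruning logic, calibration — not
clinical performance.

## Problem sizes and numerical choices

The shipped validation uses cohorts of 5,000 instances × 20 features for
the recovery study (five planted rules, confidences 0.9–0.6, carrier
fractions 5–20%) and 20,000 × 40 for the end-to-end run (top-20 features,
left-hand sides up to 3 items — the planted rules use at most 2, so the cap
exercises strictly larger conjunctions without inflating the candidate
space). Oracle-equivalence checks run exhaustive enumeration on dozens of
random data sets of up to 12 items and 300 instances, where full subset
enumeration is cheap and independent of the level-wise implementation.

Degenerate inputs are handled explicitly: all-missing features warn and
emit no items; a left-hand side satisfied by no instance has undefined
confidence and is never emitted; a flat remaining-rules curve returns the
smallest tolerance with a warning; zero true positives make the
true-positive coverage `NA` rather than 0.

## Known limitations

* The ranking weights are defaults, not fitted quantities; different
  weightings reorder near-tied rules.
* Subsumption pruning compares confidences only; a statistical test on the
  confidence difference (accounting for support) is out of scope.
* Only bad-outcome rules are mined; good-outcome ("protective") rules are
  out of scope.
* The miner is in-memory, level-wise R; it is comfortable at the desk
  scales above, and the candidate budget guards, rather than removes, the
  exponential worst case.
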