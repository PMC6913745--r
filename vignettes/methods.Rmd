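---
title: "Methods: learning and querying the clinician-estimate network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: learning and querying the clinician-estimate network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icubn)
```

## The problem and the model

When a patient is acutely admitted to an intensive-care unit, the examiner
(student or physician) estimates cardiac function on a four-level scale —
poor, moderate, reasonable, good — from bedside information alone, before
any ultrasound measurement is available. `icubn` models the joint
distribution of that estimate and 14 discretized clinical variables
(vasopressor use, ventilation status, blood pressures, heart rhythm,
lactate, urine output, peripheral perfusion signs, age, gender, and so on)
as a discrete Bayesian network: a directed acyclic graph $G$ over
variables $X_1,\dots,X_k$ together with one conditional probability table
(CPT) per node, so that

$$P(X_1,\dots,X_k) \;=\; \prod_{i=1}^{k} P\!\left(X_i \mid \mathrm{pa}_G(X_i)\right).$$

Arcs express conditional dependence; the parents of *estimate* are the
variables the examiners' judgement is directly conditioned on. The
companion question — how good is the estimate? — is answered separately by
classical diagnostic-accuracy statistics against the dichotomized cardiac
index (low: $\le$ 2.2 L/min/m²) measured by critical-care ultrasonography.

## Structure learning

`mmhc()` implements Max-Min Hill-Climbing:

1. **Constraint phase** (`mmpc()`). For each target $T$ a candidate
   parent-children set is grown greedily: the next admitted variable is
   the one whose *minimum* association with $T$ — the largest $G^2$
   p-value over all subsets of the current set (capped at `max_sx = 3`
   conditioning variables) — is strongest, stopping when every remaining
   variable is separable at level $\alpha$. A backward pass re-tests each
   member given subsets of the others, and the symmetry correction keeps
   $X \in \mathrm{CPC}(T)$ only if $T \in \mathrm{CPC}(X)$.
2. **Search phase** (`hill_climb()`). Greedy arc addition/deletion/
   reversal restricted to candidate pairs, maximizing the BDeu score
   (equivalent sample size `ess`), until no move improves it. The search
   starts from the whitelist-only graph and is deterministic: moves are
   enumerated lexicographically (sorted node names; add before delete
   before reverse) and the first of tied best moves wins.

The $G^2$ statistic is $2\sum O \ln(O/E)$ over the $x \times y$ table in
each stratum of the conditioning set; empty cells contribute zero and the
degrees of freedom $(r_x-1)(r_y-1)\,q$ count only strata with
observations. The BDeu local score uses $\alpha_{jk} = \mathrm{ess}/(rq)$,
which makes Markov-equivalent DAGs score identically — the test suite
checks covered-arc reversals to $10^{-9}$.

Prior knowledge enters as constraints (`sics_constraints()`): age and
gender are exogenous, so all arcs into them are blacklisted, and the
estimate influences nothing, so all arcs out of it are blacklisted.

**Defaults and why.** `alpha = 0.05` and `ess = 1` are the conventional
defaults of this learner family; the source analysis does not state
either, so both are configuration (`score_params()`), not constants. The
initial DAG is the whitelist-only graph because the analysis describes a
single deterministic search, not restarts.

## Bootstrap consensus

`bootstrap_confidence()` resamples the cohort with replacement
(study scale: R = 2000 replicates; the desk-scale default used by tests
is 200) and relearns the structure each time. Every unordered pair gets a
*strength* (fraction of replicates containing the edge in either
orientation) and a *direction* coefficient, defined **conditionally on
presence**: among replicates containing the edge, the fraction oriented
the reported way. The conditional convention is an interpretation choice;
it is the one consistent with a published edge of strength 0.994 and
direction 0.504 (an always-present edge with maximally uncertain
orientation).

`build_consensus()` retains edges whose strength strictly exceeds
$\max(\text{data-driven threshold}, 0.700)$. The data-driven value is the
L1-optimal cutpoint of the empirical strength CDF (the length-weighted
median of its step heights, mapped back through the generalized quantile
function). Strict `>` at the strength floor and inclusive `>=` at the
0.666 direction threshold follow the wording of the thresholds ("minimum
significance threshold", "below 0.666 ... considered undirected"): the
floor itself does not qualify, the direction threshold itself does.
A retained edge with both orientations under 0.666 stays undirected;
`orient_undirected()` then applies expert orientations (here: high
respiratory rate → mechanical ventilation) and refuses to create cycles.
A cycle among retained directed arcs is reported as an error rather than
repaired, because it signals an inconsistent confidence table.

## Exact inference

`fit_cpts()` estimates CPT rows as $(N_{jk} + c)/(N_j + rc)$ with
pseudocount $c = 1$ by default (Laplace), keeping all probabilities
strictly positive as exact inference requires; $c$ is configuration.
`posterior()` answers conditional queries by sum-product variable
elimination with a greedy min-width elimination order — the order affects
only speed, never the answer, and on this 15-node problem every query is
milliseconds. The engine is validated against an independent full-joint
enumeration oracle on hundreds of random networks (max error below
$10^{-9}$).

`query_tree()` produces the tree-diagram view: evidence variables are
revealed in a fixed order (ventilation, noradrenaline, dCRT-M), and every
node stores the accumulated evidence, its exact probability, and the
conditional estimate distribution. Two invariants are enforced by tests:
branch probabilities sum to one at every node, and each parent's
distribution equals the branch-weighted average of its children (law of
total probability).

One subtlety: ventilation is *not* a parent of the estimate, yet
conditioning on it shifts the estimate distribution. This happens through
marginalization over dCRT-M (a child of ventilation and parent of the
estimate); the package reproduces the published ventilation-conditioned
values through exactly this mechanism.

## The synthetic cohort: what it emulates and what it does not

The study cohort (~1075 ICU patients; 73% with a validated cardiac index)
is not publicly deposited. `build_ground_truth()` therefore constructs a
fully specified stand-in: the 14-arc consensus structure plus a
cardiac-index node attached to the estimate, with CPTs calibrated so that

- every published prevalence (noradrenaline 49%, ventilation 59%, male
  gender 63%, irregular rhythm 11%, cold extremities 37.2%) is matched
  *exactly* by forward inference (root finding on each node's baseline
  rate against the exact parent joint; verified to $10^{-6}$ by
  `calibration_report()`, in practice machine precision);
- the four published probabilities of a reasonable-or-good estimate given
  ventilation and noradrenaline status (0.63 / 0.91 / 0.67 / 0.93) hold
  exactly, via the closed-form solution of the linear system that links
  them through the dCRT-M rates under ventilation;
- the cardiac index attaches to the *estimate alone* with
  $P(\text{low} \mid \text{est low}) = 0.464$ and
  $P(\text{low} \mid \text{est high}) = 0.33$ — the PPV and 1 − NPV of
  the reconstructed overall 2×2 table — the minimal structure that
  reproduces the published accuracy behaviour without inventing
  unprinted dependencies;
- the cardiac index is masked completely at random at 292/1075, matching
  the reported ultrasound feasibility and the similarity of measured and
  unmeasured patients.

Unprinted quantities are configuration defaults chosen once as clinically
plausible values: prevalences not in the publication (tachycardia 28%,
high respiratory rate 25%, low SBP 25%, low DBP 30%, low MAP 28%,
elevated lactate 28%, oliguria 30%, age ≥ 65 at 42%) follow the published
means/medians of the underlying continuous measurements under the default
cutoffs; dCRT-M rates are 0.45 (ventilated) vs 0.30 (not ventilated).
Conditional effect sizes are relative risks. Three were revised during
calibration, before being frozen: the low-MAP profile (3.0 × for low SBP,
2.6 × for low DBP — the initial stronger profile made the 28% target
algebraically unreachable, which the calibrator reports as an error), the
age effect on irregular rhythm (6.5 ×, i.e. atrial fibrillation at ~22%
in the elderly vs ~3% below 65 — a weaker first choice was inconsistent
with the published near-certainty of that arc), and the ventilation
profile (1.5 × for tachypnoea, 1.45 × for noradrenaline — the strongest
jointly feasible profile under the exact 59% marginal, again because the
published confidence in that edge is near 1).

A green test on this cohort therefore establishes that the pipeline
*recovers a known truth of the published shape at the published sample
size* — not that it would recover the real SICS-I structure, and not that
the real data satisfy the generator's simplifications (no residual
dependence of the cardiac index on clinical variables given the estimate,
missingness completely at random, complete clinical predictors,
independence of patients). Real-data quantities that depend on
unpublished structure (for example the cross-validated AUROC of the real
cohort) are treated as plausibility bands, not numeric targets.

## Diagnostic accuracy

`dx_metrics()` reports sensitivity, specificity, PPV, NPV and accuracy
with Wilson score intervals and the likelihood ratios
$LR^+ = \mathrm{sens}/(1-\mathrm{spec})$,
$LR^- = (1-\mathrm{sens})/\mathrm{spec}$ with standard log-method
intervals. The interval methods are not named in the source; Wilson + log
is the only standard pair whose bounds reproduce the printed overall CIs,
which is itself verified by `reconstruct_overall_table()`: an exhaustive
search over all 2×2 tables with margins (183, 600) for the unique table
matching *every* printed overall value at its printed rounding (half away
from zero). The per-examiner columns are not reconstructed: their printed
roundings admit no exactly consistent integer table, so only the overall
column is used as a fixture.

`cross_validate()` partitions records once into ten folds, refits CPTs on
the training folds with the structure held fixed, and scores the held-out
predicted probability of a *low* estimate against the dichotomized
cardiac index (AUROC by the rank statistic with midrank ties). A
probability score is the default because dichotomized class predictions
make the ROC degenerate; whether the original analysis scored classes or
probabilities is not stated.

## Degenerate inputs and numerical conventions

- Discretization assigns boundary values to the lower (non-abnormal) bin;
  the two inclusive protocol definitions (age ≥ 65, cardiac index ≤ 2.2)
  are encoded as inclusive operators rather than exceptions.
- $0 \ln 0 := 0$ in $G^2$; conditioning strata with no observations add
  no degrees of freedom.
- Zero-probability evidence raises an inconsistency error instead of
  returning NaN; CPT fitting with pseudocount 0 fails loudly on
  unobserved parent configurations.
- Cramér's V drops unobserved states before computing $\chi^2$, making it
  invariant to relabeling and to declared-but-unseen categories; a
  variable with a single observed state is an error, not V = 0.
- All stochastic functions take an explicit seed and restore the caller's
  RNG state; the pipeline derives every stage seed from one master seed.

## Known limitations

- The learner is exact only in the sense of local search: on small
  problems it provably reaches the global BDeu optimum (tested by
  exhaustive enumeration on 3 nodes), but on 15 nodes it inherits MMHC's
  usual local-optimum caveat.
- The generator produces discretized states directly; it does not emulate
  raw continuous measurements, repeated measurements, severity scores or
  mortality.
- Inference is exact variable elimination without a junction-tree cache;
  adequate here, but not tuned for networks far larger than this one.
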