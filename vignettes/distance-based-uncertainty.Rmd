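---
title: "Distance-based epistemic uncertainty for binary risk classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based epistemic uncertainty for binary risk classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distuq)
```

## The model and its assumptions

`distuq` quantifies the *epistemic* uncertainty of a binary classification:
the component of uncertainty that comes from limited or unrepresentative
training data, and that would shrink if more data could be collected. The
measure is deliberately simple — a 1-nearest-neighbour (optionally
k-nearest-neighbour) distance construction in the model's feature space —
so that a clinical user can see exactly what it responds to: how far the
case at hand sits from the training examples of each class.

For case $y$ and candidate label $x$, with $D_x(y)$ the Manhattan distance
to the nearest training case of label $x$, the score is

$$\mathrm{Uncertainty}(y, x) \;=\; D_x(y)\cdot\frac{D_x(y)}{a} \;=\; \frac{D_x(y)^2}{a},$$

where $a$ is a reference distance. Two conventions for $a$ are implemented
and recorded in every result:

* **opposite-label** (default): $a$ is the distance to the nearest training
  case that does *not* carry label $x$, so
  $U_{LR} = D_{LR}^2/D_{HR}$ and $U_{HR} = D_{HR}^2/D_{LR}$;
* **global-min**: $a = \min(D_{LR}, D_{HR})$ for both labels, under which
  the nearer label's score collapses to its raw distance.

The default was chosen by validation against the method's four worked
examples: only the opposite-label convention reproduces all four printed
scores at two decimals (`score_case(0.19, 0.28)` gives 0.13 where global-min
gives 0.19), so global-min is retained only as an explicit variant for
sensitivity analysis. The final risk class is the label with the smaller
score — the score closest to 0 — and an exact tie is reported as
`INDETERMINATE` (a flag, not a default; `run_config(tie_break =
"predicted")` lets the classifier's prediction break ties explicitly).

Key assumptions the user accepts with this measure:

* **It is an applicability-domain check, not a noise model.** The score
  detects cases in sparsely covered regions of feature space; it says
  nothing about aleatoric uncertainty (measurement error, intrinsic outcome
  variability), and it can *underestimate* uncertainty for an outlier that
  happens to be clearly nearer one class than the other.
* **Distances are meaningful on the feature scale used.** Manhattan distance
  sums per-feature absolute differences, so features on wildly different
  scales dominate or vanish. Scaling is therefore a visible parameter
  (`scaling = "none" | "minmax" | "zscore"`), fitted on the training cohort
  only and re-applied to every test case; the choice is recorded in the
  cohort object and in the resolved run configuration written next to every
  output.
* **The training cohort is the reference.** All distances, summaries and
  traffic-light percentiles are computed against the training split;
  nothing is ever calibrated on test cases.

## Edge cases of the score

$D_x(y) = 0$ scores 0 even when the reference distance is also 0: an exact
training duplicate is maximal certainty. $D_x(y) > 0$ with a zero reference
scores `Inf`: the case coincides with an opposite-label training example,
maximal uncertainty for label $x$. Infinite scores survive to the report
layer (serialized as the token `"inf"`) and raise a warning in the
pipeline, as does any disagreement between the probability classifier's
prediction and the distance-based final class — disagreements are the
"difficult cases" the method exists to surface, so they are reported, never
reconciled automatically.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 1 | neighbours averaged per label; `k > 1` (mean of the k smallest distances) smooths over single outlying training cases |
| `p` | 1 | Minkowski order; 1 (Manhattan) is the convention the worked examples use, larger `p` is for sensitivity checks |
| `uq_variant` | `"opposite-label"` | reference-distance convention (above) |
| `scaling` | `"none"` | feature scaling fitted on the training cohort |
| `threshold` | `NULL` → event rate | positive-class probability cut-off; `NULL` calibrates it to the training prevalence of the positive class (0.36 for a 36%-positive cohort), the standard mitigation for class imbalance, boundary-inclusive on the positive side |
| `quantile_definition` | `"all-pairs"` | which within-group distance population summaries and traffic lights use |
| traffic-light percentiles | (50, 75) | illustration only; mandatory argument, see below |

### The two within-group distance populations

A "within-group distance distribution" can mean two different populations:
every unordered within-label pair counted once (**all-pairs**), or each
member's distance to its nearest same-label neighbour (**nearest-only**).
The two differ greatly on clustered data, and published summary tables
rarely say which was used — indeed a published quantile row and a published
mean intra-group distance can be impossible to reconcile under any single
population. `distuq` therefore implements both and makes the choice an
explicit argument everywhere; no function silently assumes one.

The directed mean nearest distances (`LR→HR`, `HR→LR`, and the two
intra-group directions) use each source-group member's *minimum* distance
into the target group. This population is genuinely asymmetric — a tight
cluster near one edge of a dispersed group gives a small mean in one
direction and a large one in the other — which is exactly the signature of
empty feature-space regions between groups, and is why an all-pairs mean
(necessarily symmetric between groups) could not be the right reading.

## Traffic lights

`categorize_uncertainty()` compares the case's distance to the nearest
training example of its *predicted* class against percentiles of that
class's within-group training distance distribution: at or below the green
percentile value → GREEN (uncertainty low); above it but at or below the
amber percentile value → AMBER (uncertainty medium — exercise caution);
above → RED (uncertainty high). Boundaries are upper-inclusive; this
half-open convention is a documented choice validated on the worked
anecdote (distance 0.21 against an LR group with median 0.20 and 75th
percentile 0.34 must land AMBER). Whether a case *exactly at* the median is
GREEN or AMBER is not decidable from the method's description; the
inclusive-upper rule is our convention, stated rather than asserted as
intent. Off-grid percentiles interpolate linearly between order statistics
(`stats::quantile` type 7); summaries built from a published five-number
table can only serve the five printed percentiles and error otherwise.

There are deliberately **no default thresholds in the API**: generic
uncertainty cut-offs are the "magic number" failure mode, so
`traffic_light_config()` is a mandatory argument and the (50, 75) bands are
documented as an illustration to be recalibrated per model, disease and
clinic. The categorized quantity is the distance itself (the quantity the
within-group distribution is a distribution *of*), not the UQ score; a
score-based mode would need a reference distribution of scores and is left
to the user via the same config mechanism.

## The synthetic scenario generator

Real radiomics cohorts cannot ship with a package, so testing runs on
seeded synthetic cohorts that emulate the qualitative regimes that matter
to a distance-based measure:

* `EVEN_COVERAGE` — both classes drawn from one shared distribution; the
  two within-group median distances agree closely (the idealized,
  data-hungry regime).
* `CLUSTERED_NEG_SPARSE_POS` — tight negative cluster (spread 0.3), diffuse
  positive class (spread 1.2): the negative within-group median is reliably
  the smaller.
* `TWO_SEPARATED_CLUSTERS` — two equally tight clusters far apart: all
  inter-group directed means exceed all intra-group means, i.e. empty space
  between the classes.
* `NONLINEAR_BOUNDARY` — two interleaved crescents, on which a linear
  logistic boundary demonstrably underperforms a 1-NN rule.

Default class sizes are 85 negative / 47 positive — the scale of a small
single-centre rare-disease cohort — with independent Gaussian per-feature
noise (a `"uniform"` family is available; the crescents' arc structure is
deterministic given the seed). Generation is a pure function of
(specification, seed). `generate_boundary_cases()` then constructs probe
cases by perturbing training members (`IN_CLUSTER`), bisecting along
segments between opposite-label pairs until the two per-label distances tie
(`NEAR_BOUNDARY`), or pushing points outward until they are farther from
every training case than the cohort's maximum within-group distance
(`OUTLIER_EMPTY_SPACE`).

What passing tests on these cohorts shows — and does not show: they verify
the distance algebra, the score's invariances (monotonicity, scale
covariance, label-swap symmetry), the regime orderings, and the end-to-end
pipeline on data whose geometry is known by construction. They do not show
that any particular clinical feature pair is well served by Manhattan
distance, nor reproduce any real cohort's summary values or a real model's
accuracy — those are properties of external data the package does not
bundle.

## Numerical choices

* Problem sizes in the test suite: oracle-equivalence checks run 100 random
  cohorts of 8–30 cases in 2–5 features against brute-force enumeration;
  regime-ordering checks run 100 seeded replicates at the default 85 + 47
  cohort size. Both populations are large enough to exercise every code
  path while keeping the full suite under a minute on one core.
* Report files render numerics at 2 decimals (matching clinical report
  tables); JSON outputs keep full precision. Recomputing a score from
  2-dp-rounded distances reproduces 2-dp scores only approximately (e.g.
  0.41 vs a printed 0.42 when the original was scored on unrounded
  distances) — a rounding-provenance effect, documented rather than
  corrected.
* Ties among k-th nearest neighbours are harmless: distances are scalars
  and the mean over the k smallest values is permutation-stable.
* Bisection for `NEAR_BOUNDARY` probes runs 60 halvings of the segment
  (ample for double precision); the sign change of
  $D_{LR} - D_{HR}$ along a segment joining an LR case to an HR case is
  guaranteed because the function is continuous and has opposite signs at
  the endpoints.

## Known limitations

The score only addresses epistemic uncertainty, and only its
data-coverage aspect; it has no notion of label noise, and a weighted
metric or a density-aware method would handle empty-space outliers that are
nonetheless class-asymmetric better. Cohorts are assumed small (hundreds of
cases): all neighbour searches are exact scans, with no approximate
indexing. Missing feature values are rejected, not imputed — the metric has
no defined behaviour for them.
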