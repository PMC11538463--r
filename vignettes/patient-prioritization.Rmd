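---
title: "Prioritized fuzzy-linguistic WASPAS: models, parameters and design notes"
author: "qrf2l"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritized fuzzy-linguistic WASPAS: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrf2l)
```

## The problem and the data model

Hospitals that triage admissions face a group decision problem: several
experts, not equally authoritative, rate several patients on several
criteria that are themselves ordered by importance (disease severity before
emergency degree before special-disease priority before insurance type).
Judgements are linguistic ("good", "very poor") and hedged: an expert may
support a label only partially and simultaneously hold evidence against it.

The package's elementary datum, the *q-rung orthopair fuzzy 2-tuple
linguistic number* (q-RF2LN), encodes exactly this. It couples

* a **linguistic 2-tuple** $(s_r, \Delta)$: a label $s_r$ from an ordered
  term set $S = \{s_0, \dots, s_{g-1}\}$ of odd cardinality $g$ plus a
  symbolic translation $\Delta \in [-0.5, 0.5)$. The pair is equivalent to
  the real number $\varsigma = r + \Delta \in [0, g-1]$, and `toTwoTuple()`
  / `fromTwoTuple()` convert back and forth without information loss
  (rounding ties go up, so $\Delta$ always stays in its half-open
  interval);
* an **orthopair** $\langle m, n \rangle$ of membership and non-membership
  grades constrained by $m^q + n^q \le 1$. The rung $q \ge 1$ controls how
  much simultaneous support and opposition is admissible: $q = 1$ is the
  intuitionistic constraint, $q = 2$ the Pythagorean one, and a judgement
  like $\langle 0.8, 0.9 \rangle$ only becomes expressible at $q \ge 5$.

Two scalar keys order these numbers: the **score**
$$S(\partial) = \frac{\varsigma \,(1 + m^q - n^q)}{2g} \in [0, 1],$$
and the **accuracy** $A(\partial) = \varsigma\,(m^q + n^q)$, which breaks
score ties (higher accuracy wins by default; `compareQ()` exposes the
opposite orientation, which some sources print, as a switch). The score
normalizes by **twice the cardinality** $2g$, not by twice the largest
index: with a seven-term set the denominator is 14. The distinction matters
because every published value this package reproduces — collective
matrices, model scores, comparison-method scores — is consistent only with
the $2g$ normalization; the package uses it uniformly, including in the
Hamming distance $d(\partial_1, \partial_2) = |(1 + m_1^q -
n_1^q)\varsigma_1 - (1 + m_2^q - n_2^q)\varsigma_2| / (2g)$.

The five operational laws (`qAdd`, `qMultiply`, `qScale`, `qPower`,
`qComplement`) combine orthopairs through the algebraic product/sum on the
$q$-th powers, so all of them are closed under the rung constraint. The
linguistic parts combine arithmetically on the values $\varsigma$; since a
product or power can leave $[0, g-1]$, the user-facing laws clamp the
result into range with a warning, while aggregation formulas evaluate their
linguistic component in the unclamped aggregation-value domain (their final
results are provably in range; see "Numerical choices").

## Prioritized Maclaurin symmetric means

Priorities enter through *prioritized-averaging weights*
(`priorityWeights()`): items in priority order with satisfaction scores
$s_1, s_2, \dots$ receive degrees $T_1 = 1$, $T_i = \prod_{t<i} s_t$,
normalized to $w = T / \sum T$. An item is thus discounted exactly by how
poorly everything more important scored — a lexicographic-flavoured
softening with no free tuning parameter.

Interdependence among the aggregated items enters through the Maclaurin
symmetric mean of order $k$, which averages products over all
$\binom{n}{k}$ subsets of size $k$. The two operators combine both ideas:

$$\mathrm{PMSM}^{(k)}(\partial_1,\dots,\partial_n) =
  \Big(\tbinom{n}{k}^{-1} \bigoplus_{i_1 < \dots < i_k}
  \bigotimes_{j=1}^{k} \partial_{i_j}^{\,w_{i_j}}\Big)^{1/k},
  \qquad
\mathrm{PDMSM}^{(k)} =
  \frac{1}{k}\Big(\bigotimes_{i_1 < \dots < i_k}
  \bigoplus_{j=1}^{k} \big(w_{i_j}\, \partial_{i_j}\big)\Big)^{1/\binom{n}{k}}.$$

The priority weight attenuates each argument through the *power* law in
the primal operator and through *scalar multiplication* in the dual — the
two laws swap roles exactly as sum and product do. This placement (with
the weights used as-is, not rescaled by $n$) is the form that reproduces
the published worked example cell-for-cell; variants with $n w_i$ scaling
do not. `qrf2lPMSM()`/`qrf2lPDMSM()` evaluate closed-form expressions;
`qrf2lSpecialCase()` implements the independently simplified $k = 1, 2, 3,
n$ reductions (prioritized averaging, Bonferroni-type and geometric
forms), and the test suite verifies that closed forms, reductions and
stepwise evaluation through the raw laws all coincide.

Both operators are monotone in every argument and bounded by the
aggregates of the min/max envelopes. They are deliberately **not
idempotent**: a panel of identical judgements does not aggregate to itself
unless the priority weights are uniform, because prioritization trades
idempotency for discounting. The test suite asserts this as intended
behaviour, not a defect.

## The WASPAS pipeline

`waspas()` runs the nine-step group procedure:

1. cost criteria are complemented into benefit orientation
   (`normalizePanel()`, an involution);
2. per cell, expert priority degrees are built from the scores of all
   strictly higher-priority experts (`expertPriorityWeights()`);
3. the per-expert matrices are fused cell-wise with PMSM (or PDMSM) over
   experts into a collective matrix (`aggregateExperts()`);
4. per alternative, criteria priority degrees are built from the
   collective scores of higher-priority criteria
   (`criteriaPriorityWeights()`);
5. each alternative's row is aggregated twice: PMSM over criteria gives
   the prioritized sum model $\bowtie^{(1)}_i$, PDMSM the prioritized
   product model $\bowtie^{(2)}_i$;
6. the combined measure is the convex mixture
   $\bowtie_i = \theta\, S(\bowtie^{(1)}_i) + (1-\theta)\,
   S(\bowtie^{(2)}_i)$, and alternatives are ranked by descending
   $\bowtie_i$ (ties: accuracy of the sum model, then input order —
   the case study never exhibits one).

`sensitivityScan()` re-runs this over grids of $\theta$ and $q$. Because
$\bowtie_i(\theta)$ is affine with endpoints $S(\bowtie^{(2)}_i)$ and
$S(\bowtie^{(1)}_i)$, the scan computes the two endpoints once per $q$ and
mixes; when $q$ changes, everything — scores, priority weights, operators —
is recomputed and every input cell is revalidated against the new rung.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| $q$ (rung) | 3 | size of the admissible orthopair region; unitless. Larger $q$ shrinks all scores and compresses differences, so rankings are usually stable in $q$ while magnitudes fall. Validated against every cell at load time. |
| $k$ (mean order) | 2 | number of jointly interacting items in the symmetric mean; $k = 2$ is the smallest order that captures pairwise interrelation, and the value used throughout the case study. |
| $\theta$ | 0.5 | weight of the sum model in the combined measure, in $[0,1]$; 0.5 balances the optimistic (sum) and conservative (product) models. |
| `weightDigits` | `c(expert = 2, criteria = 3)` | decimal places at which normalized priority weights are consumed. The published workflow tabulates intermediate weights and feeds the tabulated values forward; these defaults reproduce it exactly. Set both to `NULL` for full precision (differences appear in the fourth decimal of the collective matrices). |

## Comparison methods

Three alternative aggregation routes are included so the case study's
validation analysis can be rerun end to end:

* **q-RF2L PROMETHEE II** (`pairwiseDeviations()`, `prometheeFlows()`):
  for every ordered pair of alternatives and every criterion, the signed
  deviation $\tfrac{g}{2}(A_a - A_b)$ of the score numerators
  $A = \varsigma(1+m^q-n^q)$ passes through a Type-I (positive-part)
  preference function; global preferences are weight-averaged over
  criteria and netted into flows $\Psi = \Psi^+ - \Psi^-$. Because one
  weight vector serves all pairs, $\sum_i \Psi_i = 0$ holds exactly. The
  default weighting treats criteria evenly; this reproduces the published
  outranking order of the case study, whereas its printed flow *values*
  are internally inconsistent (their positive and negative totals differ
  by about 0.04, and no fixed criteria weighting maps the printed
  deviation table onto them), so flow values should only be compared
  qualitatively. The preference function and the weights are both
  pluggable.
* **q-RF2L Muirhead mean** (`qrf2lMuirhead()`): a permutation-symmetric
  mean with parameter vector $P$ (the case study uses $P = (1,1,2,1)$),
  evaluated by full enumeration of $S_n$ and therefore guarded at
  $n \le 8$ arguments. It models interrelation but ignores priorities.
* **q-ROF MSM** (`qrofMSM()`): the Maclaurin mean on bare orthopairs with
  the linguistic terms discarded; its score is $(1+m^q-n^q)/2$. Included
  to quantify what dropping the linguistic component does to a ranking.

## The synthetic panel generator

`generatePanel()` draws reproducible random panels: label indices uniform
on the term set, symbolic translations zero (elicited judgements sit on a
label; `randomDelta = TRUE` draws a continuous linguistic value instead),
and orthopairs uniform on the unit square by rejection under
$m^q + n^q \le 1$. The defaults mirror the case-study conditions — five
alternatives, four criteria, three experts, $q = 3$, a seven-term set.

The generator emulates the *structure* of elicited panels, not their
statistics: real expert judgements are correlated across experts and
criteria, cluster in the upper label range, and rarely use extreme
orthopairs, whereas generated cells are independent and uniform. Property
tests on generated panels therefore certify algebraic behaviour
(closed-form/stepwise agreement, monotonicity, boundedness, constraint
closure, affinity in $\theta$) for arbitrary valid inputs; they say
nothing about elicitation quality or about how real panels distribute.

## Numerical choices

* **Score normalization** is $2g$ (twice the cardinality), uniformly, as
  discussed above.
* **Rounding** of aggregation values to 2-tuples is round-half-up, so
  $\Delta \in [-0.5, 0.5)$ exactly; round-half-even would produce
  $\Delta = +0.5$ for some inputs.
* **Clamping policy**: the raw laws are total functions — linguistic
  overflow is clamped to $[0, g-1]$ with a warning. Aggregation operators
  skip intermediate clamping: their linguistic components are plain
  (weighted) Maclaurin means of values in $[0, g-1]$ raised to weights
  $\le 1$, and such means never leave the range, so only the final value
  is converted to a 2-tuple. The stepwise oracles in the test suite use
  the laws with `clamp = FALSE` to match this domain.
* **Weight precision**: see `weightDigits` above — tabulated-precision
  consumption is the default because it is the published workflow.
* **Tie-breaks**: comparison ties break by accuracy (orientation
  switchable); ranking ties by sum-model accuracy, then stable input
  order.
* **Degenerate inputs**: a single expert with $k = 1$ aggregates to its
  own (normalized) matrix; a single argument passes through both
  operators unchanged; a degenerate term set ($g \le 1$) is rejected.
* **Floating tolerance**: validity checks use $10^{-9}$; subset and
  permutation enumeration is canonical lexicographic so results are
  bit-reproducible.

## Known limitations

* Priority weights consumed at tabulated precision (the default) make the
  pipeline reproduce published tables at the cost of a small, documented
  dependence on the rounding convention; full-precision mode is one
  argument away.
* The Muirhead mean's factorial enumeration limits it to eight arguments;
  that is ample for criteria-wise aggregation but not for large panels.
* Unbalanced, hesitant or interval-valued linguistic term sets are out of
  scope, as are consensus-reaching iterations and learned expert weights.
* The dual (PDMSM-collective) route is substantially less discriminating
  in its product model — scores of order $10^{-5}$ — so its combined
  measure is dominated by the sum model for all but tiny $\theta$.

## Problem sizes used by the test suite

The property suites run on panels of 2–4 aggregated items (500 random
panels for closed-form agreement, 500 ordered pairs for monotonicity and
boundedness, $10^4$ law applications for constraint closure), matching the
case study's scale, where each aggregation fuses three experts or four
criteria. The full worked example — both operators, the $\theta$ and $q$
scans and the three comparison methods — re-runs from the packaged raw
tables in well under ten seconds.
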