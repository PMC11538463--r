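# qrf2l

Multi-criteria group decision analysis with **q-rung orthopair fuzzy
2-tuple linguistic** (q-RF2L) information, built for problems like
patient-triage prioritization: several experts of unequal authority rate
several alternatives on criteria that are themselves ordered by
importance, using hedged linguistic judgements.

## The model in brief

Each judgement is a q-RF2L number
$\partial = \big((s_r, \Delta), \langle m, n\rangle\big)$: a linguistic
2-tuple — a label $s_r$ from an odd-cardinality term set plus a symbolic
translation $\Delta \in [-0.5, 0.5)$, jointly equivalent to the real value
$\varsigma = r + \Delta$ — carrying an orthopair of membership and
non-membership grades with $m^q + n^q \le 1$. Numbers are ordered by the
score $S(\partial) = \varsigma\,(1+m^q-n^q)/(2g)$ ($g$ = term-set
cardinality), with accuracy $\varsigma\,(m^q+n^q)$ as tie-break.

Priorities enter through prioritized-averaging weights ($T_1 = 1$,
$T_i = \prod_{t<i} S_t$, normalized), and interdependence through the
Maclaurin symmetric mean of order $k$. The package's core operators fuse
both:

* **q-RF2L PMSM** $\big(\binom{n}{k}^{-1}\bigoplus_{i_1<\dots<i_k}
  \bigotimes_j \partial_{i_j}^{w_{i_j}}\big)^{1/k}$, and
* **q-RF2L PDMSM** $\tfrac1k\big(\bigotimes_{i_1<\dots<i_k}
  \bigoplus_j w_{i_j}\partial_{i_j}\big)^{1/\binom{n}{k}}$ (the dual),

wrapped in an extended WASPAS pipeline: expert aggregation into a
collective matrix, criteria aggregation through a prioritized sum model
and a prioritized product model, and the convex combination
$\bowtie_i = \theta\,S(\bowtie^{(1)}_i) + (1-\theta)\,S(\bowtie^{(2)}_i)$
that ranks the alternatives. Sensitivity scans over $\theta$ and the rung
$q$, and three published comparison methods (q-RF2L PROMETHEE II
outranking flows, the q-RF2L Muirhead mean, and the linguistic-free q-ROF
MSM), round out the toolkit. See the vignette
`vignettes/patient-prioritization.Rmd` for models, parameters and design
notes.

## Worked example

The packaged fixture is the case study shipped with the package: three
admission-service experts (priority order E1 > E2 > E3) rate five patients
on four benefit criteria — disease severity, emergency degree,
special-disease priority, insurance type, in descending priority — with
q = 3 on a seven-term set.

```r
library(qrf2l)
pan <- examplePanel()
waspas(pan, theta = 0.5)
#> Prioritized WASPAS (pmsm collective, theta = 0.5, q = 3, k = 2)
#>  alternative    psm    ppm combined rank
#>           P1 0.1496 0.0055   0.0776    3
#>           P2 0.1427 0.0045   0.0736    4
#>           P3 0.1502 0.0059   0.0781    2
#>           P4 0.1419 0.0045   0.0732    5
#>           P5 0.1575 0.0069   0.0822    1
#> ranking: P5 > P3 > P1 > P2 > P4
```

`psm` and `ppm` are the scores of the prioritized sum and product models;
`combined` mixes them with weight `theta`. Patient P5 is the most urgent
admission, and a sensitivity scan
(`sensitivityScan(pan, thetaGrid = seq(0.1, 1, 0.1), qGrid = c(3, 5, 7, 9, 11, 13, 15))`)
shows that this winner is stable across the whole $\theta$ and $q$ range.

The outranking comparison runs from the collective matrix:

```r
prometheeFlows(pairwiseDeviations(exampleCollective()))
#>  alternative positive negative     net rank
#>           P1   0.6699   0.2176  0.4523    1
#>           P2   0.5627   0.6625 -0.0998    4
#>           P3   0.5790   0.5491  0.0299    3
#>           P4   0.4375   0.8820 -0.4445    5
#>           P5   0.7332   0.6711  0.0621    2
#> ranking: P1 > P5 > P3 > P2 > P4
```

PROMETHEE II promotes P1: unlike the prioritized pipeline it weighs the
criteria evenly and ignores the expert/criteria priority structure, which
is exactly the methodological difference the comparison is meant to
expose.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/qrf2ld.R waspas --panel inst/extdata/triage_panel.csv --theta 0.5
Rscript inst/cli/qrf2ld.R simulate --out panel.csv --seed 7
Rscript inst/cli/qrf2ld.R validate --panel panel.csv
```

Panels are plain CSV/JSON files with cells in the canonical form
`"s<r>:<delta>|<mu>,<nu>"`; `readPanel()` validates every cell against the
rung constraint with errors addressed by expert, row and column, and
`generatePanel()` draws seeded random panels for simulation.

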