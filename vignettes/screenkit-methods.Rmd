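---
title: "screenkit: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{screenkit: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenkit)
```

screenkit implements the downstream arithmetic of an anticancer screening
campaign: five-dose growth-inhibition endpoints, activity-fingerprint
comparison, target-prediction consensus, graph-derived drug-likeness
descriptors, tumor-genomics statistics, and interaction-network summaries.
This vignette explains each model, the conventions the package fixes where
the field leaves room, and what the synthetic-data generators do and do not
emulate.

## Dose-response endpoints

The sulforhodamine-B five-dose protocol yields, per cell line, a time-zero
signal Tz, an untreated-control signal C, and treated signals Ti at five
log-spaced concentrations. Percent growth is piecewise:
`(Ti − Tz)/(C − Tz) × 100` when the treated well still grew (Ti ≥ Tz), and
`(Ti − Tz)/Tz × 100` when cells were killed below the starting population
(Ti < Tz). Both branches vanish at Ti = Tz, so the curve is continuous at
the total-growth-inhibition point. The three endpoints are the
concentrations where percent growth crosses 50 (GI50), 0 (TGI) and −50
(LC50).

Two conventions are ours to fix:

* **Interpolation scale.** The defining levels say nothing about how to
  interpolate between tested doses. We interpolate percent growth linearly
  against log10(concentration), matching the log-spaced five-dose design;
  a linear-concentration alternative would bias endpoints toward the upper
  dose of each bracket.
* **Non-monotone curves.** With noise the curve may cross a level more
  than once; we report the first crossing from the low-concentration side,
  which is deterministic and conservative (it never overstates potency).

Endpoints are stored in molar and reported in µM with two significant
figures; unreached levels are censored and serialize as the literal
strings `"> max"` / `"< min"` of the tested range, which mirrors how
screening services report them. Panel summaries exclude censored values
from min–max ranges and count them separately.

## Fingerprint comparison

A compound's fingerprint is its per-cell-line potency vector,
−log10(endpoint in molar); censored endpoints become missing cells. That
transform is the conventional one for screening potencies — it is an
assumption, not something the endpoint definitions dictate. Correlation is
plain Pearson over the cell lines present in both fingerprints
(pairwise-complete, no imputation), and a pair is *rejected* — not an
error — when the common-cell-line count falls below `min_common` or a
restricted vector is constant. The default `min_common = 25` guards
against spuriously perfect correlations on tiny overlaps while remaining
usable on mid-sized synthetic panels; published comparisons typically run
at overlaps of 44–57 lines. Ranking sorts by correlation, breaking ties by
overlap size then compound id, so results are reproducible to the byte.

## Target consensus

Prediction tools report incommensurable scores: Pa/Pi activity
probabilities, plain probabilities, or pharmacophore fit scores. Mixing
the raw numbers would be meaningless, so aggregation works on
within-predictor ranks only: Pa/Pi entries score as Pa − Pi, probabilities
as themselves, pharmacophore entries by normalized fit (z-score breaking
exact ties), and the consensus orders targets by how many predictors named
them, then by mean reciprocal rank. Gene symbols are uppercased and
trimmed before set operations, but no alias resolution is attempted — that
would require an external database and can silently merge distinct genes.

## Drug-likeness descriptors

Descriptors are computed on a minimal molecular graph read from V2000
molfiles (V3000 is rejected with a clear error; coordinates are
discarded). Implicit hydrogens come from default valences (C 4, N 3, O 2,
F/Cl/Br/I 1, S 2, P 3) adjusted by formal charge; rings from a minimum
cycle basis (spanning-tree fundamental cycles with pairwise reduction,
deterministic tie-breaks); aromaticity by benzenoid perception only —
six-membered C/N rings with alternating Kekulé bond orders. No Hückel
electron counting and no five-membered heteroaromatics: sufficient for
biphenyl/anilide chemistry and common drug-like fixtures, and a documented
limitation for, say, furans or imidazoles.

Conventions that matter to the printed values:

* **Acceptors** are Lipinski N + O. With four fluorines present this is
  the only convention reproducing an acceptor count of 3 for the packaged
  study compound.
* **Rotatable bonds** are acyclic single bonds between two non-terminal
  heavy atoms, *including* amide C–N. The stricter convention that
  excludes amides would give 3 for the study compound, not the printed 4.
* **TPSA** sums Ertl fragment contributions over N/O atoms, classified by
  element, hydrogen count, bond-order pattern and aromatic/ring context.
  A polar atom matching no packaged class raises an error naming the
  environment — a silent zero would corrupt sums invisibly.
* **Masses** are IUPAC standard atomic weights at three decimals with a
  final half-up rounding to two decimals, which reproduces 361.29 g/mol
  for C19H11F4NO2 exactly.
* **logP and molar refractivity are inputs, never computed.** Their usual
  sources are proprietary regression models; the Lipinski verdict
  evaluates the rules it can and reports the skipped ones. When both
  Lipinski-relevant logP values are available (a single-model value and a
  consensus), the single-model value is the default input.

The packaged structure file was drawn from the compound's systematic name,
N-(2,4-difluorophenyl)-2′,4′-difluoro-4-hydroxybiphenyl-3-carboxamide,
which determines the graph completely; its 26 heavy atoms and 11 implicit
hydrogens check against the molecular formula.

## Genomics statistics

Co-occurrence enrichment splits a cohort by index-gene alteration status
and tests every other gene's 2×2 table. The **log ratio is computed from
the two group percentages**, not raw counts, because portal-style tables
print percentages without their denominators; this makes printed log
ratios reproducible from the table alone. Genes altered in only one group
get an infinite log ratio and a `degenerate` flag rather than an arbitrary
finite sentinel. Fisher p-values are two-sided by point-probability
summation (the convention of `stats::fisher.test`, checked in the tests
against exhaustive enumeration of all tables with small margins), and
q-values are Benjamini–Hochberg. Note that BH is *not* idempotent —
re-adjusting q-values inflates them — so the package never re-adjusts
downstream.

Survival uses the product-limit estimator and the Mantel–Cox log-rank
test; the hazard ratio is the observed/expected ratio
`(OA/EA)/(OB/EB)` with CI `exp(log HR ± 1.96·√(1/EA + 1/EB))`. That
estimator pairs naturally with the log-rank statistic and needs no
iterative fit; it approximates the proportional-hazards estimate closely
at moderate hazard ratios. Median splits send samples tied at the median
to the low group — deterministic, stated, and testable.

## Networks and gene sets

Graph summaries report nodes, edges, average degree 2E/N (half-up to one
decimal) and the mean local clustering coefficient with degree-< 2 nodes
contributing 0. Hub identification ranks by degree with alphabetical
tie-breaks and can be restricted to a candidate list, since the usual
question is which *query* genes are hubs of their interaction
neighborhood, not which database neighbor has most edges. Gene-set
enrichment is upper-tail hypergeometric with BH correction and the
three-part retention filter (p below a cutoff, overlap count, and
strength ≥ threshold, where strength = log10(observed/expected overlap) —
the only sensible reading of a "strength ≥ 2" filter). The packaged
26-node demonstration network is synthetic: it honors the reported node
count, edge count and candidate-gene degrees (23/14/13/4/4/1), with the
unpublished remainder filled deterministically among partner nodes.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of configuration and seed, and writes a
truth table alongside the data; recovery tests read only the truth tables.
One root seed fans out to per-stage child seeds by fixed offsets so stages
draw from independent reproducible streams.

* **Plates** follow a Hill-shaped growth model from 100% down to a
  per-line floor, with additive Gaussian noise on percent growth
  (default sd 3 points, a typical plate CV). The five-dose grid is
  0.01–100 µM in 10-fold steps: the printed five-dose lists of screening
  protocols include a 0 µM anchor that cannot sit on a log grid, so the
  generator treats the tested concentrations as the four decades up from
  0.01 µM. Default GI50s are drawn log-uniformly from 1–5 µM, the potency
  band of an active screen; 30% of lines are lethal (floor below −50).
  Analytic GI50/TGI/LC50 of each noiseless curve go into the truth table.
* **Fingerprint libraries** plant `n_correlated` look-alikes (seed vector
  plus noise at 0.1× the signal sd) among independent compounds, with 10%
  missing cells.
* **Alteration matrices** are Bernoulli per gene, with planted genes'
  odds multiplied by a configurable odds ratio in index-altered samples.
* **Survival** is exponential event times with independent exponential
  censoring and a configurable group hazard ratio.
* **Predictor outputs** give planted targets high scores and decoys low,
  with per-predictor dropouts so the Venn structure is nontrivial; a
  deterministic fixture mode reproduces the six-triple/two-double
  three-list structure used in the consensus tests.

What passing tests on these generators shows is that the *estimators*
recover known truth under clean, well-specified noise. Real screens add
plate effects, cell-line identity drift, non-Hill curve shapes and
informative censoring; real cohorts add population structure and
panel-composition biases. None of those are modeled, so recovery here is a
necessary, not sufficient, indication of field performance.

## Numerical choices and problem sizes

Endpoint interpolation is exact at grid hits; otherwise a single
log-linear cell, so recovered endpoints are within one 10-fold dose cell
of truth by construction, and in practice the median absolute log10 error
over noisy plates is well under 0.15 (checked over 200 plates with Hill
slopes 0.5–3). Test problem sizes — 200 plates, 100-compound libraries,
10,000-sample cohorts, 1,000 log-rank simulations at n = 100 — were chosen
as the smallest sizes at which the statistical tolerances above are
comfortably non-flaky; the whole suite runs in well under a minute.

Pipeline configuration is a YAML file (or an R list); YAML is the R
ecosystem's standard human-writable config format and ships with the
`yaml` package. Stage outputs are plain CSVs with a run-metadata record,
and identical configuration + seed produces byte-identical outputs.

## Known limitations

* Aromaticity perception is benzenoid-only; descriptor values for
  five-membered heteroaromatics will classify their N atoms as
  non-aromatic (or error in TPSA where no non-aromatic class fits).
* The hazard ratio is the O/E estimator, not a Cox fit; with heavy
  censoring imbalance or strong non-proportionality the two diverge.
* Fingerprint comparison is plain Pearson; no rank-based or
  mechanism-weighted variants.
* No external databases are queried; alias resolution, live PPI edges and
  pathway membership must be supplied as files.
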