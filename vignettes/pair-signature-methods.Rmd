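---
title: "Methods: two-gene signature discovery from pathway-panel subtyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-gene signature discovery from pathway-panel subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairsig)
```

## The model and its assumptions

`pairsig` operationalizes a common translational-biomarker workflow: a
pathway gene panel is assumed to carry a latent subtype structure in which
one subtype has distinctly poor prognosis, and that subtype is assumed to be
recoverable from just two genes — one up-regulated, one down-regulated —
dichotomized at their cohort medians. The package makes each assumption an
explicit, testable step:

1. **Scale.** All analysis happens on log2(TPM+1). `expr_matrix` objects
   carry their scale, and every analysis entry point refuses raw TPM. This
   prevents the silent TPM/log mixing that plagues ad hoc scripts.
2. **Subtyping.** Panel genes are z-scored (so high-variance genes do not
   dominate), sample distance is `1 − Pearson` correlation, linkage is
   average, `k = 3`. These are the prevailing choices for expression
   subtyping; none is claimed optimal and all are arguments. Clustering is
   deterministic and permutation-equivariant.
3. **Worst-cluster designation** uses Kaplan–Meier median overall survival,
   not pathway activity: the signature is meant to capture prognosis, so
   prognosis defines the target class. Ties or undefined medians fall back
   to restricted mean survival, then to the lowest original label, with the
   decision logged.
4. **Pair election** maximizes binary agreement between pair-positivity and
   worst-cluster membership. A two-gene rule can only define a binary split,
   so agreement is measured against the indicator `cluster == 3` rather
   than the three-way labels. Precision of the positive set
   (`target_consistency`) is the tie-breaker and is reported alongside
   recall, since "consistency of the positive set with the worst cluster"
   is ambiguous between the two; precision is designated because the
   positive set is the clinically actionable group.
5. **Survival and response statistics** assume proportional hazards (Cox),
   independent censoring (KM), and fixed margins (exact contingency tests).

## Tunable parameters

| parameter | default | units / rationale |
|---|---|---|
| `k`, `linkage` | 3, average | field convention for expression subtyping |
| `fc_threshold` | 1 | log2 units; one doubling on the TPM scale |
| `q_threshold` | 0.05 | BH FDR for direction calls |
| median tie rule | ties → "lo" | keeps the "hi" set ≤ n/2; deterministic |
| `p_enter`, `p_remove` | 0.05, 0.10 | the SPSS "Forward:LR" convention |
| ssGSEA `alpha` | 0.25 | the customary rank-weight exponent |
| ssGSEA `n_perm` | 1000 | permutation p resolution ≈ 1/1001 |
| `callable_mb` | 38 | conventional exome size for TMB |
| MATH constant | 1.4826 | Gaussian consistency factor of the MAD |
| CPS cut-off | 10 | clinical PD-L1 positivity convention |
| IHC split | composite ≤ 2 low | intensity (0–3) + extensity (0–3) |
| Fisher convention | prob ≤ observed | two-sided as the sum of all fixed-margin table probabilities no larger than the observed table's |

The Fisher convention, the enumeration bound (`enumeration_limit = 1e6`
tables, then seeded Monte-Carlo with `1e5` draws) and the Shannon log base
(natural) are recorded in each result object so downstream reports are
self-describing.

## What the synthetic generator emulates — and what it does not

`cohort_spec()` encodes the study conditions the analysis assumes. Defaults:
300 samples in three equal clusters over a 55-gene panel; the two designated
markers shift by ±4 log2 units in cluster 3 against Gaussian noise of SD 0.5;
the remaining panel genes form two blocks elevated (+2) in clusters 1 and 2
respectively, leaving cluster 3 at panel baseline — a pathway-suppressed
worst cluster in which only the marker pair separates cleanly. Survival is
exponential with a cluster-3 hazard ratio of 3 around a 20-month baseline
median and exponential censoring tuned to a 30% censored fraction; responder
probability is 1.0 in cluster 3 and 0.5 elsewhere (the magnitudes reported
for this design's motivating cohorts); mutation counts are Poisson(2/Mb ×
38 Mb), VAFs Beta with precision 12 vs 4 so the worst cluster is
over-dispersed (higher MATH); trinucleotide contexts mix two synthetic
signature profiles at 0.3/0.7 vs 0.7/0.3 weights; immune markers gain
+0.3 log2 on dendritic-cell markers post-therapy in cluster 3; clonotype
counts follow a log-series abundance model with subtype-dependent richness.

The generator is Gaussian on the log2 scale rather than negative-binomial on
counts: the analysis consumes normalized expression, and a location-shift
model is the minimal structure the clustering and rank tests respond to. It
does **not** emulate batch effects, tumor purity, gene–gene correlation
beyond the block design, or realistic signature catalogs. Passing tests
therefore demonstrate that the pipeline recovers structure of the assumed
form at the assumed magnitudes — not that any real cohort has that
structure.

## Numerical choices

- **Exact tests.** 2×2 Fisher and r×c Freeman–Halton p-values are computed
  by full enumeration of fixed-margin tables in log-space (lgamma), with
  the standard `(1 + 1e-7)` relative tolerance when comparing table
  probabilities, matching the convention that reproduces published clinical
  tables. Beyond the enumeration bound, Patefield sampling (`r2dtable`)
  gives a seeded Monte-Carlo p with the `(1 + hits)/(B + 1)` estimator.
- **ssGSEA.** Genes are ranked descending with ties broken by row order
  (deterministic); ES is the sum of the running difference; NES divides ES
  by the cross-sample ES range for the set, flagged NA when the range is
  degenerate. The single-gene toy case is exposed as `ssgsea_es()`.
- **KM medians** are the earliest time with survival ≤ 0.5 and are reported
  as NA, never imputed, when the curve does not cross 0.5.
- **Forward:LR Cox** refits the partial likelihood at every candidate step;
  non-convergence aborts with the step name rather than selecting from a
  degenerate fit.
- **Degenerate inputs** follow the rule "flag, never guess": empty
  pair-positive sets score target consistency 0 with a warning; MATH with
  < 3 VAFs, correlations of constant genes, zero-overlap marker
  populations and all-zero context vectors return NA with a flag.
- **Seeds.** Every stochastic step (generators, permutations, Monte-Carlo)
  takes an explicit seed; generator stages derive fixed sub-seeds from the
  spec seed so each output is a pure function of (spec, seed).

## Test and calibration problem sizes

The shipped suite exercises discovery end-to-end on 100 seeded cohorts of
n = 300 (pair election and clustering agreement), calibrates null p-value
uniformity over 200 replicates per downstream test, bounds forward-LR null
retention over 100 runs of n = 300 with 5 null covariates, and verifies the
exact tests against brute-force enumeration on every 2×2 table with n ≤ 30
plus 200 random 2×3 tables with n ≤ 25. These sizes were chosen as the
smallest at which the Monte-Carlo error of each check is clearly below the
margin being asserted.

## Known limitations

- The pair search is exhaustive over (up × down) directional calls; with
  very permissive DE thresholds it grows quadratically.
- Median dichotomization discards within-group expression information by
  design; no coefficient-weighted or >2-gene signatures are offered.
- The Freeman–Halton enumeration is exponential in table size; large sparse
  tables fall back to Monte-Carlo with a correspondingly granular p.
- Immune scores are marker means on the log scale; they are comparable
  across groups within a cohort but are not absolute cell counts, and the
  package deliberately ships only a synthetic placeholder marker panel.
- The clinical reader never imputes: analyses are complete-case, with drop
  counts logged, which can bias comparisons when missingness is informative.
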