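---
title: "Methods: classifying farming regimes from weed functional traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying farming regimes from weed functional traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weedclass)
```

## The scientific problem

Arable weed species carry functional traits — specific leaf area, canopy
size, flowering period, vegetative propagation — that respond predictably to
soil productivity and disturbance. Surveys of modern fields under known
management regimes therefore define a trait-space signature for each regime,
and an archaeobotanical weed assemblage can be placed against those
signatures to infer how the fields that produced it were farmed. `weedclass`
implements this workflow: per-sample trait averaging, two-group linear
discriminant classification against reference survey data, and
discriminant-score visualisation.

Three reference model structures are supported:

| model | contrast | predictors |
|---|---|---|
| 1 | high- vs low-input cultivation | SLA, ARNODE, LOGCANH, LOGCAND, FLOWPER |
| 2 | high- vs low-input (fertility only) | SLA, ARNODE, LOGCANH, LOGCAND |
| 3 | high vs low soil disturbance | VEGPROP, FLOWPER |

Units: SLA in mm²/mg, ARNODE in mm²/mm, canopy height/diameter as log10 of
cm, FLOWPER in months (1–12), VEGPROP as a 0/1 indicator whose per-sample
mean is the fraction of vegetatively propagating species. Group 1 is always
the high-input / high-disturbance regime.

## From counts to profiles

Raw data are a taxa × samples seed-count matrix keyed by four-three species
codes (`agrogit`, `poa_ann`, ...). Counts are reduced to presence/absence —
seed numbers are shaped by taphonomy and processing, not field abundance —
and every model-relevant trait is averaged over the species present:

$$\bar t_s \;=\; \frac{1}{\lvert P_s^{(t)}\rvert} \sum_{i \in P_s^{(t)}} t_i,$$

where $P_s^{(t)}$ is the set of species present in sample $s$ with a
*non-missing* value of trait $t$. The denominator is per-trait: a species
with unknown VEGPROP still contributes to SLA. This matters for model 3,
where analysts routinely blank VEGPROP for species (or composite taxa) whose
propagation behaviour in the study region is uncertain; the package stores
such values as `NA`, never 0, because "does not propagate" and "no data" are
different statements.

Two cleaning rules are applied before averaging:

* samples with fewer than 10 weed seeds in total are dropped (`min_seeds` is
  a flag — the threshold is a recommendation, and the boundary is inclusive);
* samples with fewer than 3 species are *flagged*, not dropped, so results
  can be compared with and without them.

Composite taxa (seeds identifiable only to a small species set) get
per-trait means over their members, again with per-trait denominators, with
optional overrides applied last. Averaging more than four species triggers a
caution and member trait ranges are attached for inspection, but divergence
is never a hard error: how divergent is too divergent is the analyst's call.
Composite flowering periods are kept at full precision internally and only
rounded to half months for display (`display_flowper()`).

## The discriminant

With group means $m_1, m_2$ and pooled within-group covariance

$$S = \frac{(n_1-1)S_1 + (n_2-1)S_2}{n_1+n_2-2},$$

the discriminant direction is the Fisher solution $w \propto S^{-1}(m_1 -
m_2)$. Three conventions pin the solution down completely, and are worth
stating because discriminant software differs on all three:

1. **Scale**: $w$ is normalised so $w^\top S w = 1$ — unit pooled
   within-group variance of the score.
2. **Origin**: the constant maps the prior-weighted grand mean
   $\pi_1 m_1 + \pi_2 m_2$ to score 0, so the centroids satisfy
   $\pi_1 c_1 + \pi_2 c_2 = 0$ and are reproducible from the reported fit.
3. **Sign**: group 1 scores positive. Discriminant signs are arbitrary and
   different programs disagree; fixing the convention keeps figures
   comparable across studies (state the software used regardless).

Priors default to the training group proportions, with an equal-priors
override; standardised coefficients are $w_j \cdot s_j$ with $s_j$ the pooled
within-group SD of predictor $j$. Because the standardised score is computed
on predictors centred at the grand mean and scaled by $s_j$, the
standardised and unstandardised routes yield the same score to rounding
error, and provably the same classes — which is why pooled within-group SDs
(not total SDs) were chosen for standardisation.

Posteriors use the two-group Gaussian rule with shared covariance, which
collapses to one dimension on the score:

$$\log\frac{p_1}{p_2} = \log\frac{\pi_1}{\pi_2} + LD1\,(c_1-c_2) -
\frac{c_1^2-c_2^2}{2}.$$

The test suite verifies this collapse against an independent brute-force
oracle that evaluates full $p$-dimensional Gaussian densities via
Mahalanobis distances. A posterior of exactly 0.5 resolves to class 2 (the
low-input / low-disturbance group) — a measure-zero event that the tests
construct deliberately.

Numerical notes: the solve of $S$ fails with an actionable error when $S$ is
singular (constant or collinear predictors); each group must contribute at
least $p+2$ fields; log-odds are computed directly, so extreme scores give
posteriors that saturate at 0/1 without overflow.

## The synthetic world

No survey or archaeobotanical data ship with the package; a seeded generator
produces structurally faithful stand-ins so every stage runs and is tested
offline.

* **Trait database** (`make_trait_db`): invented binomials run through the
  real code-assignment routine; SLA ~ N(22, 6²) and ARNODE ~ N(30, 10²)
  truncated positive, canopy logs ~ N(1.5, 0.3²)/N(1.3, 0.3²), VEGPROP
  Bernoulli(0.4) with a configurable missing rate (default 10 %), FLOWPER
  uniform on 1–8 months. The 928-species scale of the published database is
  exercised in tests; the default is 60 species for speed.
* **Model data** (`make_model_data`): field trait vectors from two Gaussians
  sharing a diagonal within-group covariance (field-level SDs: 3, 5, 0.15,
  0.15, 0.12, 0.8 on the trait scales above), means split by the configured
  shift, centred on the same baselines as the species generator — that
  shared baseline is what makes end-to-end classification meaningful. The
  default shift (6, 8, 0.25, 0.2, 0.25, 1.5) corresponds to a Mahalanobis
  separation of roughly 3–4 depending on the model, chosen once as a
  plausible strong-contrast survey pair; 20 fields per group mirrors a
  realistic survey effort.
* **Counts** (`make_counts`): each sample draws 5–15 species with inclusion
  probabilities from a logistic link on the species' standardised traits
  projected onto the shift direction, tilted toward the sample's assigned
  regime; seed counts are 1 + Poisson. This is the simplest mechanism that
  makes trait-averaged profiles separable by construction.

What the generator does **not** emulate: phylogenetic or co-occurrence
structure, taphonomic loss, abundance distributions, regional species pools,
or trait correlations. A green end-to-end test therefore establishes that
the machinery recovers a known signal under the model's own assumptions —
not that the ecological models are valid, which only the original field
surveys can support.

One statistical subtlety found while validating the null configuration
(zero shift): within a single simulated world the fitted boundary is pure
noise while the sample profiles cluster tightly, so the per-world group-1
fraction sits near 0 or 100 — the 50/50 behaviour only emerges *across*
replicate worlds. The acceptance report therefore averages the null fraction
over 20 independent replicates and also reports null training accuracy,
which is binomial at the field level.

## Design choices where the design was open

* **Code collisions** extend the epithet by one letter at a time, then the
  genus, until unique; an explicit error if both are exhausted. Which of two
  colliding taxa keeps the unmodified code is a database curation decision —
  the importer accepts whatever codes a published database uses rather than
  re-deriving them.
* **Unknown taxa** in the count matrix are excluded with a warning naming
  them, erroring only when nothing remains. Silent exclusion hides data
  entry errors; a hard error would block exploratory runs.
* **Database versioning** is mandatory in the CSV metadata line because the
  underlying trait data evolve; results are only reproducible if the trait
  set used is citable. Unversioned published files can be imported by
  passing a version explicitly.
* **Stored canopy logs are treated as opaque**: averaging happens on the
  stored (log) scale whichever base produced it, so the base choice only
  affects the synthetic generator's documentation (log10 assumed).
* **Run manifests**: every pipeline run writes tool version, trait-db
  version, model id, priors, thresholds, input digests and a timestamp next
  to the results, so a results file can always be traced to what produced it.

## Limitations

Two groups only (no quadratic discriminant, no multi-group models); no
automatic screening of non-arable taxa (use correspondence-analysis or
crop-processing tools upstream); tentative (`cf.`) identifications must be
merged or dropped by the analyst before import; the beeswarm is a
deterministic greedy packing, not the published swarm algorithm — behaviour
(readable 1-D score distributions), not pixel output, is replicated.
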