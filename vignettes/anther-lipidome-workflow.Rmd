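---
title: "Methods: heat-stress remodeling analysis of anther lipidomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat-stress remodeling analysis of anther lipidomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antherlipids)
```

This vignette documents the models and procedures implemented by
`antherlipids`, the assumptions behind them, the tunable parameters and
their defaults, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## The data model

The unit of analysis is a **normalized mass-spectral signal table**: one row
per anther sample, one column per lipid analyte, in units of signal per mg
anther dry weight where a value of 1.0 equals the signal of 1 nmol of
internal standard. Samples carry genotype, treatment (`AT` ambient, `HT`
heat), year, block, replicate, and a quality-control-pool flag. Analytes
are named in the shorthand nomenclature `CLASS(c:d)` — total acyl carbons :
total carbon–carbon double bonds — or with explicit chains
(`TAG(18:2/16:0/18:1)`); chain order never encodes sn-position, and `_A`/`_B`
suffixes keep isobaric analytes with different chain sets distinct. Twelve
headgroup classes are recognized; TAG carries three acyl chains, the diacyl
phospho- and galactolipids two, the acyl part of SE and ASG one, and the
sterol glycoside SG none (it is excluded from chain-based metrics).

## Quality control

An analyte is dropped when, **in any year**, (1) its mean signal across the
experimental samples of that year falls below the limit of detection, or
(2) its coefficient of variation across that year's QC-pool injections
exceeds `cov_max`.

Three choices here were open and are fixed as follows:

* **LOD default** is `5e-5` normalized-signal units, exposed as the `lod`
  argument (the alternative reading `5e-4` that appears in some figure-level
  documentation of such experiments can simply be passed in).
* **CoV uses the sample (n−1) standard deviation** divided by the mean; for
  QC values (1, 2) this gives 0.707/1.5 ≈ 0.471.
* **LOD is tested against the mean** of the experimental samples within a
  year, the weaker and more stable criterion, rather than requiring every
  single observation to clear the limit.

Percent-of-total normalization divides each row by its total and multiplies
by 100; a row with zero total is an error, not a silent zero. Filtering is
idempotent, preserves analyte order, and reports a per-analyte, per-year
verdict (`pass`, `below_LOD`, `high_CoV`).

## Composition and unsaturation metrics

Class composition sums analyte percentages within headgroup classes per
sample and averages over grouping cells. Species composition pools a
configurable class set by the `c:d` key and re-expresses it as percent of
the pooled total; the default set for "structural glycerolipids" is
{PC, PE, PI, PA, PG, MGDG, SQDG, DAG} — membrane-forming diacyl lipids plus
DAG, with TAG and sterol lipids excluded, since storage and sterol pools
would otherwise swamp the membrane signal under heat.

The **unsaturation index** of a molecular species is its double bonds per
acyl chain (`PC(36:6)` → 3.0); the class index is the amount-weighted mean
of its species' indices, computed per sample and then summarized per cell.
It is scale-invariant, so it gives the same answer in signal or percent
units.

The **fatty-acid decomposition** sums amount × occurrences of each fatty
acid over the species whose chain composition is known — explicit in the
name, or from a built-in assignment map covering the unambiguous PC and PE
species (34:4 = 16:1/18:3, 34:3 = 16:0/18:3, 34:2 = 16:0/18:2,
34:1 = 16:0/18:1, 36:6 = 18:3/18:3, 36:5 = 18:2/18:3, PC 36:1 = 18:0/18:1).
The 34:2 entry deserves a note: a 16:0/18:1 pairing is arithmetically a 34:1
species, so the only standard-fatty-acid pair consistent with 34:2 totals is
16:0/18:2, and that is the default; the map is a plain tibble argument and
fully overridable. Unassigned species contribute nothing and are returned
in an exclusion log rather than silently ignored. Ratio metrics
(PC 18:3/18:2, TAG:PC) are computed **per sample and then averaged** (mean
of ratios, matching per-observation error bars), not as ratios of cell
means; fold changes of fatty-acid totals between treatments are ratios of
treatment means, which keeps them exact for planted multiplicative effects.

## Design statistics

The field design is a two-factor factorial (treatment × genotype) carried
over 2 years × 2 blocks × 4 replications. The package fits

```
value ~ genotype * treatment + year:block
```

by ordinary least squares, treating year and block-within-year as **fixed
blocking terms**. This is a deliberate approximation of the random-effects
(mixed-model) treatment of year and block: with only two years, variance
components for year are essentially unestimable, and the fixed-blocking fit
preserves the treatment and genotype contrasts of interest while absorbing
additive year/block shifts (a property the tests assert directly). Cell
means are computed by averaging model-matrix rows over the blocking levels
**observed for that genotype**, so a genotype grown in only one season is
summarized within its own cells, with its smaller n carried into the
standard error.

AT-vs-HT comparisons are per-genotype *t* tests of the cell-mean contrast on
the residual degrees of freedom — the per-comparison Fisher LSD criterion at
α = 0.05, with **no multiple-testing correction across analytes** by
default (an optional Benjamini–Hochberg flag exists). Genotype comparisons
within a treatment are summarized by a compact letter display: levels are
sorted by descending mean and every maximal run of mutually non-significant
levels receives one letter (insert-and-absorb).

## PLS-DA and VIP

The discriminant analysis is a from-scratch two-class PLS1: the class label
is coded 0/1 and centered, predictors are **mean-centered only** (no
unit-variance autoscaling, matching analysis of signal tables that were not
scaled; `scale = TRUE` is available). Components are extracted
NIPALS-style and deterministically — at each stage the weight vector is
`w = X'y/||X'y||`, scores `t = Xw`, loadings `p = X't/t't`,
`q = y't/t't`, followed by rank-one deflation of X (and y). There is no
random initialization; component sign is fixed by forcing the
largest-magnitude weight entry positive. The response sum of squares
explained by component a is `SS_a = q_a² t_a't_a`, and Wold's VIP is

VIP_j = sqrt( p · Σ_a SS_a w_ja² / Σ_a SS_a ),

so mean(VIP²) = 1 exactly — an identity the tests check to 1e-8 on random
data, alongside numerical equivalence of scores, weights, and VIP with an
independently implemented reference (mixOmics) to 1e-6. VIP is computed
from the same A = 2 components shown in a two-axis scores plot; A is an
argument, bounded by the rank of the centered predictor matrix. Top-k
rankings break VIP ties by analyte name so output is deterministic.

## Co-occurrence analysis

Spearman ρ (average ranks for ties) is computed over all pooled non-QC
samples of both treatments — co-occurrence is about joint variation across
the whole study, and because ranks are taken within analytes, the result is
identical for raw signal and percent-of-total inputs up to the per-sample
renormalization, so the percent table is used by default. Zero-variance
analytes are flagged, excluded, and logged rather than producing NaNs.

Single-linkage agglomeration runs on the distance 1 − ρ. Lipid **groups**
at threshold ρ* = 0.90 are the connected components (size ≥ 2) of the graph
with an edge wherever ρ ≥ ρ*; under single linkage this is identical to
cutting the tree at similarity ρ*, and the test suite asserts that
equivalence against graph-component and brute-force clustering oracles. The
definition means every group member correlates with at least one other
member at ρ ≥ ρ* — groups chain transitively, which is the intended
single-linkage semantics. Each analyte is annotated `up`/`down`/`ns` from
the pooled AT-vs-HT contrast of the design model at α = 0.05. Trees export
to Newick through the ultrametric convention (two leaves joined at distance
d sit d/2 from their node), so `(A:0.05,B:0.05);` for a pair at ρ = 0.9.

## ΔΔCT expression

Technical replicates are averaged first; per biological replicate,
ΔCT = CT_target − CT_reference (*Actin-7*); per treatment, biological
replicates are averaged; ΔΔCT = mean ΔCT(HT) − mean ΔCT(AT) and
fold = 2^(−ΔΔCT), i.e. amplification efficiency is fixed at 2 with no
efficiency correction. Calls use the 1.5-fold rule — `up` above 1.5, `down`
below 1/1.5, `nc` otherwise — deliberately mirroring the fold-threshold
convention rather than inventing a significance test for it. Plate-wide CT
shifts cancel exactly, and swapping the treatments inverts every fold.

## The synthetic-data generator

`default_template()` defines 89 analytes across the 12 classes with
ambient-temperature class shares PC 43%, PE 18%, TAG 9%, PG 5%, PI 5%,
MGDG 4%, DAG 4%, PA 3%, ASG 2.5%, SG 2.5%, SE 2%, SQDG 2%, and within-class
species weights that put the diacyl species 34:3 (≈26%), 34:2 (≈25%),
36:6 (≈11%), 36:5 (≈16%), and 36:4 (≈12%) in dominant positions — the
composition regime of heat-stressed legume anther tissue. TAG, DAG, ASG,
and SE species carry explicit chains (TAG(54:5) intentionally stays in
totals form so the fatty-acid stage has a genuinely ambiguous species).

`simulate_study()` draws each value as

baseline × HT multiplier (genotype-specific) × year factor × block factor ×
lognormal noise,

with:

* **18:3 depletion**: every 18:3-containing membrane species — explicit
  chains where available, otherwise the canonical chain sets of 34:4, 34:3,
  34:6, 36:5, 36:6 (36:4 being 18:2/18:2 and 36:3 being 18:2/18:1 carry
  none — is multiplied under HT by the genotype's depletion factor.
  Defaults: Bailey 0.85, Georgia 12Y 0.70, SPT 06-07 0.55 — the tolerant
  genotype depletes hardest, bracketing a pooled ≈0.8 drop.
* **TAG gain**: genotype gains 2.0 / 3.0 / 4.0 on the strong-response TAG
  block, gain^0.45 on a second TAG block, gain^0.25 on remaining TAGs, and
  none for the fully saturated and fully tri-unsaturated extremes
  (TAG(48:0), TAG(54:9)), which are known not to accumulate in this system.
* **Planted co-occurrence blocks**: PC {34:3, 36:5, 36:6},
  PE {34:3, 34:2, 36:6, 36:5, 36:4} (the whole PE block shares the
  down-response — headgroup-coordinated remodeling), and two TAG blocks of
  six. Block members share 95% of their replicate-noise variance through a
  per-sample latent factor. The two TAG blocks respond with different
  magnitudes on purpose: with a shared treatment response of equal size, the
  between-block correlation would approach the 0.90 threshold and
  single-linkage chaining would merge them; the damped exponent keeps the
  population between-block ρ near 0.75 while within-block ρ stays ≈0.98.
* **Noise**: multiplicative lognormal, CoV 0.2 for experimental samples and
  0.1 for QC pools (signal data are positive and right-skewed); year and
  block factors are pure per-sample scale factors, so they vanish under
  percent-of-total normalization and are absorbed by the blocking terms in
  signal units.
* **Determinism**: every draw comes from a named substream of the master
  seed (one per analyte, per planted block, per QC year), so the same seed
  is bit-reproducible and adding analytes does not perturb existing noise.
* **Junk analytes**: `n_below_lod` / `n_high_cov` extra analytes can be
  planted to exercise the QC filter; the default is 0 so the 89 template
  analytes all pass.

The default study simulates three genotypes spanning the tolerance range
over the full 2 × 2 × 4 design (96 experimental samples, 8 QC injections) —
large enough for every recovery property to be testable in seconds, small
enough that the whole suite runs in about two minutes.

What the generator emulates: compositional structure, genotype-graded
multiplicative heat effects, block-correlated replicate noise, QC-pool
behavior, below-LOD and high-CoV failure modes, and CT tables whose planted
folds survive the ΔΔCT arithmetic. What it does **not** emulate: mass
spectrometer artifacts (isotopic overlap, in-source fragmentation,
saturation), missing values, heavy-tailed outliers, correlations induced by
shared internal standards, year × treatment interactions, or any mechanistic
lipid metabolism. Passing recovery tests therefore demonstrates that the
pipeline's inference is correct under its own statistical assumptions — not
that those assumptions exhaust real MS data.

## Numerical and edge-case conventions

* Exact zeros are legal signal values and participate in totals; negative
  values are rejected at construction.
* A zero class total makes the class unsaturation index a flagged `NA` for
  that sample; zero denominators in ratio metrics are flagged `NA`
  (18:3/18:2) or an error naming the sample (TAG:PC, percent-of-total).
* Constant analytes are allowed in PLS-DA (zero weight) and excluded with a
  warning from correlation; constant class labels are an error.
* Merge trees use the deterministic tie-handling of the underlying
  agglomeration; merge *heights* are the tested invariant, since tie
  topology is not identifiable.
* LSD letters are assigned after sorting by descending mean, making the
  display invariant to input order.
* All statistics run on 32-bit-safe integer seeds; simulation substreams are
  hashed into [1, 2^31).

## Known limitations

* The fixed-blocking approximation understates the extra uncertainty a
  random-year model would add to broad-inference statements about *new*
  years; contrasts within the observed years are unaffected.
* VIP is reported for the fitted A = 2 components; orderings deep in the
  ranking (beyond the clearly separated top group) are sensitive to A and
  to sampling noise, so set-level statements are more stable than exact
  ranks.
* The 1.5-fold expression rule is a convention, not a test; no p-values are
  attached to ΔΔCT folds.
* No efficiency-corrected qPCR quantification, no multi-class PLS-DA, no
  REML variance components, and no raw-spectra processing — the pipeline
  starts at the quantified analyte table.
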