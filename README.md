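# antherlipids

Heat stress during flowering damages the pollen-bearing anthers of crop
plants, and one of the cell's first lines of defence is membrane remodeling:
under high temperature, plants lower the unsaturation of their membrane
glycerolipids (fewer 18:3 acyl chains, mostly via reduced omega-3 desaturase
activity) and shunt acyl chains into triacylglycerol (TAG) storage.
`antherlipids` is an R package for analyzing exactly this kind of experiment:
a field trial of several genotypes under ambient (AT) and heat (HT)
treatments, profiled by direct-infusion ESI-MS/MS into a table of normalized
lipid signals per sample, optionally accompanied by qRT-PCR CT values for
desaturase genes. It is aimed at plant stress physiologists and lipidomics
analysts who want the whole published analysis path as reusable, tested
functions.

## What it computes

* **Nomenclature** — parsing/formatting of shorthand lipid names:
  `CLASS(c:d)` with total acyl carbons *c* and total carbon–carbon double
  bonds *d*, explicit chain sets `TAG(18:2/16:0/18:1)`, and `_A`/`_B`
  variants for isobaric analytes.
* **QC filtering** — an analyte is removed when, in any year, its mean
  signal falls below the limit of detection (default 5·10⁻⁵ normalized
  units) or its coefficient of variation over quality-control-pool
  injections exceeds 0.3.
* **Composition** — headgroup-class and molecular-species percentages of
  total signal.
* **Unsaturation index** — per species, double bonds per acyl chain
  (*d*/chains); per class, the amount-weighted mean
  Σ(uᵢ·aᵢ)/Σaᵢ over the class's species.
* **Fatty-acid decomposition** — occurrence-weighted totals
  Σ(amount × occurrences of the fatty acid) over unambiguously assigned
  species, HT/AT fold changes, the PC 18:3/18:2 ratio, and the TAG:PC
  ratio.
* **Design statistics** — least-squares genotype × treatment cell means
  with year and block-within-year blocking, AT-vs-HT *t* tests, and
  Fisher's LSD compact letter display at α = 0.05.
* **PLS-DA** — from-scratch two-class NIPALS partial least squares
  discriminant analysis (mean-centering only, no autoscaling) with Wold's
  variable importance in projection, VIPⱼ = √(p·Σₐ SSₐ·w²ⱼₐ/Σₐ SSₐ),
  whose squares average to exactly 1.
* **Co-occurrence** — Spearman ρ across samples, single-linkage clustering
  on 1 − ρ, lipid groups as the connected components of the ρ ≥ 0.90 graph
  (equivalently, cutting the tree at that similarity), per-analyte
  heat-response arrows, and Newick export.
* **ΔΔCT expression** — 2^(−ΔΔCT) fold changes of desaturase genes
  normalized to *Actin-7*, with >1.5-fold direction calls.
* **Synthetic studies** — a seeded generator (89 analytes, 12 classes,
  2 years × 2 blocks × 4 replications, genotype-specific 18:3 depletion and
  TAG gain, planted co-occurrence blocks, QC pools, CT tables) so every
  stage is testable end to end without any external data.

## Worked example

```r
library(antherlipids)

res <- run_pipeline(run_config(seed = 1))
print(res$vip_top, n = 10)
```

```
    rank analyte                 vip
 1     1 PC(34:3)               4.91
 2     2 TAG(18:2/16:0/18:1)    3.15
 3     3 PC(36:5)               2.96
 4     4 TAG(16:0/18:3/18:2)    2.52
 5     5 TAG(18:1/18:3/18:2)    2.51
 6     6 TAG(18:2/18:2/16:0)_B  2.49
 7     7 TAG(18:2/16:0/16:0)    2.21
 8     8 PC(36:6)               2.10
 9     9 TAG(18:1/18:2/18:1)    1.87
10    10 PE(34:3)               1.81
```

The VIP ranking of this simulated study is led by the 18:3-containing PC
species that are planted to decrease under heat and by the TAG species
planted to increase — the discriminant analysis finds the heat-responsive
lipids. The co-occurrence stage recovers the planted correlation blocks as
ρ ≥ 0.90 groups, with their heat directions:

```r
print(res$cooccurrence)
#> <cooccurrence_result> 89 analytes, 4 groups at rho >= 0.9
#>   group 1: PC(34:3), PC(36:6), PC(36:5)
#>   group 2: PE(34:3), PE(34:2), PE(36:6), PE(36:5), PE(36:4)
#>   group 3: TAG(18:2/16:0/16:0), TAG(18:2/16:0/18:1), ...
#>   group 4: TAG(18:1/18:1/16:0), TAG(18:3/16:0/18:1)_A, ...
```

And the class unsaturation index drops under heat, here for the most
heat-responsive simulated genotype (units: double bonds per acyl chain,
mean ± SE of 16 observations):

```r
idx <- res$unsaturation
idx[idx$class %in% c("PC", "PE") & idx$genotype == "SPT 06-07", ]
#>   genotype  treatment class index    se     n
#> 1 SPT 06-07 AT        PC     1.70 0.0143    16
#> 2 SPT 06-07 HT        PC     1.60 0.0129    16
#> 3 SPT 06-07 AT        PE     1.68 0.0046    16
#> 4 SPT 06-07 HT        PE     1.62 0.0093    16
```

`autoplot(res$plsda)`, `plot_vip(res$plsda)`,
`plot_class_composition(res$class_composition)`, and
`autoplot(res$cooccurrence)` give the standard figures. To analyze your own
data, point `run_config(lipid_csv = ..., meta_csv = ..., ct_csv = ...)` at a
wide samples × analytes CSV (headers in the shorthand nomenclature), a
metadata CSV (`sample_id`, `genotype`, `treatment`, `year`, `block`,
`replicate`, `is_qc_pool`), and optionally a CT table.

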