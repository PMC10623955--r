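# bileaxis

Case–control analysis of the gut microbiome – bile acid – FGF19 axis, built
for studies that profile microbial bile-acid (BA) biotransformation genes
from stool metagenomes, quantify faecal BA panels by targeted
metabolomics, and relate circulating FGF19 to clinical outcome — here
atrial fibrillation (AF) as the case condition.

The package is tidyverse-native: every stage takes a data frame and
returns a tibble, fitted objects have `tidy()`/`glance()` methods and
`autoplot()` figures, and a synthetic-cohort generator with planted ground
truth makes the whole pipeline verifiable without any external download.

## What it computes

**Enzyme profiling.** Alignment hits of catalogue genes against 13
biotransformation enzymes — bile-salt hydrolase, the 7α-/7β-hydroxysteroid
dehydrogenases (CDCA ⇌ UDCA epimerisation) and the ten *bai* operon genes
(7-dehydroxylation of CA/CDCA to DCA/LCA) — are filtered by the 10× rule
(keep hits with e-value ≤ 10 × the gene's top hit), assigned best-hit
enzymes, and summed into enzyme × sample profiles. Per-gene taxonomy uses a
lowest-common-ancestor walk over the retained lineages. Group differences
use the Wilcoxon rank-sum test (exact for ≤ 12/group without ties).

**Producer genera.** Genus × enzyme harbouring matrices, pathway-based
producer sets (UDCA / LCA / DCA synthesis), the 7α+7β-HSDH pair set, genera
with ≥ 5 distinct *bai* genes, disjoint Venn regions, and a Spearman
genus–enzyme correlation network (TSV + GraphML).

**BA metabolomics.** Composition and secondary-BA proportion; per-analyte
differential tests with volcano coordinates; PCA; OPLS-DA (NIPALS with
orthogonal signal removal, 7-fold venetian-blind Q2) with VIP selection,

```math
\mathrm{VIP}_j = \sqrt{K}\,\lvert w_j\rvert,\qquad \tfrac1K\sum_j \mathrm{VIP}_j^2 = 1,
```

and ROC evaluation: AUC = normalised Mann–Whitney U (ties ½), DeLong 95%
CI, and the Youden-optimal cutpoint (max J = sens + spec − 1, midpoint
between observed values).

**Clinical association.** Baseline tables (Student t / Mann–Whitney /
chi-square / Fisher with documented gates), Pearson FGF19–LAD correlation,
univariate logistic screening (p < 0.100, diabetes forced) and a
multivariable logistic model with Wald odds ratios,
OR = exp(β), CI = exp(β ± 1.96·SE).

## Worked example

```r
library(bileaxis)

cfg <- simulation_config(seed = 1)     # 50/50 metagenome, 23/23 BA panel, 36/24 clinical
mg  <- simulate_metagenome(cfg)
asg <- assign_enzyme(filter_significant_hits(mg$hits))
prof <- compute_enzyme_profile(asg, mg$abundance)
dplyr::arrange(differential_features(prof, mg$groups), p_value)
#> # A tibble: 13 × 6
#>   enzyme  median_af median_control log2_fc  p_value direction
#> 1 BaiN      0.00705         0.0266   -1.73 3.74e-17 down-in-AF
#> 2 BaiH      0.00585         0.0211   -1.64 2.69e-16 down-in-AF
#> 3 7b-HSDH   0.00643         0.0265   -1.89 4.01e-16 down-in-AF
#> ...
```

The seven enzymes planted at 4-fold depletion in cases lead the table with
the planted direction. The BA panel stage:

```r
ba <- simulate_ba_panel(cfg)
m  <- fit_oplsda(ba$panel, ba$groups)
m
#> <ba_oplsda> 1 predictive + 1 orthogonal component(s), 24 variables
#>   R2X 0.361  R2Y 0.942  Q2 0.885
vip_select(m, p_table = differential_bas(ba$panel, ba$groups))
#> # A tibble: 16 × 4
#>   ba      vip      p_value direction
#> 1 TCDCA  1.45 0.0000000650 up-in-AF
#> 2 HCA    1.33 0.000000613  up-in-AF
#> 3 UDCA   1.26 0.00000288   up-in-AF
#> ...
roc_analysis(ba$panel$UDCA, ba$groups$group)
#> <ba_roc> AUC 0.904 (95% CI 0.818-0.990), 23 cases / 23 controls
#>   Youden cutpoint 124.9 (higher-in-cases marker): sens 0.870, spec 0.826
```

A Q2 of 0.885 says the class is predicted well out of fold; the 16
VIP-selected analytes recover the 12-up/4-down planted direction map, and
UDCA alone separates cases at AUC 0.904 with its Youden cutpoint printed in
nmol/g. `autoplot(m)`, `autoplot(m, "vip")`, `plot_volcano()` and
`autoplot()` on ROC/PCA objects draw the standard figures.

The full pipeline — simulation, profiling, producers, metabolome, clinical
model, all stage outputs as TSV/CSV/JSON/GraphML plus a consolidated
`report.json` — runs from one call:

```r
report <- run_pipeline(simulation_config(seed = 1), outdir = "run1")
```

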