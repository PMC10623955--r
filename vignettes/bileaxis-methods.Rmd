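---
title: "Methods: profiling the gut microbiome – bile acid – FGF19 axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling the gut microbiome - bile acid - FGF19 axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bileaxis)
```

## The scientific problem

Gut bacteria transform the host's primary bile acids (cholic acid, CA, and
chenodeoxycholic acid, CDCA) into secondary bile acids: the
7α-/7β-hydroxysteroid dehydrogenases (HSDHs) epimerise CDCA to
ursodeoxycholic acid (UDCA), and the ten-gene *bai* operon 7-dehydroxylates
CDCA to lithocholic acid (LCA) and CA to deoxycholic acid (DCA). Secondary
bile acids signal through the intestinal receptor FXR, inducing the hormone
FGF19. `bileaxis` implements a three-stage case–control analysis of this
axis — here with atrial fibrillation (AF) as the case condition:

1. **Functional profiling** of bile-acid enzyme genes from a metagenomic
   gene catalogue, with genus-level attribution and producer classification.
2. **Faecal bile-acid metabolomics**: composition, differential analysis,
   PCA, OPLS-DA with VIP selection, ROC biomarker evaluation.
3. **Clinical association**: baseline tables, FGF19–LAD correlation, and a
   univariate-screen → multivariable logistic model for case status.

Every stage is driven either by user data in plain-text formats or by the
package's synthetic-cohort generator, whose planted ground truth makes the
full pipeline testable end to end.

## Stage 1: enzyme profiling and taxonomic attribution

**Hit filtering.** Alignment hits of catalogue genes against the 13 enzyme
references (BSH, 7α-HSDH, 7β-HSDH, BaiB, BaiF, BaiA, BaiH, BaiI, BaiN,
BaiCD, BaiE, BaiA2, BaiG) are filtered per gene by the *10× rule*: a hit is
retained iff its e-value is at most 10 × the gene's minimum e-value
(inclusive, so the top hit always survives). An input e-value of exactly 0
is mapped to 1e-308 before multiplication — otherwise the threshold would
be 0 and every co-hit of a perfect match would be discarded, which is not
the rule's intent. The filter is idempotent.

**Enzyme assignment.** Each gene takes the enzyme of its best retained hit
(lowest e-value; ties broken by higher bitscore, then lexicographic enzyme
name, so assignment is deterministic). Best-hit assignment rather than
multi-assignment is a design choice: it keeps the enzyme profile a
partition of gene abundance, so profile mass can never exceed sample mass.

**Enzyme profile.** The abundance of enzyme *e* in sample *s* is the sum of
relative abundances of genes assigned to *e*. Enzymes without genes keep
explicit zero rows, so downstream tables always have 13 rows.

**Taxonomic LCA.** Taxonomy hits pass the same 10× filter; the gene's
lineage is then the deepest rank prefix shared by all retained lineages on
the fixed ladder superkingdom → … → species. Disagreement at superkingdom
leaves the gene at root. Lineages must satisfy the prefix property (no rank
below a missing rank); violations are an input error, not silently patched.
Genes resolved above genus are kept in enzyme profiles but excluded from
genus-level analyses.

**Differential testing.** Group differences use the two-sided Wilcoxon
rank-sum test: exact when both groups have ≤ 12 samples and the pooled data
are tie-free, otherwise the normal approximation with tie and continuity
correction. The 12-sample gate keeps exact enumeration cheap while covering
the metabolomics cohort sizes where exactness matters most. Fold changes
are ratios of group medians with pseudo-count ε = half the smallest nonzero
value of the feature; for data with negative values (where a ratio of
medians is meaningless) the fold change is NA. Raw p-values are primary —
Benjamini–Hochberg q-values are available but off by default, matching how
per-enzyme results are conventionally reported in this literature.

## Stage 1b: producer genera and the correlation network

A genus is a *potential producer* for a pathway if it harbours ≥ 1 gene of
any enzyme in that pathway. The default pathway map follows the
biotransformation chemistry: UDCA synthesis = {7α-HSDH, 7β-HSDH}; LCA and
DCA synthesis = the ten *bai* genes (the same operon acts on both routes);
BSH deconjugates but synthesises nothing, so it sits in no pathway set.
The map is fully configurable because reasonable alternatives exist (e.g.
restricting DCA synthesis to a *bai* subset). Two further summaries mirror
standard practice: genera carrying *both* HSDHs (the epimerisation pair)
and genera with a near-complete operon, defaulting to ≥ 5 distinct *bai*
genes. Venn regions are computed disjointly, so region counts always sum to
the union.

The genus–enzyme network correlates per-genus summed abundance with enzyme
profiles across samples. Spearman is the default (abundances are heavy
tailed and the quantity of interest is monotone association; edges are then
invariant under monotone transforms); Pearson is available. Edges need
p < 0.05 by default; zero-variance vectors are skipped with a warning
rather than producing NaN correlations.

## Stage 2: bile-acid panel analysis

**Composition.** Per-sample total bile-acid load and the secondary
proportion (secondary / total). The default class map assigns CA, CDCA and
their glycine/taurine conjugates to *primary* and everything downstream of
bacterial transformation (DCA, LCA, UDCA, HCA, keto/dehydro/iso
derivatives and their conjugates) to *secondary*; it is configurable
because conjugate grouping conventions differ between laboratories.
Zero-total samples have an undefined proportion: they are flagged and
excluded from the group test instead of contributing a 0/0.

**Scaling.** Before PCA and OPLS-DA, concentrations are log10(x + ε_j)
transformed (ε_j = half the variable's minimum nonzero value) and scaled to
unit variance. Log transformation linearises the multiplicative structure
of concentration data; unit variance stops abundant analytes from
dominating the latent space. Constant or all-zero variables cannot be
unit-scaled and are dropped with a warning.

**OPLS-DA.** The class response (case = 1, control = 0, centred) defines a
single predictive component by the NIPALS construction
w ∝ Xᵀy, ‖w‖ = 1; each orthogonal component removes class-uncorrelated
variation (w_o ∝ p − (wᵀp)w) before the predictive scores t = Xw are
taken. By construction the predictive scores are exactly orthogonal to
every orthogonal score. One orthogonal component is the default — the
usual choice for a two-class model — and 0 components reduce the model to
one-component PLS-DA (a test asserts score equality). Q2 comes from
7-fold venetian-blind (interleaved) cross-validation with scaling refit on
each training split, so no test information leaks through the
preprocessing. VIP is computed on the predictive component,
VIP_j = √K·|w_j| with K variables, so mean(VIP²) = 1 exactly and the
conventional VIP > 1 cut (strict) selects variables carrying more than
average discriminant weight. A permutation helper refits under shuffled
labels; sound models give permuted Q2 ≤ 0 essentially always.

**ROC.** Empirical AUC with ties counted one half — identical to the
normalised Mann–Whitney U, which a brute-force pair-counting oracle checks
to 1e-12 — with DeLong 95% confidence intervals. The optimal cutpoint
maximises Youden's J = sensitivity + specificity − 1 and is reported as the
midpoint between adjacent observed values; among equal-J candidates the
smallest cutpoint is taken (deterministic, and it favours sensitivity for
an "up" marker). Markers are auto-oriented so AUC ≥ 0.5, with the
orientation recorded.

## Stage 3: clinical association

Baseline comparisons follow a documented gate: continuous variables use the
pooled-variance Student t-test when both groups pass Shapiro–Wilk at 0.05,
otherwise Mann–Whitney; categorical variables use Yates-corrected
chi-square, switching to Fisher's exact test when any expected cell < 5.
These gates are deliberate defaults — published tables rarely state their
exact rules, so ours are explicit and tested. A summary-statistic t-test
(`t_test_from_summary()`) reproduces published rows from mean/SD/n alone.

The FGF19–LAD association uses complete-case Pearson correlation. Variable
selection mirrors the conventional two-step design: one single-predictor
logistic fit per covariate, candidates at p < 0.100, plus a forced set
(diabetes by default, as a known FGF19 confounder); the multivariable model
is then a maximum-likelihood logistic fit with Wald standard errors,
OR = exp(β) and 95% CI = exp(β ± 1.96·SE). Wald (not profile-likelihood)
intervals match the presentation convention of clinical tables. FGF19
enters untransformed in pg/mL, so its OR is per pg/mL. Separation is
detected heuristically (non-convergence, |β| > 15, or SE > 100) and flagged
loudly; flagged fits are never reported as converged.

## The synthetic-cohort generator

The generator emulates the statistical structure each stage assumes, with
defaults fixed once at the study's cohort scale:

* **Metagenome** (50 cases / 50 controls): 400 genes over a 40-genus pool —
  a desk-scale catalogue that keeps the full test suite fast while leaving
  every code path exercised; gene baselines N(0,1) on the log scale,
  within-gene log-normal noise (sdlog 1), closed-composition renormalisation
  to sum 1 per sample. 30% of genes carry enzyme identities spread evenly
  over the 13 references, each with its true enzyme as strict best hit,
  occasional within-threshold same-enzyme secondary hits, and 0–2
  off-target decoys planted beyond the 10× rule. Taxonomy hits mirror this:
  planted genus on top, 0–3 decoys beyond threshold, plus optional
  within-threshold confounders (`decoy_within`) for stressing the LCA
  backoff. E-values are log-uniform; exact 0 is never generated.
* **Planted enzyme effects**: the seven enzymes a depleted
  secondary-BA-synthesis phenotype flags (both HSDHs, BaiA, BaiA2, BaiH,
  BaiCD, BaiN) at 4-fold depletion in cases (log2 −2). At these sizes every
  planted effect is detected with the correct direction in well over 80% of
  seeds, which is the power the recovery tests assert.
* **BA panel** (23/23): log-normal concentrations around 50 nmol/g with
  coefficient of variation 1.0 — a realistic spread for faecal bile acids —
  and the canonical direction map: 12 analytes up in cases (UDCA, bUDCA,
  HCA, 7-KetoLCA, 3-DHCA, 6-KetoLCA, CDCA, TCA, CA, GUDCA, TCDCA, TUDCA)
  and 4 down (dehydroLCA, 12-ketoLCA, LCA, GDCA), at 4-fold effects.
* **Clinical table** (36 cases / 24 controls): control FGF19 log-normal
  with median ≈ 233 pg/mL and log-SD 0.87 (an interquartile spread typical
  of plasma FGF19), case shift −0.51 on the log scale (≈ 40% lower);
  LAD normal (36 mm + 5 mm case shift, SD 5); LVEF normal with a −4% case
  shift; diabetes Bernoulli; age/sex/BMI group-independent.

**Correlation calibration.** The target FGF19–LAD correlation is defined on
the *observed raw-scale Pearson r*. Because FGF19 is log-normal (which
attenuates any latent normal correlation by σ/√(e^σ² − 1)) and both
variables carry group shifts (which add covariance of their own), the
latent correlation is solved analytically from the configured moments so
the sample r converges to the target. Targets whose solution would need
|ρ_latent| ≥ 1 raise an error instead of silently missing.

**Determinism.** One master seed; each table draws from a deterministically
derived child stream, so regenerating any single table never perturbs the
others, and identical configurations give byte-identical output files.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: inter-analyte covariance (real BA panels are
strongly cross-correlated along shared pathways), measurement censoring at
the limit of quantification, zero inflation, compositional coupling between
bile-acid concentrations, batch effects, real taxonomy (lineages are a
synthetic 3-per-family ladder), and any relationship between the
metagenomic, metabolomic and clinical cohorts beyond shared group labels.
Power statements transfer to real cohorts only to the extent that real
dispersions resemble the configured ones, which are free parameters, not
estimates.

## Problem sizes and numerical choices

The test suite validates against independent oracles at fixed sizes chosen
to keep the default run comfortably interactive: 1,000-list hit-filter and
LCA comparisons, exhaustive Wilcoxon enumeration for all group sizes ≤ 7,
500 pair-counting AUC checks, 100 label permutations for Q2, 1,000-rep
Wald-coverage simulation at n = 500, ~2,000 null features for calibration,
and 200-seed recovery runs at the default cohort sizes. Key tolerances:
closed-composition sums to 1 ± 1e-9; score orthogonality and VIP algebra
at 1e-8; AUC against brute force at 1e-12; logistic closed forms at 1e-6.

Known limitations: a single predictive component (two-class designs only);
no compositional log-ratio treatment of relative abundances (they are
consumed as given); DeLong intervals degenerate at AUC = 1; exact Wilcoxon
is skipped in the presence of ties (the corrected approximation is used
instead); and the LCA operates on a fixed seven-rank ladder without
intermediate ranks.
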