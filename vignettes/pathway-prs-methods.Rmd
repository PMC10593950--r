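---
title: "Pathway-partitioned polygenic scores: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-partitioned polygenic scores: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathprs)
library(data.table)
```

## The question the package addresses

A genome-wide polygenic risk score (PRS) aggregates risk-allele dosages
weighted by GWAS effect sizes. When the trait of interest is biologically
heterogeneous — schizophrenia being the canonical example — a natural
refinement is to partition the score by biology: for a named gene set
(say, postsynaptic density, axon, or histone H3-K4 methylation), build one
PRS from the SNPs annotated to the set's genes and a second PRS from *all
remaining* SNPs ("whole genome minus set"). Entering both scores jointly
into one model asks whether the pathway carries signal for a phenotype
*beyond* the rest of the genome, rather than merely echoing overall
polygenic burden.

`pathprs` implements that design end to end: summary-statistic QC and
allele harmonization, interval-based SNP-to-gene annotation, gene-set
partitioning of the SNP universe, clumping + thresholding (C+T) scoring of
each set and its complement, derived neuroimaging-style and rare binary
questionnaire phenotypes, three joint association model families,
per-phenotype Benjamini–Hochberg FDR, and a circular genomic permutation
test for significant gene-set associations. A synthetic-data generator with
a recorded ground truth makes every stage testable without access to any
controlled cohort.

## Scoring model

For subject $i$ and SNP subset $S$, the raw score is
$\mathrm{PRS}_i(S) = \sum_{j \in S} \hat\beta_j \, g_{ij}$, with
$\hat\beta_j$ the harmonized GWAS per-allele effect (log-odds for
case-control GWAS) and $g_{ij} \in \{0,1,2\}$ the effect-allele dosage
(missing dosages mean-imputed per SNP). The subset $S$ is produced by
greedy LD clumping (retain a SNP iff its $r^2$ with every already retained
SNP on the same chromosome within the window is below the threshold,
visiting SNPs by ascending GWAS p) followed by p-value thresholding at each
of the five standard thresholds $.01, .05, .1, .5, 1$, with $.1$ treated as
the primary one. Scores are z-scored before modeling, so reported effects
are per-SD standardized coefficients and the raw-sum-versus-average choice
is immaterial.

Clumping is performed **once, genome-wide**, and the retained list is then
intersected with each set and complement. The alternative — clumping each
set's SNP list separately — is available via `clump_scope = "per-set"`. We
made global clumping the default for two reasons: it makes the additive
identity $\mathrm{PRS}(\mathrm{set}) + \mathrm{PRS}(\mathrm{complement}) =
\mathrm{PRS}(\mathrm{universe})$ hold exactly (a strong invariant the test
suite asserts to machine precision), and it lets the permutation null
rebuild both halves of the partition from cached per-SNP contributions
instead of re-clumping per rotation. Circular permutation is only offered
for the global scope.

## Annotation conventions

Gene coordinates are internally 1-based inclusive; BED input (0-based
half-open) is converted once at the reader boundary. A SNP maps to a gene
iff it lies within the gene body extended by a symmetric `window_kb` flank.
The default window is 0 kb: annotation-tool windows vary across studies and
a strict gene-body default is the conservative, reproducible choice — the
parameter is exposed rather than hard-coded. Gene sets may overlap; each
set receives its own independent set/complement partition, which is exactly
the paired design the joint models expect.

## Association model families

All families take the gene-set PRS and its complement PRS jointly, plus
nuisance covariates on their native scale (their scaling cannot affect the
PRS coefficients):

* **linear** (`fit_linear_joint`) — OLS for unilateral/global continuous
  phenotypes; outcome and both PRSs z-scored, so $t = \beta/\mathrm{se}$
  and p comes from the $t$ tail with the usual residual df.
* **bilateral-mixed** (`fit_bilateral_joint`) — for phenotypes measured
  once per hemisphere: a subject-level random intercept absorbs the
  within-person correlation, hemisphere enters as a fixed within-subject
  covariate. Estimated by REML via `lmer` with Satterthwaite df; a zero
  between-subject variance is an acceptable boundary estimate (the fit then
  agrees with pooled OLS, which the tests verify). Subjects without exactly
  one L and one R row are dropped with a warning.
* **logistic** (`fit_logistic_joint`) — for rare binary questionnaire
  items; the effect is the log-odds change per SD of PRS. Complete
  separation raises an error instead of returning a divergent fit.

Imaging models adjust for age, age², sex, 15 genetic PCs, scan site, three
head-position coordinates and genotype array, with intracranial volume
added for gray-matter phenotypes only; the binary-item models use the
reduced set age, sex, 15 PCs and array. Whether age² belongs in the binary
models is genuinely ambiguous in the source protocol; we implemented it as
listed (absent) and left it switchable through the covariate builder.
Missing data are handled by listwise deletion with dropped counts logged,
which is why per-phenotype n varies in the outputs.

## Multiple testing and the permutation null

Q-values are BH step-up within one family per phenotype, members being all
gene sets × both predictors × all thresholds — the closest reading of
"applied separately for each phenotype and across all p-value thresholds".
The family key is configurable.

A gene-set association that survives FDR still inherits a subtle
confound: the set is tiny relative to its complement, and any LD-clustered
subset of SNPs could score well by accident. The circular genomic
permutation addresses this: order the clumped, thresholded SNPs by
(chromosome, position), join them into a circle, and rotate the membership
labels by a random nonzero offset. Each rotation preserves every SNP's
weight, the set's size, and the local LD of the pruned panel, while
re-assigning which contiguous genomic stretch is "the set". For each of
`n_perm` distinct offsets both scores are rebuilt and the same joint model
refitted; the empirical p is $(r+1)/(n_{\mathrm{perm}}+1)$ with $r$ the
count of null $|t|$ at least as large as the observed one — never zero and
never above one by construction. Two-sided comparison on $|t|$ was chosen
because standardized effects are reported in both directions. Rotations
that produce a degenerate (constant) score are redrawn and logged. For the
linear family the per-rotation refit uses Frisch–Waugh–Lovell
residualization against the fixed covariate block, which reproduces the
full OLS t exactly (the suite checks agreement to 1e-8) at a small fraction
of the cost; the mixed and logistic families refit in full. By default only
associations whose set-PRS q ≤ 0.05 are permuted, mirroring a
significant-hits-only protocol; a flag permutes the full grid.

## What the generator emulates — and what it does not

`sim_config()` fixes the study conditions:

* **Genotypes.** Latent Gaussian AR(1) blocks (`block_size`, correlation
  `rho`, default 20 SNPs at 0.8), thresholded at each SNP's MAF quantile
  into two independent haploid draws per subject. This yields dosages with
  controllable within-block $r^2$ and independent blocks — exactly the
  structure clumping needs to be exercised — with MAFs uniform on
  `maf_range` (default 0.05–0.5).
* **Summary statistics.** Spike-and-slab true effects: causal with
  probability `prop_causal` (default 0.1), multiplied by `set_enrichment`
  inside the target set; slab variance `h2_like`. Observed effects add
  noise with the additive-model asymptotic SE
  $1/\sqrt{2\,n_{\mathrm{gwas}}\,\mathrm{maf}(1-\mathrm{maf})}$
  (default $n_{\mathrm{gwas}} = 100{,}000$), avoiding the cost of
  simulating a discovery cohort while keeping the SE–MAF coupling real
  data shows.
* **Continuous phenotypes.** $y = \gamma_{\mathrm{set}}
  \mathrm{PRS}^{\mathrm{true}}_{\mathrm{set}} + \text{covariate effects} +
  u_i + e_{ih}$, emitted as left/right rows; variance components are scaled
  to total 1 so `gamma_set` is a *standardized* effect, `icc` (default 0.5)
  splits the residual into subject-level and hemisphere-level parts, and
  `var_covariates` (default 0.1) fixes the covariate share.
* **Binary items.** Four rare lifetime items from a logistic model whose
  intercept is solved numerically (`uniroot`) for the target prevalence
  (default 2%, matching the 0.5–3% range typical of population
  psychotic-like-experience items); a distress rating is drawn for
  positives with `distress_frac` rated "distressing". The distress
  contrast is distressing-reporters versus non-reporters, with
  neutral/positive reporters set missing — the alternative coding is behind
  a switch.

One global seed fans out to fixed per-stage child seeds, so regenerating
one stage never perturbs another, and all outputs are bit-identical under a
fixed seed.

The generator deliberately does **not** model realistic human LD maps,
imputation INFO, the X chromosome, population stratification that
correlates with phenotype, or item-level questionnaire wording. Passing
tests therefore demonstrate that the *machinery* is correct and calibrated
under a known generative model — not that any particular real-data
association would replicate.

## Numerical choices and degenerate inputs

* Clumping ties (equal p) break by (chromosome, position); a zero-variance
  SNP is treated as uncorrelated with everything ($r = 0$).
* Duplicate summary-statistic ids drop *all* copies — the correct record
  cannot be adjudicated. Odds ratios convert to log-odds at read time so a
  single effect scale flows through. Records whose alleles mismatch the
  panel are dropped; swapped-allele records are sign-flipped. Position
  disagreements warn but do not drop, since matching is by id and
  build-version drift is common.
* Standardization uses the sample SD (n − 1); constant vectors error
  rather than silently producing NaN.
* The composite-PC sign is fixed so scores correlate positively with the
  subject-wise mean of the standardized inputs: "first unrotated principal
  component" leaves the sign free, and downstream effect signs depend on it.
* Outlier exclusion is a single pass at mean ± 3 SD (no re-estimation);
  both the per-phenotype and the modality-composite scopes are available
  because both conventions appear in published protocols — the caller
  chooses what vector to pass.
* The empirical p estimator $(r+1)/(n_{\mathrm{perm}}+1)$ avoids zero
  p-values from finite permutation counts.

## Problem sizes used by the shipped experiments

The calibration experiment runs 200 replicates of n = 1000 subjects ×
2000 SNPs with 199 rotations each; the power experiment plants
$\gamma_{\mathrm{set}} = 0.3$ on a contiguous two-gene set at n = 2000 over
20 replicates; parameter recovery uses 50 replicates at n = 2000 (linear),
one n = 2000 bilateral fit, and 50 replicates at n = 10,000 with 2%
prevalence (logistic). These sizes give the binomial bands quoted in the
tests (e.g. a [0.02, 0.09] acceptance band for a 5% rejection rate over
200 replicates) while keeping a full run on one desktop core in minutes.
Recovery experiments regress on the generator's *true* set PRS (part of
the truth record): the planted effect is defined on that scale, and C+T
estimation attenuates it by the correlation between estimated and true
scores, which is a property of score construction noise rather than of the
estimators under test. The estimated-score path is exercised separately by
the permutation power experiment.

## Known limitations

* Per-set clump scope disables the permutation test (re-clumping inside
  every rotation is the only exact analogue and is not implemented).
* The LD model is block-diagonal AR(1); long-range LD, MHC-like mega-blocks
  and MAF-dependent LD are absent, so clumping behaves more cleanly here
  than on real panels.
* Logistic recovery at 2% prevalence carries the usual small upward
  finite-sample MLE bias (order a few percent at ~200 cases); the recovery
  tolerance absorbs it.
* INDELs and build liftover are out of scope; harmonization assumes
  shared rs-style identifiers.
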