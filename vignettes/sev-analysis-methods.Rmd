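---
title: "Detecting stochastic epigenetic variations: models and methods"
author: "sevscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stochastic epigenetic variations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevscan)
```

## The problem

DNA methylation arrays report, for every interrogated CpG, a beta value in
[0, 1]: the fraction of methylated signal at that site.  Most epigenetic
epidemiology asks whether *mean* methylation differs between groups.  A
complementary question is whether individual subjects carry *stochastic
epigenetic variations* (SEVs): single CpGs at which one subject's
methylation is an extreme outlier relative to a reference population —
candidate epimutations.  A subject's SEV burden, and whether their SEVs
cluster in particular genomic regions (notably germline imprinting-control
DMRs), is informative about early developmental instability, e.g. in
cohorts conceived by assisted reproduction.

sevscan implements this analysis end to end: per-CpG outlier fences,
per-subject calls and burden under multiple reference populations,
hypergeometric region enrichment, mixed-phenotype dimension reduction, and
the burden-versus-phenotype association stage.

## The SEV statistic

At each CpG, the reference cohort's quartiles define extreme-outlier
fences

$$L = Q_1 - 3 \cdot IQR, \qquad U = Q_3 + 3 \cdot IQR,$$

the extreme-whisker limits of a box-and-whiskers summary (multiplier 3, not
the conventional 1.5).  A subject's value is a SEV iff it lies *strictly*
beyond a fence; ties at the fence are not outliers, matching the convention
that boxplot outliers lie strictly beyond the whisker limit.  Per subject
we report the SEV count and its natural log; the log of the count plus one,
flagged, when the count is zero.

Two numerical choices deserve note:

* **Quartile convention.** The default is Tukey hinges (the quartile rule
  behind R's boxplot statistics), with linear-interpolation quantiles as an
  option.  On small reference cohorts the two differ; every reported result
  uses the default.
* **Fences are not clipped to [0, 1].**  A fence below 0 or above 1 is
  infeasible — it simply yields no calls on that side.  Probes with zero
  IQR collapse to a point; calls at such probes are kept but tallied
  separately (`n_zero_iqr`) because a zero-IQR fence flags *any* deviation.

Three reference populations are supported simultaneously (the study design
this package serves used an internal cord-blood control group, an external
cord-blood cohort and a general-population whole-blood cohort).  For the
internal reference the default is *pooled* calling: members of the
reference are called against fences computed from the whole reference,
themselves included.  A leave-one-out mode is available; for any reference
member the leave-one-out count is at least the pooled count, since a
subject's own extreme values can only widen the pooled fences.

## Region enrichment

Whether a subject's SEVs cluster is tested with the hypergeometric
upper-tail probability: with $N$ post-QC probes genome-wide, $K$ in the
region, $n$ subject SEVs genome-wide, and $k$ in the region, the p-value is
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$.  The test is applied
to sliding windows (default 5 kb width, 2.5 kb step — the width matches the
5 kb tiling convention; the overlap is a documented choice, the source
protocol does not fix one), and to arbitrary region sets (genes, promoters,
imprinted DMRs).  Bonferroni correction is per subject over the tested
(non-empty) regions of one set; direction of the calls is ignored.
Promoters are derived as 1500 bp upstream to 500 bp downstream of the
strand-oriented TSS; annotation positions are 1-based (manifest
convention), all interval files 0-based half-open BED, converted explicitly
at the containment test.

## Quality control

Probes flagged as SNP-overlapping, sex-chromosomal, or overlapping rare
variants are removed first (a probe flagged twice is attributed to the
first criterion in that fixed order).  Reliability filtering reads the
detection p-value threshold literally: an entry is unreliable iff
$p \ge 0.05$ (closed at the threshold).  The greedy pruning step then
iteratively removes the row or column with the highest unreliable fraction
(ties: probe before sample, then lexicographic) until every row and column
is at or below `max_unreliable`; the default 0 removes until fully
reliable.  This is a simplified stopping rule — the reference
implementation in array-processing suites uses an ROC-style curve — chosen
because the analysis this package reproduces reported only the outcome of
the step, not its trajectory.

## Phenotype dimension reduction (FAMD)

Perinatal phenotype tables mix continuous traits (weights, centiles,
gestational age, cell-composition fractions) with categoricals (sex,
smoking, cesarean, folate supplementation, season of birth).  Factor
analysis of mixed data generalizes PCA to such tables: continuous columns
are standardized (population variance); each categorical is expanded to
indicators, each indicator divided by the square root of its level
frequency and centered.  The SVD of the combined matrix yields sample
scores (Dims) and loadings; total inertia is the number of continuous
variables plus $\sum(\text{levels}-1)$.  With only continuous columns this
is exactly standardized PCA.  Each dimension is oriented so its
largest-magnitude loading is positive, making signs reproducible.

Dimension–trait relations are summarized by Pearson correlation
(continuous), point-biserial correlation (binary) and the correlation ratio
(multi-level categoricals), flagged at $|\rho| > 0.5$ and $p < 0.01$.  The
maximum-likelihood polyserial/polychoric alternative was deliberately not
implemented: its estimation machinery is out of proportion to its role (a
visual correlogram), and the substitution is a documented divergence.
Season of birth is treated as a plain four-level categorical; no cyclic
encoding is attempted.  A per-dimension logistic screen against case
status flags candidate confounder dimensions; perfect separation is
detected and reported with a floored likelihood-ratio p rather than a
failure.

## Association of SEV burden with phenotypes

Per reference mode, one OLS fit of log(SEVs) on all retained dimensions
plus chip-batch indicators gives per-dimension t-test p-values; each
dimension's three p-values are combined by Fisher's method
($-2\sum\ln p \sim \chi^2_{2k}$, exact zeros floored at $10^{-300}$) and
Bonferroni-corrected over the dimensions.  All dimensions enter jointly
(the alternative — one model per dimension — is available by subsetting the
scores).  Fisher's method assumes independent inputs; the three modes share
subjects, so the combination is anti-conservative.  This mirrors the
analysis the package reproduces and is documented rather than changed; the
null-calibration test shows the adjusted rejection rate stays within its
Monte-Carlo bound at the package's study conditions.

The per-site scan (`ewas_lite`) is plain OLS with classical standard
errors, a genome-wide flag at $p < 10^{-7}$ and the genomic inflation
factor $\lambda$ = median observed 1-df chi-square / 0.4549364.  It exists
for the inflation diagnostic and covariate-adjustment demonstration, not as
a replacement for moderated-statistics engines.  The sample-size utility
uses the standard two-group normal approximation.

## The synthetic study

No subject-level data are distributed with this package; all calibration
and power results are computed on a synthetic generator whose defaults
encode the emulated study design: 41 reference and 23 case subjects, a
bimodal beta landscape (45% hypomethylated near 0.1, 45% hypermethylated
near 0.9, 10% intermediate), subject noise Beta(mean·ν, (1−mean)·ν) with
precision ν = 100 (matching the unimodal-around-mode shape of normalized
array betas without modeling intensities), two chip batches with
per-batch/per-probe shifts of sd 0.01, detection p-values almost all below
0.01 with a 0.1% unreliable fraction, and an expected 20 injected
epimutations per subject.

Key generator decisions:

* **Injection magnitude.**  An injected SEV is set to the midpoint between
  the fence and the nearer of {0, 1}; the direction is drawn uniformly
  among feasible sides (a fence below 0 or above 1 is infeasible).  This
  guarantees detectability regardless of quantile convention.
* **Winsorised baseline.**  After batch shifts, baseline values falling
  outside the clean cohort's own fences are clipped to 0.02 inside the
  fence (bounded by IQR/2, which provably leaves the Tukey hinges — and
  hence the fences — unchanged).  Injected epimutations are therefore the
  *only* outliers, and ground-truth recovery is exact: sensitivity 1, zero
  false calls, by construction.  The 0.02 margin keeps clipped values from
  being borderline at replicate-noise scale (the duplicate-concordance
  experiment adds noise of sd 0.01).  Real arrays do have natural extreme
  tails; in this generator that biology is represented by `sev_rate`
  itself, so passing recovery tests demonstrates correctness of the
  calling machinery, not that real data are free of ambiguous calls.
* **Per-component RNG streams.**  Annotation, baseline betas, batch
  shifts, injections, the defect, detection p-values and phenotypes each
  draw under their own sub-seed derived from the master seed, so changing
  `sev_rate` does not perturb baseline betas and identical configs are
  bit-identical.
* **Latent factors.**  Four standard-normal subject factors drive both the
  phenotypes (fixed loading pattern: factor 1 dominates centiles,
  gestational age, cesarean, parental BMI and adaptive cell fractions;
  factor 2 the weights; factor 3 smoking/NK/season; factor 4
  folate/cesarean) and, through `phenotype_effect`, the per-subject SEV
  rate ($\text{rate}_i = \texttt{sev\_rate} \cdot e^{\sum_f \beta_f f_{if}}$).
  Cell proportions are a closed composition (log-linear weights normalized
  to sum 0.97), hence non-negative and summing below 1.
* **Imprinting defect.**  The defect subject receives mid-range aberrant
  values (0.6 for hypomethylated probes, 0.4 for hypermethylated, sd 0.02)
  at every probe of one DMR — the signature of a mosaic loss/gain of
  parent-of-origin methylation.  DMRs span at least 8 contiguous probes so
  the cluster is enrichable.
* **The Poisson injection model is a modeling choice.**  No empirical
  per-subject epimutation-rate distribution was available to emulate; a
  Poisson count with log-linear factor modulation is the simplest
  mechanism consistent with the downstream log-linear association model.

What the generator does *not* emulate: probe type chemistry and intensity
noise, genotype artifacts under probes, cell-composition effects on
methylation itself (composition appears only as a phenotype), spatial
correlation of neighbouring CpGs, and batch effects more structured than
additive shifts.  Tests passing on this generator validate the pipeline's
statistics, not the biology of any particular cohort.

## Problem sizes and test design

The packaged experiments run at desk scale, chosen so the full suite
completes in minutes while keeping every statistical property measurable:
exact fence/call equivalence on 200 random small matrices against a
brute-force oracle; exact ground-truth recovery at 10,000 probes x 64
subjects; hypergeometric exactness by complete enumeration for all
universes up to N = 12 plus PMF-tail summation on larger random cases;
imprinting-defect detection over 100 seeds at 1,000 probes (target: at
least 95 detections, clean-subject false rate at most 0.05); association
null calibration over 200 replicates at 300 probes and power over 100
seeds at 400 probes with a planted factor-1 slope of 0.3; duplicate
concordance at 2,000 probes over 30 replicate pairs.  Counts scale with
probe number, so burden summaries at these sizes are smaller than
array-scale values by roughly the probe-count ratio; all rates,
calibrations and recovery properties are scale-free.

## Known limitations

* Pooled internal calling means a reference member's own value influences
  its fences; the leave-one-out mode quantifies the difference.
* Fisher combination across reference modes ignores their dependence
  (shared subjects) and is anti-conservative.
* Bonferroni throughout; no FDR alternative is offered because the
  reproduced analysis used Bonferroni exclusively.
* `ewas_lite` uses classical standard errors; it will be conservative or
  anti-conservative where moderated variance estimators would differ.
* No missing-data imputation in FAMD; no rotation; no supplementary
  projection.
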