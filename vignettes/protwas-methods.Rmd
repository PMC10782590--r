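---
title: "Methods: proteome-wide association from pQTL prediction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide association from pQTL prediction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`protwas` implements a proteome-wide association study (PWAS) in the
TWAS/FUSION style.  For each plasma protein measured by an aptamer, a
genetic prediction model $\hat{p} = \sum_j w_j x_j$ is trained on a pQTL
cohort from cis and trans SNP dosages $x_j$, validated in an independent
subcohort, and then tested against disease GWAS summary statistics with

$$ Z_{\mathrm{PWAS}} = \frac{w' Z}{\sqrt{w' \Sigma_{s,s} w}}, $$

where $Z$ is the vector of per-SNP Wald z-scores from the GWAS, $w$ the
prediction weights, and $\Sigma_{s,s}$ the SNP correlation (LD) matrix
estimated from an external reference panel.  Under the null of no
association between the genetically predicted protein level and the
outcome, $Z_{\mathrm{PWAS}}$ is standard normal; the two-sided p-value is
$2(1-\Phi(|z|))$, floored at $10^{-300}$ to keep log-scale work finite.

## Pipeline stages and their parameters

**Variant QC.**  A SNP enters training iff imputation info $\ge 0.7$,
MAF $\ge 0.05$, Hardy-Weinberg exact-test $p \ge 5\times10^{-6}$,
missing rate $< 0.05$, and it is present in the LD reference panel (all
inclusive comparisons at the boundary).  The HWE test is the exact
conditional test on hard calls, computed with the mode-outward
recurrence; we use it rather than the $\chi^2$ approximation because the
$5\times10^{-6}$ threshold sits in the far tail where $\chi^2$ is
anticonservative at low MAF.  Imputation info is carried as metadata
(assigned by the simulator; supplied by the user for real data) — the
package does not recompute it from dosage distributions.

**Protein preprocessing.**  Raw abundances are strictly positive
(relative fluorescence); they are log-transformed (natural log — any
base difference vanishes after the rank transform) and adjusted by OLS
for age, sex, blood-draw-to-processing duration and three ancestry PCs.
Constant covariate columns are dropped from the design (all-constant
reduces to plain centering); samples missing any covariate are excluded
listwise with a reported count.  Residuals are mapped through the
rank-based inverse normal transform
$\Phi^{-1}((r_i - c)/(n - 2c + 1))$ with the Blom offset $c = 3/8$
(exposed as a parameter) and average ranks on ties.

**Predictor selection.**  A marginal scan (simple regression of the
adjusted phenotype on mean-imputed dosage) seeds the model: cis SNPs
(within 1 Mb of the encoding gene's TSS) passing Benjamini–Hochberg
FDR $\le 0.05$ computed *per protein over its cis SNPs*, and trans SNPs
at $p \le 5\times10^{-8}$ (trans is everything else, including the rest
of the gene's chromosome).  Each seed contributes a half-open
$\pm 100$ kb window; overlapping windows merge, and merged blocks are
laid on a single pseudo chromosome with a 1 Mb spacer — order- and
distance-preserving, so locality information survives while cross-window
adjacency is never implied.  Strand-ambiguous (A/T, C/G) SNPs are
excluded at extraction, where allele orientation starts to matter.

**Learners.**  Four models are fit on standardized dosages: `top1` (the
single smallest-p marginal SNP; ties by largest $|z|$ then snp id),
`lasso` and `enet` (glmnet, mixing 0.5 for the elastic net, penalty by
inner 5-fold CV at `lambda.min`), and `blup` — ridge regression with
$\lambda = m(1-\hat h^2)/\hat h^2$, where $\hat h^2$ is a grid-profile
maximum-likelihood estimate of the single-variance-component model
$y = g + e$, $g \sim N(0, h^2 XX'/m)$, computed from the SVD of $X$
(classical BLUP/ridge equivalence under equal per-SNP prior variance);
if $\hat h^2$ hits the grid boundary the fit falls back to CV-chosen
ridge.  Model quality is the squared correlation between the phenotype
and out-of-fold predictions over 5 outer folds whose assignment is
derived deterministically from the seed and the *sorted* sample ids
(hence invariant to input order).  A fold where a sparse learner selects
no SNP contributes the constant (centered-mean) prediction.  The best
method by this cv $R^2$ is retained when cv $R^2 \ge 0.01$; exact ties
break toward the sparser method (top1 < lasso < enet < blup).

**External validation.**  Stored weights are per allele (standardized
weights divided by the training dosage SD), so prediction in a new
cohort is a plain dosage dot product; swapped-allele SNPs contribute
$2-d$, mismatched or ambiguous SNPs are dropped, missing dosages are
mean-imputed.  The gate is the *signed* Pearson correlation
$r \ge 0.1$ against the validation cohort's own adjusted phenotypes
(adjusted and rank-normalized within that cohort): a model that predicts
with the wrong sign is a failed model even though $r^2$ may be large.

**Association.**  Per model SNP, harmonization against the summary
statistics keeps exact allele matches, negates z on swapped alleles, and
drops ambiguous/mismatched/absent SNPs.  A protein is skipped when
*strictly more than half* of its model SNPs are unusable (exactly half
is still tested); the LD matrix over the used SNPs is the panel
correlation of mean-imputed dosages, repaired by eigenvalue flooring at
$10^{-8}$ with re-symmetrization and unit-diagonal restoration (ridge
shrinkage would perturb non-degenerate directions; flooring touches only
the null space).  Because $\Sigma$ is a correlation matrix, per-allele
weights are rescaled by the panel dosage SDs before the statistic is
evaluated.  Significance uses Bonferroni $p < \alpha/m$ with $m$ the
number of proteins actually tested in the run; an absolute threshold can
be supplied instead to reproduce a published cutoff — the package does
not guess a denominator.

## The synthetic world

The generator emulates a two-cohort pQTL study (defaults: 2481 training,
820 validation samples) plus a 503-sample reference panel, the size of
the 1000 Genomes European panel.  Genotypes are hard calls from a binary
AR(1) haplotype Markov chain: within an LD block all SNPs share one MAF
(drawn from the configured range) and adjacent haplotype alleles have
correlation $\rho$, so standardized dosages have correlation exactly
$\rho^{|i-j|}$ and every SNP is in Hardy-Weinberg proportions.  We chose
this over thresholding a latent Gaussian because dichotomization
attenuates correlations below the nominal $\rho$, breaking the
closed-form target the tests check.  Proteins are built on a latent
standardized scale — cis genetic + trans genetic + covariate loadings +
Gaussian noise — with effects rescaled against the *population* LD so
the cis/trans variance shares equal the planted $h^2$ exactly in the
generative law; the emitted value is $\exp(\mathrm{latent})$ so the
pipeline's log step is real.  Effect sizes have no canonical published
distribution, so the causal architecture (counts, $h^2$) is
configuration, not assertion.  GWAS z-vectors are drawn from
$\mathrm{MVN}(\mu, \Sigma)$ with $\mu = 0$ under the null and
$\mu = \gamma\sqrt{N}\,\Sigma w_{\mathrm{true}}$ under a
protein-to-disease effect — the standard summary-statistic generative
model conjugate to the tested statistic.

What a green test does **not** establish: the simulator has no
population structure, no imputation noise, a flat MAF spectrum within
blocks, no aptamer cross-reactivity or batch structure, and cohorts
drawn from one generative law — so external-validation concordance on
synthetic data is a consistency check of the code path, not evidence
about real-data transferability.

## Numerical choices and known behaviors

* **p-value floor** $10^{-300}$; z-to-p always two-sided normal.
* **Degenerate LD** (duplicated SNPs) is repaired, not rejected;
  degenerate predicted-protein variance ($w'\Sigma w \le 10^{-12}$)
  skips the protein with a reason code.
* **Null calibration of cv $R^2$.**  The pooled out-of-fold squared
  correlation — the estimator the field reports — has a heavy null
  tail: model selection shared across folds leaks full-sample chance
  alignment, so under pure noise individual replicates occasionally
  exceed the 0.01 retention gate (about 20% of replicates have some
  method above it at $n=500$, 50 SNPs) even though the per-method mean
  and median stay an order of magnitude below the gate.  Tests assert
  the mean/median calibration, which is the property that holds.
* **Summary vs individual-level statistic.**  $Z_{\mathrm{PWAS}}$ and
  the OLS z of the outcome on the predicted protein agree only up to a
  $1/\sqrt{1-R^2}$ factor that the summary statistic omits; agreement at
  $|\Delta| < 0.05$ is therefore a weak-effect statement, and the
  matched-simulation check runs at $h^2 = 0.01$ — the scale of the
  retention gate, i.e. the weakest instruments the pipeline would keep.
* **Published-table checks.**  The packaged 69-row association table is
  verified for p/z consistency with a relative tolerance of
  $\max(5\%, e^{0.005|z|}-1)$ (the second term is the worst-case effect
  of 2-decimal z printing).  Fourteen large-$|z|$ rows are internally
  inconsistent beyond even that tolerance in the source; the check
  reports them rather than widening the band.  The published threshold
  check uses $\le$ at printed precision because the last row prints
  exactly at the threshold.
* **Distances** to risk SNPs are anchored at the TSS (the cis definition
  is TSS-based) and reported in kb to 2 decimals; this check is
  informational since the source's anchor is unstated.

## Limitations

No sample-level QC, no imputation, no conditional/joint seed refinement,
no colocalization or MR sensitivity analyses, and no PLINK binary
reader (genotypes travel in a documented TSV dosage dialect).  The BH
scope is per protein; a study-wide FDR over all cis tests would be a
different analysis and is deliberately not offered as an option.
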