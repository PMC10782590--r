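# protwas

Proteome-wide association studies (PWAS) from pQTL genetic prediction
models and GWAS summary statistics.

## The problem

Observational protein–disease associations are confounded and can run
backwards (disease changes the proteome).  A PWAS sidesteps both by
testing the *genetically predicted* component of each plasma protein's
level against a disease GWAS: train per-protein SNP weight models in a
proteogenomic cohort, validate them in an independent subcohort, then
combine the weights with GWAS z-scores through an LD reference panel.
For each protein with weights $w$, GWAS z-vector $Z$ and reference LD
matrix $\Sigma_{s,s}$ over the model SNPs, the association statistic is

$$ Z_{\mathrm{PWAS}} = \frac{w' Z}{\sqrt{w' \Sigma_{s,s} w}} \sim N(0,1)
   \ \text{under the null}, $$

with two-sided $p = 2(1-\Phi(|z|))$ and Bonferroni correction over the
proteins tested.

`protwas` implements the full pipeline for biostatisticians working with
this design:

* **variant QC** — imputation info ≥ 0.7, MAF ≥ 0.05, Hardy–Weinberg
  exact test p ≥ 5×10⁻⁶ (Wigginton-style recurrence), missing rate
  < 5%, reference-panel membership, strand-ambiguity detection;
* **protein preprocessing** — log transform, covariate adjustment (age,
  sex, processing duration, 3 ancestry PCs), rank-based inverse normal
  transform (Blom offset 3/8);
* **weight training** — cis seeds by per-protein Benjamini–Hochberg
  FDR ≤ 0.05 (±1 Mb of the TSS), trans seeds at p ≤ 5×10⁻⁸, merged
  ±100 kb windows on a single pseudo chromosome; four learners (top1,
  LASSO, elastic net, BLUP/ridge with ML variance-component shrinkage)
  with deterministic 5-fold cross-validation and the cv R² ≥ 0.01 gate;
* **external validation** — allele-aware prediction into a second
  cohort, signed correlation gate r ≥ 0.1;
* **association engine** — allele harmonization (flip, drop-ambiguous),
  skip rule when > 50% of model SNPs are unusable, PSD-repaired panel
  LD, Bonferroni or absolute-threshold significance;
* **synthetic-data module** — a first-class generator for a two-cohort
  study with exact blockwise AR(1) LD, planted cis/trans heritability,
  covariate effects, planted QC violations, and GWAS z-vectors drawn
  from MVN(γ√N·Σw, Σ), so every stage is testable at desk scale.

## Worked example

```r
library(protwas)

cfg <- sim_config(n_train = 1500, n_valid = 820, n_ref = 503,
                  n_blocks = 2, n_snps = 25, ld_rho = 0.5, seed = 11)
G     <- simulate_genotypes(cfg, "train")
truth <- make_truth(G, cfg, aptamer_id = "APT001", h2_cis = 0.3,
                    n_cis = 4, seed = 11)
covs  <- simulate_covariates(G$samples, seed = 11)
prot  <- simulate_proteome(G, covs, truth, seed = 11)
y     <- prepare_phenotypes(prot$proteins, covs)[, "APT001"]

G    <- compute_snp_stats(G)
kept <- filter_snps(G$snps)$kept
model <- train_protein(G, y, gene_chrom = attr(truth, "gene_chrom"),
                       tss = attr(truth, "tss"), kept = kept,
                       aptamer_id = "APT001", seed = 11)
print(model)
#> weight_model APT001: lasso, 11 SNPs (11 cis / 0 trans), cv R2 = 0.298
```

The chosen learner (LASSO here) explains cv R² ≈ 0.30 of the adjusted
phenotype, close to the planted h² = 0.3.  Validate externally and test
against (simulated, alternative-hypothesis) GWAS summary statistics:

```r
G2    <- simulate_genotypes(cfg, "valid")
covs2 <- simulate_covariates(G2$samples, seed = 12)
y2    <- prepare_phenotypes(simulate_proteome(G2, covs2, truth,
                                              seed = 12)$proteins,
                            covs2)[, "APT001"]
validate_model(predict_protein(G2, model), y2, aptamer_id = "APT001")
#> external validation: r = 0.525 (r2 = 0.275), pass = TRUE

panel <- simulate_genotypes(cfg, "ref")
ld    <- ld_from_panel(panel, model$weights$snp_id)
w_std <- model$weights$weight * ld$sd[model$weights$snp_id]
w_u   <- w_std / sqrt(as.numeric(t(w_std) %*% ld$Sigma %*% w_std))
ss    <- simulate_gwas_sumstats(ld$Sigma, w_true = w_u, gamma = 0.01,
                                N = 4.5e5, seed = 13,
                                snps = G$snps[match(model$weights$snp_id,
                                                    G$snps$snp_id), ])
run_pwas(list(model), ss, panel, p_threshold = 3.01e-5)
#>   aptamer_id method n_used missing_frac   z_pwas            p significant
#> 1     APT001  lasso     11            0 8.629592 6.157147e-18        TRUE
```

A protein–disease slope of γ = 0.01 per SD at N = 450,000 yields
z ≈ 8.6: the model's predicted level is strongly associated with the
outcome, and with no SNPs missing from the summary statistics the
skip rule does not fire.

The package also ships a 69-row published PWAS association table
(`load_table1()`) used by `check_table1()` and `summarize_associations()`
— its direction split is 45 positive / 24 inverse associations.

## Command line

An installed `exec/protwas` script exposes the stages:

```sh
protwas simulate --config sim.json --out simdir --seed 1
protwas qc       --geno simdir/train --out qcdir
protwas prep     --proteins prot.tsv --covars simdir/train.covariates.tsv --out pheno.tsv
protwas train    --geno simdir/train --pheno pheno.tsv --gene-meta genes.tsv --out models --seed 1
protwas validate --geno2 simdir/valid --pheno2 pheno2.tsv --models models --out valdir
protwas assoc    --models models --sumstats ss.tsv --panel simdir/ref --out assoc.tsv
protwas report   --assoc assoc.tsv --out report
```

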