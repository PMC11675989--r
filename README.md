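# dogfear

Behavioral genetics of multi-breed dog cohorts from SNP array data.

Kennel and breeding programs increasingly want to select *against* fearful
behavior, which requires knowing whether fear phenotypes are heritable,
which loci are associated with them, and whether aggregate genetic scores
separate fearful from confident dogs. `dogfear` packages that entire
analysis as tested, reusable R code, aimed at quantitative geneticists and
veterinary-behavior researchers working with PLINK-formatted genotypes and
scored behavioral assessments:

* **Genotype handling** — bit-exact PLINK 1 `.bed/.bim/.fam` reader/writer,
  marker QC (autosomes only, MAF > 0.05, call rate > 0.90), per-variant
  mode fill of sporadic missing calls, and 200/50/0.6 sliding-window LD
  pruning.
* **Inbreeding** — the excess-homozygosity estimator
  F̂ = (O_hom − E_hom)/(L − E_hom) with small-sample frequency correction,
  and an F-test-gated two-population comparison (pooled vs Welch t-test)
  that also accepts published mean/variance/n summaries.
* **Phenotypes** — PCA of assessment items with Kaiser-normalized varimax
  rotation, KMO sampling adequacy, regression-method component scores
  (social fear, non-social fear, startle response), and fixed-effect
  adjustment (facility, sex, size, age, GRM PCs screened at α = 0.05).
* **Heritability** — AI-REML on the single-GRM animal model
  y = Xβ + g + e, g ~ N(0, Kσ_g²), with eigendecomposition-accelerated
  iterations and delta-method standard errors for
  h² = σ_g²/(σ_g² + σ_e²).
* **Association** — per-SNP linear mixed model with kinship correction,
  restricted-likelihood profiling of the variance ratio, Wald tests,
  Bonferroni (α/m) and suggestive (1/m) thresholds, genomic inflation
  λ = median(qchisq(1−p,1))/qchisq(0.5,1), and plot-ready Manhattan/QQ
  tables.
* **Annotation and risk scores** — 500-kb flanking windows merged at 1 Mb
  around top markers, SNP-to-gene distances, and count-based (cGRS) and
  effect-weighted (wGRS) genetic risk scores compared across ±1 SD
  phenotype-extremity bins with Tukey–Kramer adjustment.
* **Synthetic cohorts** — a Balding–Nichols multi-breed generator with
  block LD, within-breed inbreeding, sporadic missingness, and phenotypes
  with known causal SNPs and target heritability, so every stage above is
  validated by parameter recovery without any external data.

## Worked example

```r
library(dogfear)

cfg <- sim_config(seed = 2024)            # 6 breeds x 100 dogs, 5000 SNPs
sim <- simulate_genotypes(cfg)
ph  <- simulate_phenotypes(sim$geno, sim$samples, cfg)

qc     <- qc_filter(sim$geno, sim$variants)
geno   <- fill_sporadic_missing(qc$geno)
kept   <- ld_prune(geno, qc$variants)
geno   <- geno[, kept]

pca <- fit_pca_varimax(ph$behavior)
K   <- compute_grm(geno, "centered")
adj <- adjust_phenotype(pca$scores[, "SF"], sim$samples,
                        grm_pcs(compute_grm(geno, "variance_standardized")))
reml_h2(adj$residuals, K)
```

Running the full driver sequence (`analysis/01_simulate.R` …
`analysis/07_genes_grs.R`) on this seed prints, among other things:

```
PCA: 73.0% of item variance in 4 components (KMO = 0.82)
SF: h2 = 0.181 +/- 0.107 (converged, 8 iterations)
SF: lambda_gc = 0.940, 4 markers below the suggestive threshold
SF CGRS: less fearful 5.80 +/- 2.16 vs more fearful 4.34 +/- 2.27 (Tukey p = 1.4e-06)
```

Read: the rotated components explain 73% of item variance; social fear is
moderately heritable on the adjusted scale (attenuated from the latent
target of 0.30 by item discretization and fixed-effect adjustment — see
the methods vignette); the association scan is well calibrated (λ ≈ 1);
and dogs in the confident extreme bin carry significantly more risk
alleles than dogs in the fearful extreme bin, a descriptive (in-sample)
separation. Stage tables land under `results/`.

`vignettes/dogfear-methods.Rmd` documents the models, defaults, numerical
choices, and known limitations.

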