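---
title: "Methods: behavioral genetics of a multi-breed kennel cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral genetics of a multi-breed kennel cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dogfear` implements, as one tested toolchain, the analysis stages used in
SNP-based behavioral genetics of multi-breed dog cohorts: marker quality
control, inbreeding-coefficient comparison between populations, construction
of fear phenotypes from behavioral assessment items, SNP heritability,
kinship-corrected genome-wide association, gene-window annotation, and
genetic risk scoring. Because raw cohort genotypes are rarely available, a
synthetic-cohort generator with known ground truth is a first-class module:
every downstream stage is validated by parameter recovery against what the
generator planted.

This vignette is the package's account of the science: the models, the
tunable parameters and their defaults, the numerical choices, and what the
validation does and does not demonstrate.

## The synthetic cohort

`sim_config()` / `simulate_genotypes()` / `simulate_phenotypes()` emulate a
multi-breed commercial-breeding cohort:

* **Breed differentiation.** Ancestral minor-allele frequencies are drawn
  Uniform(0.05, 0.5); per-breed frequencies follow the Balding–Nichols model
  Beta(p(1−Fst)/Fst, (1−p)(1−Fst)/Fst). The default Fst = 0.15 is at the
  low end of between-breed differentiation in dogs, appropriate for a cohort
  of related companion breeds.
* **Within-breed inbreeding.** Each dog carries two haplotypes; at each
  marker the second haplotype is identical by descent to the first with
  probability F (default 0.05, mild kennel-level inbreeding). This yields
  the classical excess-homozygosity genotype frequencies
  P(hom minor) = p² + Fp(1−p), P(het) = 2p(1−p)(1−F). The IBD overlay is
  applied to a *copy* of the chain state: feeding it back into the LD chain
  would compound identity along blocks and inflate realized F well above
  its nominal value.
* **Linkage disequilibrium.** Within blocks of `ld_block_len` (default 10)
  markers, each haplotype allele copies its left neighbor with probability
  `ld_rho` (default 0.7), giving the pruning stage realistic structure to
  act on. This is a caricature of real canine LD — block lengths are
  constant in marker count, not in recombination distance, and there is no
  breed-specific LD decay.
* **Phenotypes.** Four latent components (social fear, food motivation,
  non-social fear, startle response) are each built as fixed effects
  (kennel facility, sex, size class, age) plus a genetic term plus noise.
  The genetic term mixes a handful of causal SNPs (`n_causal`, default 20;
  `causal_var_frac` = 0.5 of genetic variance) with a polygenic tail over
  all markers, and the genetic/residual parts are rescaled so the genetic
  fraction equals `h2_target` (default 0.3, matching moderately heritable
  fear traits) *exactly* in the realized sample. Assessment items are the
  latent component plus item noise, cut at tertiles to the 0/1/2 scale
  (binary items at the median). Default cohort composition — 6 breeds × 100
  dogs, 40 facilities, 83% female, ages Uniform(1, 10) years — mirrors a
  mid-sized multi-facility kennel study.

What the generator does **not** emulate: real genome coordinates,
recombination-rate variation, pedigree structure within kennels,
genotyping batch effects, and rater effects on the behavioral items.
Passing recovery tests therefore demonstrates internal statistical
correctness of each stage under the stated generative model, not robustness
to every artifact of field data.

## Genotype I/O and marker QC

Genotypes travel as PLINK 1 binary triplets; the 2-bit SNP-major codec is
implemented bit-exactly (round trips are byte-identical, including missing
calls). QC applies, in order: removal of non-autosomal/unmapped markers
(dog autosomes are labelled 1–38), removal of monomorphic markers and
indels, a strict MAF filter (retain MAF > 0.05 — a marker at exactly 0.05
is removed), and a strict call-rate filter (> 0.90). The `qc_report`
satisfies an exact conservation law: removals plus retained equals input,
every run.

Sporadic missingness is filled with the per-variant modal dosage (ties to
the smaller dosage). At the ~1% "sporadic" rates this stage is meant for,
mode fill and haplotype-based imputation are statistically
indistinguishable for the downstream moment-based estimators; haplotype
phasing is out of scope.

LD pruning mirrors window-based pairwise pruning (window 200 variants,
step 50, r² > 0.6): within each window, while any retained pair exceeds
the threshold, the member with the smaller MAF is removed (equal MAF: the
later variant). The tie-break makes the rule deterministic; pruning an
already-pruned panel removes nothing.

## Inbreeding coefficients and population comparison

`compute_ibc()` is the method-of-moments excess-homozygosity estimator:
F̂ = (O_hom − E_hom)/(L − E_hom), with E_hom summed over the individual's
non-missing markers as 1 − 2f(1−f)·n/(n−1) using within-group allele
frequencies and the small-sample allele-count correction. Because each
breed has its own fixed or nearly fixed markers, the driver scripts redo
QC and pruning *within* each breed before estimating F̂; skipping that
re-filter biases breed-level estimates.

`compare_ibc_groups()` gates a two-sample t-test on a two-tailed F-test of
variance equality (ratio of larger to smaller variance, doubled tail,
α = 0.05): unequal variances select Welch's t-test with unrounded
Welch–Satterthwaite degrees of freedom, otherwise the pooled test with
n₁+n₂−2 df. The function accepts published group summaries
(mean/variance/n) directly, so printed comparison tables are reusable as
fixtures; `breed_ibc_summaries()` ships one such 16-breed table and
`compare_ibc_table()` reproduces its p-values and unequal-variance flags.

## Behavioral components

`fit_pca_varimax()` runs PCA on the item correlation matrix and retains
four components — the component count is fixed by design rather than by a
retention rule, because the downstream phenotypes (SF, NSF, SR, plus the
excluded food-motivation component) are defined a priori by the assessment
instrument. Kaiser-normalized varimax rotation is iterated to convergence
(`stats::varimax`, eps 1e-10); rotation is orthonormal, so total explained
variance is preserved to numerical precision. Components are labelled by
which item group (approach-test items, treat/play items, novel-object
items, umbrella items) loads highest, greedily by strongest affinity, and
each component is signed so its defining items load positively: higher
scores mean a more confident, less fearful dog. Scores use the regression
method, S = Z R⁻¹ Λ, and are column-centered.

The sampling-adequacy measure is the standard KMO ratio of squared
off-diagonal correlations to squared correlations plus squared anti-image
partial correlations q = −P/√(P_ii P_jj), P = R⁻¹. For two items the same
formula applies and evaluates to exactly 1/2 (the 2×2 anti-image partial
correlation equals r), which avoids an undefined corner.

`adjust_phenotype()` screens facility, sex, size class, age, and the top
two principal components of the *variance-standardized* GRM one at a time
(marginal F-test, retain at p < 0.05 — the retention threshold is a design
choice), then regresses the phenotype on all retained effects jointly and
returns the residuals. When nothing is significant the adjusted phenotype
is simply the centered raw score. Factor levels observed once are dropped
with a warning.

## SNP heritability

`reml_h2()` fits y = Xβ + g + e, g ~ N(0, Kσ_g²), e ~ N(0, Iσ_e²) by
average-information REML. Numerical choices:

* **One-time eigendecomposition.** K is diagonalized once; every iteration
  then costs O(n) for the likelihood, score, and AI matrix.
* **Scale normalization.** K is divided by its mean diagonal before
  fitting. The centered GRM (1/m)Σ(x−x̄)(x−x̄)ᵀ has mean diagonal equal to
  the average marker dosage variance (≈ 0.4 for typical MAF spectra), not
  1; without normalization σ_g² is not on the phenotypic scale and
  h² = σ_g²/(σ_g²+σ_e²) systematically overstates the genetic fraction.
  Normalizing matches the convention of unit-diagonal GRMs and makes h²
  the phenotypic genetic fraction directly.
* **Positivity and convergence.** Components start at var(y)/2, updates
  use the AI step with step-halving so the restricted likelihood never
  decreases, negative proposals are truncated at 1e-6·var(y), and
  convergence requires a relative parameter change below 1e-8 or a
  likelihood change below 1e-10 (at most 100 iterations; non-convergence
  is flagged, not hidden). Variances are bounded positive, so h² stays in
  [0, 1].
* **Uncertainty.** se(h²) comes from the delta method on the inverse AI
  matrix at the optimum. A kinship matrix numerically proportional to the
  identity makes σ_g² and σ_e² inseparable; that case warns and returns a
  flagged result.

The estimate is invariant to phenotype rescaling, and the
eigendecomposition likelihood is tested against a direct dense-inversion
oracle.

**A coupling worth knowing about.** With few, strongly differentiated
breeds, most of the polygenic variance lies along the breed axes of K —
the very directions the GRM-PC adjustment removes. REML on the adjusted
phenotype is then downward-biased, occasionally to the zero bound (the
package's own driver scripts show this for a 6 × 100 cohort when PC1/PC2
are retained). This is a property of the design, not a defect of the
estimator; heritability parameter-recovery is therefore validated on a
single-breed (panmictic) cohort of 600 dogs × 5,000 markers, where the
estimate recovers a planted h² = 0.30 within two reported standard errors,
averaged over ten generator seeds. Analyses of strongly structured cohorts
should interpret post-PC-adjustment heritability as within-structure
heritability.

## Association scan

`lmm_assoc()` fits the per-SNP mixed model y = Wα + xβ + u + ε with
u ~ N(0, Kσ_g²) after one eigendecomposition of K. The variance ratio
σ_g²/σ_e² is profiled by 1-D optimization of the restricted likelihood —
a 41-point grid on log-ratio in [1e-5, 1e5] followed by Brent refinement —
either per SNP (`mode = "exact"`) or once under the covariate-only model
and reused for every SNP (`mode = "null"`, the fast EMMAX-style default in
the driver scripts; under the null the two agree almost exactly). β̂ and
se(β̂) come from generalized least squares in the rotated space and the
Wald p-value from χ²₁. With K proportional to the identity the estimator
reduces exactly to ordinary least squares. Monomorphic markers yield NA
records with a logged count; missing genotypes must be filled first.

Thresholds follow the m-test conventions: Bonferroni α/m and suggestive
1/m, both also on the −log₁₀ scale. Note the suggestive threshold depends
on the marker count actually carried into the scan, which can differ from
the QC-retained count if markers drop out later (e.g. monomorphic after
subsetting to phenotyped animals); the reporting cut-off used for
tabulating top associations (default 4 × 10⁻⁵) is presentation only and
deliberately distinct from the inference thresholds. The genomic inflation
factor is λ = median(qchisq(1−p, 1))/qchisq(0.5, 1); under a
permuted-phenotype null the scan holds λ within [0.9, 1.1] and the
empirical type-I rate at 0.05 ± 0.01, and an injected causal variant
explaining ~12% of phenotypic variance is the genome-wide top hit in at
least 9 of 10 seeds.

## Gene windows and risk scores

`build_windows()` places a 1-based inclusive window of width 2 × flank
(default 500 kb per side) around each hit — [pos − flank + 1, pos + flank]
— and merges same-chromosome hits separated by at most 1 Mb into one
window spanning min(pos) − flank + 1 to max(pos) + flank, clamped at
position 1. Merging is order-independent and idempotent.
`annotate_windows()` reports every overlapping gene with the distance from
the nearest member SNP to the nearer gene edge (0 inside the gene);
distances are measured to the nearest edge rather than the gene start, and
upstream/downstream is positional (strandless), since assessment-scale
annotations rarely carry meaningful strand context. BED input is converted
from 0-based half-open at the boundary.

Risk scores treat the minor allele as the risk allele. The count score
recodes a negative-effect SNP by full reversal (count = 2 − dosage), so
counts stay in {0, 1, 2} and the protective homozygote contributes 0; the
weighted score uses signed weights on raw dosage, wGRS = Σ β·dosage, so
protective markers contribute negatively — consistent with extreme-group
mean wGRS being negative on the fearful side. The SNP set is an explicit,
logged parameter (the driver scripts use all markers below the reporting
cut-off) because score magnitudes scale directly with the set size.
Extremity bins use the population SD with inclusive thresholds (boundary
dogs count as extreme; for continuous phenotypes the convention is
immaterial). Group comparisons use a one-way linear-model F-test with
Tukey–Kramer-adjusted pairwise comparisons (studentized range, valid for
unbalanced groups) and kernel-density curves per group for plotting.

**Circularity is surfaced, not hidden:** when effect estimates come from
the same sample that is being binned, extreme-group separation is expected
partly by construction. The comparison output carries an `in_sample` flag
and its print method labels the result descriptive, not predictive;
out-of-sample polygenic scoring is explicitly out of scope.

## Problem sizes

The test suite and acceptance script run at desk scale by choice: cohorts
of 500–600 dogs and 5,000 markers for parameter-recovery checks (ten
generator seeds where an average is asserted), and toy fixtures of tens of
markers wherever an exhaustive or hand-computed oracle is the comparison.
These sizes keep every oracle exact and every run reproducible; all
algorithms are O(n³) or better in samples and linear in markers, and scale
directly to array-sized panels.

## Known limitations

* Item discretization to the 0/1/2 scale attenuates component scores
  relative to the latent traits (recovery correlations ≈ 0.85–0.95), so
  heritability estimated from PCA scores sits below the latent-scale
  target; parameter-recovery checks therefore run on the latent scale.
* The LD simulator has constant-length blocks and no recombination map;
  pruning behavior on real canine LD will differ quantitatively.
* Per-breed QC plus pruning inside small groups (n ≈ 10–20) leaves
  frequency estimates noisy; the F-test gate inherits that noise, as the
  published-summary fixtures show for small-n breeds.
* The AI-REML positivity bound censors genuinely zero-heritability traits
  at a tiny positive value; estimates at the bound are reported with
  `converged = FALSE` when the boundary prevents the step criterion from
  being met.
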