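#!/usr/bin/env Rscript
# SNP heritability of each adjusted phenotype by AI-REML on the centered
# genomic relationship matrix (QC'd, pruned markers).
suppressPackageStartupMessages(library(dogfear))

pl <- read_plink("scratch/cohort/cohort.bed")
kept <- readLines("results/qc/retained_variants.txt")
geno <- fill_sporadic_missing(pl$geno)[, kept]
adj <- read.delim("results/behavior/adjusted_phenotypes.tsv")
K <- compute_grm(geno, "centered")

rows <- lapply(setdiff(names(adj), "id"), function(comp) {
  fit <- reml_h2(adj[[comp]], K)
  cat(sprintf("%s: h2 = %.3f +/- %.3f (%s, %d iterations)\n", comp, fit$h2,
              fit$se_h2, if (fit$converged) "converged" else "NOT converged",
              fit$n_iterations))
  data.frame(phenotype = comp, h2 = fit$h2, se = fit$se_h2,
             sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
             converged = fit$converged)
})
dir.create("results/heritability", showWarnings = FALSE)
write.table(do.call(rbind, rows), "results/heritability/heritability.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
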