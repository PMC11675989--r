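#!/usr/bin/env Rscript
# Kinship-corrected LMM association for each adjusted phenotype, with
# Bonferroni/suggestive thresholds, genomic inflation factors, and
# plot-ready Manhattan/QQ tables.
suppressPackageStartupMessages(library(dogfear))

pl <- read_plink("scratch/cohort/cohort.bed")
kept <- readLines("results/qc/retained_variants.txt")
geno <- fill_sporadic_missing(pl$geno)[, kept]
variants <- pl$variants[match(kept, pl$variants$id), ]
adj <- read.delim("results/behavior/adjusted_phenotypes.tsv")
K <- compute_grm(geno, "centered")
th <- significance_thresholds(ncol(geno))
cat(sprintf("thresholds over %d markers: Bonferroni %.3g, suggestive %.3g\n",
            th$n_variants, th$bonferroni_p, th$suggestive_p))

dir.create("results/gwas", showWarnings = FALSE)
for (comp in setdiff(names(adj), "id")) {
  rec <- lmm_assoc(adj[[comp]], geno, K, variants = variants, mode = "null")
  lam <- genomic_inflation(rec$wald_p[!is.na(rec$wald_p)])
  n_sug <- sum(rec$wald_p < th$suggestive_p, na.rm = TRUE)
  cat(sprintf("%s: lambda_gc = %.3f, %d markers below the suggestive threshold\n",
              comp, lam, n_sug))
  write.table(rec, sprintf("results/gwas/assoc_%s.tsv", comp), sep = "\t",
              quote = FALSE, row.names = FALSE)
  md <- manhattan_qq_data(rec, th)
  write.table(md$manhattan, sprintf("results/gwas/manhattan_%s.tsv", comp),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(md$qq, sprintf("results/gwas/qq_%s.tsv", comp), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
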