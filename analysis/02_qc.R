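#!/usr/bin/env Rscript
# Marker QC on the simulated cohort: autosomal/polymorphic category filter,
# MAF > 0.05, call rate > 0.90, per-variant mode fill, then 200/50/0.6
# sliding-window LD pruning.
suppressPackageStartupMessages(library(dogfear))

pl <- read_plink("scratch/cohort/cohort.bed")
qc <- qc_filter(pl$geno, pl$variants)
filled <- fill_sporadic_missing(qc$geno)
kept <- ld_prune(filled, qc$variants)
report <- qc$report
report$n_removed_prune <- report$n_retained - length(kept)
report$n_retained <- length(kept)

dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write.table(as.data.frame(unclass(report)), "results/qc/qc_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(kept, "results/qc/retained_variants.txt")
print(report)
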