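#' Run the full behavioral-genetics pipeline on a simulated cohort
#'
#' Orchestrates every stage end to end from one configuration: cohort
#' simulation (or PLINK triplet ingestion), marker QC, sporadic-missingness
#' fill, LD pruning, per-breed inbreeding coefficients (breeds with fewer
#' than \code{min_breed_n} dogs are excluded, with the reason logged),
#' behavioral PCA with varimax rotation, fixed-effect phenotype adjustment,
#' GRM construction, AI-REML heritability, kinship-corrected GWAS,
#' gene-window construction (and annotation when a gene table is supplied),
#' and count/weighted genetic risk scores. Every stage artifact is written
#' as TSV under \code{out_dir} and a JSON manifest records parameters, the
#' seed, QC accounting, and md5 checksums of all artifacts.
#'
#' @param config List with either \code{sim} (a \code{\link{sim_config}}) or
#'   \code{bed_path}/\code{behavior_path}/\code{samples_path}; optional
#'   \code{genes_path}; thresholds \code{maf_min}, \code{call_rate_min},
#'   \code{prune_window}, \code{prune_step}, \code{prune_r2},
#'   \code{alpha}, \code{flank}, \code{merge_gap}, \code{sd_mult},
#'   \code{grs_p_cutoff}, \code{min_breed_n}; and \code{out_dir}.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  defaults <- list(maf_min = 0.05, call_rate_min = 0.90, prune_window = 200,
                   prune_step = 50, prune_r2 = 0.6, alpha = 0.05,
                   flank = 5e5, merge_gap = 1e6, sd_mult = 1,
                   grs_p_cutoff = 4e-5, min_breed_n = 10,
                   out_dir = tempfile("pipeline_"))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  tsv <- function(df, name) {
    utils::write.table(df, out(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    name
  }
  artifacts <- character(0)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  # --- ingest or simulate -------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- simulate_genotypes(config$sim)
    ph <- simulate_phenotypes(sim$geno, sim$samples, config$sim)
    geno <- sim$geno
    variants <- sim$variants
    samples <- sim$samples
    behavior <- ph$behavior
    note("simulated cohort: ", nrow(geno), " dogs x ", ncol(geno), " SNPs")
  } else {
    pl <- read_plink(config$bed_path)
    geno <- pl$geno
    variants <- pl$variants
    samples <- utils::read.delim(config$samples_path,
                                 stringsAsFactors = FALSE)
    behavior <- utils::read.delim(config$behavior_path,
                                  stringsAsFactors = FALSE)
    note("loaded cohort: ", nrow(geno), " dogs x ", ncol(geno), " SNPs")
  }
  artifacts <- c(artifacts, tsv(samples, "samples.tsv"),
                 tsv(behavior, "behavior.tsv"))

  # --- marker QC, fill, prune --------------------------------------------
  qc <- qc_filter(geno, variants, maf_min = config$maf_min,
                  call_rate_min = config$call_rate_min)
  geno_qc <- fill_sporadic_missing(qc$geno)
  kept <- ld_prune(geno_qc, qc$variants, window = config$prune_window,
                   step = config$prune_step, r2_max = config$prune_r2)
  report <- qc$report
  report$n_removed_prune <- report$n_retained - length(kept)
  report$n_retained <- length(kept)
  geno_pruned <- geno_qc[, kept, drop = FALSE]
  variants_pruned <- qc$variants[match(kept, qc$variants$id), ]
  note("QC retained ", report$n_retained, " of ", report$n_input,
       " variants after pruning")
  artifacts <- c(artifacts,
                 tsv(as.data.frame(unclass(report)), "qc_report.tsv"),
                 tsv(variants_pruned, "variants_retained.tsv"))

  # --- per-breed inbreeding ----------------------------------------------
  ibc_rows <- list()
  for (breed in unique(samples$breed)) {
    idx <- which(samples$breed == breed)
    if (length(idx) < config$min_breed_n) {
      note("breed ", breed, " excluded from IBC: n = ", length(idx),
           " < ", config$min_breed_n)
      next
    }
    sub_qc <- qc_filter(geno[idx, , drop = FALSE], variants,
                        maf_min = config$maf_min,
                        call_rate_min = config$call_rate_min)
    sub <- fill_sporadic_missing(sub_qc$geno)
    sub_kept <- ld_prune(sub, sub_qc$variants,
                         window = config$prune_window,
                         step = config$prune_step,
                         r2_max = config$prune_r2)
    ibc <- compute_ibc(geno[idx, sub_kept, drop = FALSE])
    ibc_rows[[breed]] <- cbind(breed = breed, ibc$ibc,
                               n_markers_used = ibc$n_markers_used)
  }
  if (length(ibc_rows) > 0) {
    artifacts <- c(artifacts, tsv(do.call(rbind, ibc_rows), "ibc.tsv"))
  }

  # --- behavior PCA and adjustment ---------------------------------------
  pca <- fit_pca_varimax(behavior)
  K_vs <- compute_grm(geno_pruned, "variance_standardized")
  pcs <- grm_pcs(K_vs, k = 2)
  K <- compute_grm(geno_pruned, "centered")
  artifacts <- c(artifacts,
                 tsv(data.frame(item = rownames(pca$rotated_loadings),
                                round(pca$rotated_loadings, 4)),
                     "pca_loadings.tsv"),
                 tsv(data.frame(id = samples$id, pca$scores),
                     "component_scores.tsv"))
  note(sprintf("PCA: %.1f%% variance in %d components, KMO = %.2f",
               100 * sum(pca$explained_variance), ncol(pca$scores),
               pca$kmo))

  phenos <- setdiff(pca$labels, "FM")
  h2_rows <- list()
  assoc_list <- list()
  grs_rows <- list()
  windows_all <- list()
  genes_all <- list()
  gene_table <- if (!is.null(config$genes_path)) {
    read_gene_annotation(config$genes_path)
  } else NULL

  for (ph_name in phenos) {
    adj <- adjust_phenotype(pca$scores[, ph_name], samples, pcs,
                            alpha = config$alpha)
    y <- adj$residuals
    keep_y <- !is.na(y)
    h2 <- reml_h2(y[keep_y], K[keep_y, keep_y])
    h2_rows[[ph_name]] <- data.frame(phenotype = ph_name, h2 = h2$h2,
                                     se = h2$se_h2,
                                     converged = h2$converged)
    rec <- lmm_assoc(y[keep_y], geno_pruned[keep_y, , drop = FALSE],
                     K[keep_y, keep_y], variants = variants_pruned,
                     mode = "null")
    assoc_list[[ph_name]] <- rec
    lambda <- genomic_inflation(rec$wald_p)
    note(sprintf("%s: h2 = %.3f +/- %.3f, lambda_gc = %.3f", ph_name,
                 h2$h2, h2$se_h2, lambda))
    artifacts <- c(artifacts,
                   tsv(rec, paste0("assoc_", ph_name, ".tsv")))

    hits <- rec[!is.na(rec$wald_p) & rec$wald_p < config$grs_p_cutoff, ]
    if (nrow(hits) > 0) {
      win <- build_windows(hits, flank = config$flank,
                           merge_gap = config$merge_gap)
      windows_all[[ph_name]] <- cbind(phenotype = ph_name, win)
      if (!is.null(gene_table)) {
        ann <- annotate_windows(win, gene_table, hits)
        if (nrow(ann) > 0) {
          genes_all[[ph_name]] <- cbind(phenotype = ph_name, ann)
        }
      }
      bins <- bin_by_sd(y[keep_y], sd_mult = config$sd_mult)
      cg <- compute_cgrs(geno_pruned[keep_y, , drop = FALSE], rec, hits$id)
      wg <- compute_wgrs(geno_pruned[keep_y, , drop = FALSE], rec, hits$id)
      grs_rows[[ph_name]] <- data.frame(phenotype = ph_name,
                                        id = samples$id[keep_y],
                                        bin = as.character(bins$label),
                                        cgrs = cg, wgrs = wg,
                                        stringsAsFactors = FALSE)
    } else {
      note(ph_name, ": no variants below the reporting cut-off; ",
           "windows and risk scores skipped")
    }
  }
  artifacts <- c(artifacts, tsv(do.call(rbind, h2_rows), "heritability.tsv"))
  if (length(windows_all) > 0) {
    artifacts <- c(artifacts,
                   tsv(do.call(rbind, windows_all), "gene_windows.tsv"))
  }
  if (length(genes_all) > 0) {
    artifacts <- c(artifacts,
                   tsv(do.call(rbind, genes_all), "candidate_genes.tsv"))
  }
  if (length(grs_rows) > 0) {
    artifacts <- c(artifacts, tsv(do.call(rbind, grs_rows), "grs.tsv"))
  }

  manifest <- list(parameters = config[setdiff(names(config),
                                               c("sim", "out_dir"))],
                   sim_seed = if (!is.null(config$sim)) config$sim$seed,
                   qc = unclass(report),
                   log = log_lines,
                   artifacts = as.list(tools::md5sum(
                     file.path(config$out_dir, artifacts))))
  names(manifest$artifacts) <- artifacts
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
  invisible(manifest)
}
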