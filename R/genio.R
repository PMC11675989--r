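#' Write genotypes as a PLINK 1 binary triplet
#'
#' Writes the SNP-major .bed 2-bit encoding (magic bytes 0x6c 0x1b, mode
#' 0x01) with the companion 6-column .bim and .fam files. Dosages are counts
#' of the A1 (minor) allele: 2 -> 00, missing -> 01, 1 -> 10, 0 -> 11,
#' packed low-bits-first, four samples per byte.
#'
#' @param geno Samples x variants dosage matrix (0/1/2/NA), minor-allele
#'   oriented, with sample ids as rownames and variant ids as colnames.
#' @param prefix Output path prefix; \code{.bed/.bim/.fam} are appended.
#' @param variants Optional variant table (id, chrom, pos, allele_minor,
#'   allele_major); defaults are synthesized from colnames.
#' @param samples Optional sample table (id, sex); defaults from rownames.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(geno, prefix, variants = NULL, samples = NULL) {
  n <- nrow(geno)
  m <- ncol(geno)
  if (is.null(variants)) {
    variants <- data.frame(id = colnames(geno), chrom = "1",
                           pos = seq_len(m), allele_minor = "A",
                           allele_major = "B", stringsAsFactors = FALSE)
  }
  if (is.null(samples)) {
    samples <- data.frame(id = rownames(geno), sex = "F",
                          stringsAsFactors = FALSE)
  }
  stopifnot(nrow(variants) == m, nrow(samples) == n)

  bim <- data.frame(chrom = variants$chrom, id = variants$id, cm = 0,
                    pos = variants$pos, a1 = variants$allele_minor,
                    a2 = variants$allele_major)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = samples$id, iid = samples$id, pid = 0, mid = 0,
                    sex = ifelse(!is.null(samples$sex) & samples$sex == "M",
                                 1L, 2L),
                    pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  # dosage -> 2-bit code: 2->0(00), NA->1(01), 1->2(10), 0->3(11)
  code <- matrix(3L, n, m)
  code[geno == 2L] <- 0L
  code[geno == 1L] <- 2L
  code[is.na(geno)] <- 1L
  bpv <- ceiling(n / 4)
  pad <- bpv * 4L - n
  if (pad > 0) {
    code <- rbind(code, matrix(0L, pad, m))
  }
  shifted <- code * rep(c(1L, 4L, 16L, 64L), bpv)
  bytes <- rowsum(shifted, rep(seq_len(bpv), each = 4L))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Read a PLINK 1 binary triplet
#'
#' Decodes the SNP-major 2-bit .bed encoding into a samples x variants
#' minor-allele dosage matrix, preserving missing calls as \code{NA}. The A1
#' column of the .bim is taken as the minor allele (PLINK 1 convention);
#' observed frequencies are recomputed and recorded in the variant table.
#'
#' @param bed_path,bim_path,fam_path Paths to the three files; \code{bim_path}
#'   and \code{fam_path} default to the .bed path with swapped extensions.
#' @return A list with \code{geno}, \code{variants}, \code{samples}.
#' @export
read_plink <- function(bed_path,
                       bim_path = sub("\\.bed$", ".bim", bed_path),
                       fam_path = sub("\\.bed$", ".fam", bed_path)) {
  for (f in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  bim <- utils::read.table(bim_path, header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "character", "character"))
  fam <- utils::read.table(fam_path, header = FALSE,
                           col.names = c("fid", "iid", "pid", "mid",
                                         "sex", "pheno"),
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "integer", "numeric"))
  n <- nrow(fam)
  m <- nrow(bim)
  bpv <- ceiling(n / 4)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK 1 .bed file (magic bytes mismatch): ", bed_path)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major .bed files are supported: ", bed_path)
  }
  body <- raw[-(1:3)]
  if (length(body) != bpv * m) {
    stop(".bed payload size (", length(body), " bytes) does not match ",
         n, " samples x ", m, " variants from .fam/.bim")
  }
  ints <- as.integer(body)
  # unpack 4 two-bit codes per byte, low bits first
  codes <- rbind(ints %% 4L,
                 (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L,
                 (ints %/% 64L) %% 4L)
  codes <- matrix(as.vector(codes), nrow = bpv * 4L)[seq_len(n), ,
                                                     drop = FALSE]
  lookup <- c(2L, NA_integer_, 1L, 0L)  # code 0,1,2,3 -> A1 dosage
  geno <- matrix(lookup[codes + 1L], n, m)
  rownames(geno) <- fam$iid
  colnames(geno) <- bim$id

  freq <- colMeans(geno, na.rm = TRUE) / 2
  variants <- data.frame(id = bim$id, chrom = bim$chrom, pos = bim$pos,
                         allele_minor = bim$a1, allele_major = bim$a2,
                         maf = pmin(freq, 1 - freq),
                         call_rate = colMeans(!is.na(geno)),
                         polymorphic = apply(geno, 2, function(x) {
                           length(unique(x[!is.na(x)])) > 1L
                         }),
                         indel = FALSE,
                         stringsAsFactors = FALSE)
  samples <- data.frame(id = fam$iid,
                        sex = ifelse(fam$sex == 1L, "M",
                                     ifelse(fam$sex == 2L, "F", NA)),
                        stringsAsFactors = FALSE)
  list(geno = geno, variants = variants, samples = samples)
}

.autosome_labels <- function(n_chromosomes = 38) as.character(seq_len(n_chromosomes))

#' Category filter: autosomal, polymorphic, non-indel variants
#'
#' First removal stage of marker QC: drops variants on X/Y/MT or unmapped
#' contigs, then monomorphic variants and indels among the autosomal
#' remainder. Used on pre-QC manifests where only category flags are known.
#'
#' @param variants Variant table with \code{chrom}, \code{polymorphic},
#'   \code{indel} columns.
#' @param n_chromosomes Number of autosome labels considered valid.
#' @return List: \code{variants} (retained rows), \code{n_removed_nonautosomal},
#'   \code{n_removed_mono_or_indel}.
#' @export
category_filter <- function(variants, n_chromosomes = 38) {
  auto <- variants$chrom %in% .autosome_labels(n_chromosomes)
  kept <- variants[auto, , drop = FALSE]
  ok <- kept$polymorphic & !kept$indel
  list(variants = kept[ok, , drop = FALSE],
       n_removed_nonautosomal = sum(!auto),
       n_removed_mono_or_indel = sum(!ok))
}

#' Marker quality control
#'
#' Applies, in order: the autosomal/polymorphic/non-indel category filter,
#' then a strict minor-allele-frequency filter (retain MAF > \code{maf_min}),
#' then a strict call-rate filter (retain call rate > \code{call_rate_min}).
#' Each variant is accounted for exactly once, in removal order.
#'
#' @param geno Dosage matrix (may contain \code{NA}).
#' @param variants Aligned variant table.
#' @param maf_min MAF threshold (strict inequality), default 0.05.
#' @param call_rate_min Call-rate threshold (strict), default 0.90.
#' @param autosomes_only Apply the category filter first (default TRUE).
#' @param n_chromosomes Number of autosome labels.
#' @return List: filtered \code{geno}, \code{variants}, and \code{report}
#'   (class \code{qc_report}) with the removal accounting.
#' @export
qc_filter <- function(geno, variants, maf_min = 0.05, call_rate_min = 0.90,
                      autosomes_only = TRUE, n_chromosomes = 38) {
  stopifnot(ncol(geno) == nrow(variants))
  n_input <- nrow(variants)
  keep <- rep(TRUE, n_input)

  n_nonauto <- 0L
  n_mono <- 0L
  if (autosomes_only) {
    auto <- variants$chrom %in% .autosome_labels(n_chromosomes)
    n_nonauto <- sum(!auto)
    keep <- keep & auto
    poly_ok <- variants$polymorphic & !variants$indel
    n_mono <- sum(keep & !poly_ok)
    keep <- keep & poly_ok
  }

  freq <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0
  maf_ok <- maf > maf_min
  n_maf <- sum(keep & !maf_ok)
  keep <- keep & maf_ok

  cr <- colMeans(!is.na(geno))
  cr_ok <- cr > call_rate_min
  n_cr <- sum(keep & !cr_ok)
  keep <- keep & cr_ok

  report <- structure(list(n_input = n_input,
                           n_removed_nonautosomal = n_nonauto,
                           n_removed_mono_or_indel = n_mono,
                           n_removed_maf = n_maf,
                           n_removed_callrate = n_cr,
                           n_removed_prune = 0L,
                           n_retained = sum(keep)),
                      class = "qc_report")
  if (sum(keep) == 0L) {
    warning("quality control removed every variant")
  }
  out_variants <- variants[keep, , drop = FALSE]
  out_variants$maf <- maf[keep]
  out_variants$call_rate <- cr[keep]
  list(geno = geno[, keep, drop = FALSE], variants = out_variants,
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker QC report\n")
  cat(sprintf("  input variants:            %d\n", x$n_input))
  cat(sprintf("  removed non-autosomal:     %d\n", x$n_removed_nonautosomal))
  cat(sprintf("  removed monomorphic/indel: %d\n", x$n_removed_mono_or_indel))
  cat(sprintf("  removed MAF filter:        %d\n", x$n_removed_maf))
  cat(sprintf("  removed call-rate filter:  %d\n", x$n_removed_callrate))
  cat(sprintf("  removed LD pruning:        %d\n", x$n_removed_prune))
  cat(sprintf("  retained:                  %d\n", x$n_retained))
  invisible(x)
}

#' Fill sporadic missing genotypes with the per-variant mode
#'
#' Replaces each missing call by the most frequent observed dosage at that
#' variant (ties broken toward the smaller dosage). Non-missing entries are
#' never altered.
#'
#' @param geno Dosage matrix.
#' @return The completed matrix.
#' @export
fill_sporadic_missing <- function(geno) {
  if (!anyNA(geno)) return(geno)
  all_missing <- colSums(!is.na(geno)) == 0L
  if (any(all_missing)) {
    stop("variant(s) with all genotypes missing: ",
         paste(colnames(geno)[all_missing], collapse = ", "))
  }
  for (j in which(colSums(is.na(geno)) > 0L)) {
    x <- geno[, j]
    tab <- tabulate(x[!is.na(x)] + 1L, nbins = 3L)
    geno[is.na(x), j] <- which.max(tab) - 1L
  }
  geno
}

#' Sliding-window LD pruning
#'
#' Mirrors the behavior of window-based pairwise pruning (window size in
#' variants, step in variants, squared-correlation cut-off): within each
#' window, while any retained pair of variants has squared Pearson
#' correlation of dosages above \code{r2_max}, the member with the smaller
#' MAF is removed (on equal MAF, the later variant). Windows are processed
#' chromosome by chromosome in position order.
#'
#' @param geno Complete dosage matrix (run \code{fill_sporadic_missing}
#'   first).
#' @param variants Aligned variant table (chrom, pos used for ordering).
#' @param window Window size in variants (default 200).
#' @param step Window step in variants (default 50).
#' @param r2_max Squared-correlation threshold (default 0.6).
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(geno, variants = NULL, window = 200, step = 50,
                     r2_max = 0.6) {
  if (window < 2) stop("pruning window must span at least 2 variants")
  if (anyNA(geno)) stop("ld_prune requires complete genotypes")
  m <- ncol(geno)
  ids <- colnames(geno)
  if (is.null(variants)) {
    variants <- data.frame(id = ids, chrom = "1", pos = seq_len(m))
  }
  ord <- order(.chrom_rank(variants$chrom), variants$pos)
  freq <- colMeans(geno) / 2
  maf <- pmin(freq, 1 - freq)

  removed <- rep(FALSE, m)
  for (chr in unique(variants$chrom[ord])) {
    idx <- ord[variants$chrom[ord] == chr]
    start <- 1L
    repeat {
      stop_at <- min(start + window - 1L, length(idx))
      win <- idx[start:stop_at]
      win <- win[!removed[win]]
      if (length(win) >= 2L) {
        cc <- suppressWarnings(stats::cor(geno[, win, drop = FALSE]))
        r2 <- cc^2
        r2[is.na(r2)] <- 0
        diag(r2) <- 0
        alive <- rep(TRUE, length(win))
        repeat {
          r2a <- r2
          r2a[!alive, ] <- 0
          r2a[, !alive] <- 0
          mx <- which.max(r2a)
          if (r2a[mx] <= r2_max) break
          pair <- c((mx - 1L) %% length(win) + 1L,
                    (mx - 1L) %/% length(win) + 1L)
          mafs <- maf[win[pair]]
          drop_local <- if (mafs[1] < mafs[2]) pair[1]
                        else if (mafs[2] < mafs[1]) pair[2]
                        else pair[which.max(win[pair])]
          alive[drop_local] <- FALSE
        }
        removed[win[!alive]] <- TRUE
      }
      if (stop_at >= length(idx)) break
      start <- start + step
    }
  }
  ids[!removed]
}

# numeric-aware chromosome ordering (1..38 numerically, then X/Y/MT/un)
.chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  rank_extra <- match(chrom, c("X", "Y", "MT", "un"))
  ifelse(!is.na(num), num, 1000 + ifelse(is.na(rank_extra), 99, rank_extra))
}
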