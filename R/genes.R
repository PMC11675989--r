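#' Build flanking windows around associated variants
#'
#' Each hit gets a window of \code{flank} bp up- and downstream — 1-based
#' inclusive \[pos - flank + 1, pos + flank\], total width 2 x flank,
#' clamped at position 1. Same-chromosome hits separated by at most
#' \code{merge_gap} are collapsed into one window running from
#' min(pos) - flank + 1 to max(pos) + flank.
#'
#' @param hits Data frame with \code{id}, \code{chrom}, \code{pos}.
#' @param flank Flank size in bp (default 500 kb).
#' @param merge_gap Maximum hit-to-hit distance merged into one window
#'   (default 1 Mb).
#' @return Data frame: chrom, start, end, n_members, members
#'   (comma-separated ids in position order).
#' @export
build_windows <- function(hits, flank = 5e5, merge_gap = 1e6) {
  if (nrow(hits) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_members = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  }
  hits <- hits[order(.chrom_rank(hits$chrom), hits$pos), ]
  gr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$pos, hits$pos))
  # hits at distance d have a gap of d - 1; merge when d <= merge_gap
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap)
  ov <- GenomicRanges::findOverlaps(gr, red)
  members <- split(hits$id[S4Vectors::queryHits(ov)],
                   S4Vectors::subjectHits(ov))
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = pmax(GenomicRanges::start(red) - flank + 1, 1),
             end = GenomicRanges::end(red) + flank,
             n_members = lengths(members),
             members = vapply(members, paste, character(1), collapse = ","),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Annotate windows with overlapping genes
#'
#' Reports every gene whose interval overlaps a window. For each gene the
#' nearest member SNP is identified; the distance is 0 when that SNP lies
#' inside the gene (relation \code{"inside"}), otherwise the base-pair
#' distance from the SNP to the nearer gene edge, with the relation
#' describing the gene's position relative to the SNP (strandless:
#' \code{"upstream"} = lower coordinate, \code{"downstream"} = higher).
#'
#' @param windows Output of \code{\link{build_windows}}.
#' @param genes Annotation data frame: chrom, start, end, name (1-based
#'   inclusive; convert BED half-open input before calling).
#' @param hits The hit table used to build the windows (id, chrom, pos),
#'   for SNP-to-gene distances.
#' @return Data frame: chrom, window_start, window_end, gene, gene_start,
#'   gene_end, snp_id, snp_pos, distance_bp, relation.
#' @export
annotate_windows <- function(windows, genes, hits) {
  out <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    g <- genes[genes$chrom == w$chrom &
                 genes$end >= w$start & genes$start <= w$end, , drop = FALSE]
    if (nrow(g) == 0) next
    mem_ids <- strsplit(w$members, ",")[[1]]
    mem <- hits[hits$id %in% mem_ids, , drop = FALSE]
    for (k in seq_len(nrow(g))) {
      dists <- ifelse(mem$pos >= g$start[k] & mem$pos <= g$end[k], 0,
                      pmin(abs(mem$pos - g$start[k]),
                           abs(mem$pos - g$end[k])))
      best <- which.min(dists)
      rel <- if (dists[best] == 0) "inside"
             else if (g$end[k] < mem$pos[best]) "upstream"
             else "downstream"
      out[[length(out) + 1L]] <-
        data.frame(chrom = w$chrom, window_start = w$start,
                   window_end = w$end, gene = g$name[k],
                   gene_start = g$start[k], gene_end = g$end[k],
                   snp_id = mem$id[best], snp_pos = mem$pos[best],
                   distance_bp = dists[best], relation = rel,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), window_start = numeric(0),
                      window_end = numeric(0), gene = character(0),
                      gene_start = numeric(0), gene_end = numeric(0),
                      snp_id = character(0), snp_pos = numeric(0),
                      distance_bp = numeric(0), relation = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read a gene annotation table
#'
#' Accepts a 4-column TSV (chrom, start, end, name; 1-based inclusive) or a
#' BED file (0-based half-open, detected by a \code{.bed} extension and
#' converted to 1-based inclusive at the boundary).
#'
#' @param path Annotation file path.
#' @return Data frame: chrom, start, end, name.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "name"),
                          colClasses = c("character", "numeric", "numeric",
                                         "character"))
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    df$start <- df$start + 1
  }
  df
}
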