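#' Bin dogs by phenotype extremity
#'
#' Dogs at least \code{sd_mult} standard deviations above the mean adjusted
#' phenotype are labelled \code{less_fearful} (higher score = more confident
#' response), those at least \code{sd_mult} SD below are
#' \code{more_fearful}, and the rest \code{intermediate}. The population
#' form of the SD (denominator n) is used and boundary values count as
#' extreme, so a symmetric two-point phenotype has no intermediate dogs;
#' for continuous phenotypes the convention is immaterial.
#'
#' @param pheno Adjusted phenotype vector.
#' @param sd_mult SD multiplier (default 1).
#' @return Object of class \code{fear_bin}: factor \code{label}, the cut
#'   points, and group sizes.
#' @export
bin_by_sd <- function(pheno, sd_mult = 1.0) {
  pheno <- as.numeric(pheno)
  n <- length(pheno)
  if (n < 3) stop("need at least 3 dogs to bin")
  mu <- mean(pheno)
  s <- sqrt(mean((pheno - mu)^2))
  if (s == 0) stop("phenotype has zero standard deviation; bins undefined")
  label <- factor(ifelse(pheno >= mu + sd_mult * s, "less_fearful",
                         ifelse(pheno <= mu - sd_mult * s, "more_fearful",
                                "intermediate")),
                  levels = c("more_fearful", "intermediate", "less_fearful"))
  structure(list(label = label, mean = mu, sd = s, sd_mult = sd_mult,
                 sizes = table(label)),
            class = "fear_bin")
}

.check_grs_inputs <- function(geno, effects, snp_set) {
  missing_eff <- setdiff(snp_set, effects$id)
  if (length(missing_eff) > 0) {
    stop("no effect estimate for SNP(s): ",
         paste(missing_eff, collapse = ", "))
  }
  missing_geno <- setdiff(snp_set, colnames(geno))
  if (length(missing_geno) > 0) {
    stop("no genotypes for SNP(s): ", paste(missing_geno, collapse = ", "))
  }
  G <- geno[, snp_set, drop = FALSE]
  if (anyNA(G)) stop("genotypes must be complete for risk scoring")
  G
}

#' Count-based genetic risk score
#'
#' The minor allele (B) is the risk allele: BB counts 2, AB counts 1, AA
#' counts 0. For a SNP with a negative estimated effect the coding is
#' reversed (count = 2 - dosage), so that risk-allele homozygotes of a
#' protective marker contribute 0; counts stay in {0, 1, 2} and the cGRS is
#' their sum over the SNP set.
#'
#' @param geno Complete dosage matrix.
#' @param effects Data frame with \code{id} and \code{beta} (e.g. an
#'   \code{\link{lmm_assoc}} result).
#' @param snp_set Variant ids to score over.
#' @return Named integer vector, one cGRS per dog.
#' @export
compute_cgrs <- function(geno, effects, snp_set) {
  G <- .check_grs_inputs(geno, effects, snp_set)
  beta <- effects$beta[match(snp_set, effects$id)]
  neg <- !is.na(beta) & beta < 0
  G[, neg] <- 2L - G[, neg]
  out <- as.integer(rowSums(G))
  names(out) <- rownames(geno)
  out
}

#' Effect-weighted genetic risk score
#'
#' wGRS = sum_j beta_j x dosage_j over the SNP set: each minor-allele count
#' is weighted by its signed estimated effect, so protective (negative-
#' effect) markers contribute negatively.
#'
#' @inheritParams compute_cgrs
#' @return Named numeric vector, one wGRS per dog.
#' @export
compute_wgrs <- function(geno, effects, snp_set) {
  G <- .check_grs_inputs(geno, effects, snp_set)
  beta <- effects$beta[match(snp_set, effects$id)]
  out <- drop(G %*% beta)
  names(out) <- rownames(geno)
  out
}

#' Compare risk scores across fear-extremity groups
#'
#' One-way linear-model F-test across the (non-empty) groups, with pairwise
#' comparisons adjusted by the Tukey-Kramer method (studentized-range based,
#' valid for unequal group sizes). Also reports mean, SD, median, and range
#' per group and kernel-density curves for plotting. Because the effect
#' estimates are typically fitted in the same sample, the comparison is
#' descriptive, not predictive, and the output labels it so.
#'
#' @param scores Per-dog risk scores (cGRS or wGRS).
#' @param bins A \code{\link{bin_by_sd}} result (or a factor of group
#'   labels).
#' @param mode \code{"two_group"} (extreme bins only) or
#'   \code{"three_group"} (include intermediate dogs).
#' @return Object of class \code{grs_comparison}: \code{group_summary},
#'   \code{anova_p}, \code{tukey} (pairwise table), \code{density}
#'   (score grid x group), \code{in_sample} flag.
#' @export
compare_grs_groups <- function(scores, bins,
                               mode = c("two_group", "three_group")) {
  mode <- match.arg(mode)
  label <- if (inherits(bins, "fear_bin")) bins$label else factor(bins)
  stopifnot(length(scores) == length(label))
  keep_levels <- levels(label)
  if (mode == "two_group") {
    keep_levels <- setdiff(keep_levels, "intermediate")
  }
  keep <- label %in% keep_levels
  g <- droplevels(label[keep])
  x <- scores[keep]
  small <- names(which(table(g) < 2))
  if (length(small) > 0) {
    warning("dropping group(s) with fewer than 2 dogs: ",
            paste(small, collapse = ", "))
    keep2 <- !(g %in% small)
    g <- droplevels(g[keep2])
    x <- x[keep2]
  }
  if (nlevels(g) < 2) stop("need at least 2 non-empty groups")

  fit <- stats::aov(x ~ g)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(tk),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      row.names = NULL, stringsAsFactors = FALSE)

  group_summary <- do.call(rbind, lapply(levels(g), function(lev) {
    xs <- x[g == lev]
    data.frame(group = lev, n = length(xs), mean = mean(xs),
               sd = stats::sd(xs), median = stats::median(xs),
               min = min(xs), max = max(xs), stringsAsFactors = FALSE)
  }))

  grid <- seq(min(x), max(x), length.out = 200)
  if (min(x) == max(x)) grid <- min(x) + seq(-1, 1, length.out = 200)
  dens <- do.call(rbind, lapply(levels(g), function(lev) {
    d <- stats::density(x[g == lev], from = min(grid), to = max(grid),
                        n = length(grid))
    data.frame(group = lev, score = d$x, density = d$y,
               stringsAsFactors = FALSE)
  }))

  structure(list(group_summary = group_summary, anova_p = anova_p,
                 tukey = tukey, density = dens, in_sample = TRUE),
            class = "grs_comparison")
}

#' @export
print.grs_comparison <- function(x, ...) {
  cat("Risk-score group comparison (descriptive; in-sample effects)\n")
  print(x$group_summary, digits = 4)
  cat(sprintf("one-way F-test p = %.4g\n", x$anova_p))
  print(x$tukey, digits = 4)
  invisible(x)
}
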