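#' Kinship-corrected linear mixed-model association
#'
#' Per-SNP model y = W alpha + x beta + u + epsilon with
#' u ~ N(0, K sigma_g^2), epsilon ~ N(0, I sigma_e^2). K is eigendecomposed
#' once; in the rotated space the covariance is diagonal in
#' h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2), which is profiled by 1-D
#' optimization of the restricted likelihood (a coarse log-spaced grid over
#' the variance ratio followed by Brent refinement). beta-hat and its
#' standard error come from generalized least squares in the rotated space;
#' the Wald p-value is P(chi^2_1 >= (beta/se)^2). \code{mode = "null"}
#' estimates the variance ratio once under the covariate-only model and
#' reuses it for every SNP (EMMAX-style); \code{mode = "exact"} re-profiles
#' per SNP.
#'
#' @param y Adjusted phenotype vector (complete).
#' @param geno Complete dosage matrix, sample-aligned with \code{y}.
#' @param K Kinship matrix (centered flavor).
#' @param W Covariate design matrix (default intercept only).
#' @param variants Optional variant table supplying id/chrom/pos/alleles;
#'   matched to \code{colnames(geno)}.
#' @param mode \code{"exact"} (per-SNP profiling, default) or \code{"null"}.
#' @param ratio Optional fixed variance ratio sigma_g^2/sigma_e^2; when
#'   given, no profiling is done (useful for oracle comparisons).
#' @return Data frame of class \code{assoc_result}: id, chrom, pos,
#'   allele_minor, allele_major, maf, beta, se, wald_p, sorted by
#'   (chrom, pos). Monomorphic variants get NA statistics; their count is
#'   attached as attribute \code{n_monomorphic}.
#' @export
lmm_assoc <- function(y, geno, K, W = NULL, variants = NULL,
                      mode = c("exact", "null"), ratio = NULL) {
  mode <- match.arg(mode)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(geno) == n, nrow(K) == n)
  if (anyNA(y)) stop("phenotype must be complete (align samples first)")
  if (anyNA(geno)) stop("genotypes must be complete (fill missing first)")
  if (is.null(W)) W <- matrix(1, n, 1)
  W <- as.matrix(W)

  eig <- eigen(unclass(K), symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  Wt <- crossprod(U, W)

  null_ratio <- if (!is.null(ratio)) ratio else .profile_ratio(d, yt, Wt)
  freq <- colMeans(geno) / 2
  maf <- pmin(freq, 1 - freq)
  mono <- apply(geno, 2, stats::sd) == 0

  m <- ncol(geno)
  beta <- se <- rep(NA_real_, m)
  Gt <- crossprod(U, geno)
  for (j in seq_len(m)) {
    if (mono[j]) next
    Xt <- cbind(Wt, Gt[, j])
    rj <- if (is.null(ratio) && mode == "exact") {
      .profile_ratio(d, yt, Xt)
    } else {
      null_ratio
    }
    fit <- .gls_fit(d, yt, Xt, rj)
    beta[j] <- fit$beta[ncol(Xt)]
    se[j] <- fit$se[ncol(Xt)]
  }
  wald_p <- stats::pchisq((beta / se)^2, df = 1, lower.tail = FALSE)

  ids <- colnames(geno)
  if (!is.null(variants)) {
    idx <- match(ids, variants$id)
    chrom <- variants$chrom[idx]
    pos <- variants$pos[idx]
    a1 <- variants$allele_minor[idx]
    a2 <- variants$allele_major[idx]
  } else {
    chrom <- rep("1", m)
    pos <- seq_len(m)
    a1 <- a2 <- rep(NA_character_, m)
  }
  out <- data.frame(id = ids, chrom = chrom, pos = pos,
                    allele_minor = a1, allele_major = a2,
                    maf = maf, beta = beta, se = se, wald_p = wald_p,
                    stringsAsFactors = FALSE)
  out <- out[order(.chrom_rank(out$chrom), out$pos), ]
  rownames(out) <- NULL
  if (any(mono)) {
    message(sum(mono), " monomorphic variant(s) skipped in association")
  }
  attr(out, "n_monomorphic") <- sum(mono)
  attr(out, "variance_ratio_null") <- null_ratio
  class(out) <- c("assoc_result", "data.frame")
  out
}

# restricted log-likelihood of the variance ratio, profiled over beta and
# total scale; d, yt, Xt live in the eigenspace of K
.reml_ratio_loglik <- function(log_ratio, d, yt, Xt) {
  r <- exp(log_ratio)
  v <- r * d + 1
  w <- 1 / v
  XtW <- Xt * w
  XtWX <- crossprod(Xt, XtW)
  R <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  beta <- backsolve(R, forwardsolve(t(R), crossprod(XtW, yt)))
  res <- yt - drop(Xt %*% beta)
  rss <- sum(w * res^2)
  n <- length(yt)
  p <- ncol(Xt)
  -0.5 * ((n - p) * log(rss) + sum(log(v)) + 2 * sum(log(diag(R))))
}

# maximize the profiled restricted likelihood over log(sigma_g^2/sigma_e^2)
# on a coarse grid spanning 1e-5..1e5, then refine with Brent
.profile_ratio <- function(d, yt, Xt) {
  grid <- seq(log(1e-5), log(1e5), length.out = 41)
  ll <- vapply(grid, .reml_ratio_loglik, numeric(1), d = d, yt = yt, Xt = Xt)
  k <- which.max(ll)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(.reml_ratio_loglik, c(lo, hi), d = d, yt = yt,
                         Xt = Xt, maximum = TRUE, tol = 1e-8)
  exp(opt$maximum)
}

# GLS at a fixed variance ratio; returns coefficients and standard errors
.gls_fit <- function(d, yt, Xt, ratio) {
  v <- ratio * d + 1
  w <- 1 / v
  XtW <- Xt * w
  XtWX <- crossprod(Xt, XtW)
  XtWX_inv <- solve(XtWX)
  beta <- drop(XtWX_inv %*% crossprod(XtW, yt))
  res <- yt - drop(Xt %*% beta)
  sigma2 <- sum(w * res^2) / (length(yt) - ncol(Xt))
  list(beta = beta, se = sqrt(pmax(diag(XtWX_inv) * sigma2, 0)))
}

#' Genome-wide significance thresholds
#'
#' Bonferroni threshold alpha / m and suggestive threshold 1 / m for m
#' tested markers, both also reported on the -log10 scale, together with a
#' configurable reporting cut-off used for tabulating top associations.
#'
#' @param n_variants Number of markers tested.
#' @param alpha Family-wise error rate for the Bonferroni bound.
#' @param reporting_p Presentation cut-off (default 4e-5).
#' @return List of class \code{threshold_set}.
#' @export
significance_thresholds <- function(n_variants, alpha = 0.05,
                                    reporting_p = 4e-5) {
  if (n_variants < 1) stop("n_variants must be at least 1")
  structure(list(n_variants = n_variants,
                 bonferroni_p = alpha / n_variants,
                 suggestive_p = 1 / n_variants,
                 reporting_p = reporting_p,
                 bonferroni_log10 = -log10(alpha / n_variants),
                 suggestive_log10 = -log10(1 / n_variants),
                 reporting_log10 = -log10(reporting_p)),
            class = "threshold_set")
}

#' Genomic inflation factor (lambda_gc)
#'
#' lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1) over the Wald-test
#' p-values; values near 1 indicate well-controlled stratification.
#'
#' @param pvals Vector of p-values in (0, 1\]; NAs are dropped.
#' @return lambda_gc.
#' @export
genomic_inflation <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0) stop("no p-values supplied")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  stats::median(stats::qchisq(1 - pvals, df = 1)) /
    stats::qchisq(0.5, df = 1)
}

#' Plot-ready Manhattan and QQ tables
#'
#' Adds a cumulative genome coordinate (chromosomes laid end to end in
#' karyotype order) and -log10 p to each association record, and builds the
#' expected-vs-observed quantile table for a QQ plot, with expected
#' quantiles -log10((i - 0.5) / m).
#'
#' @param records An \code{\link{lmm_assoc}} result (or any data frame with
#'   chrom, pos, wald_p).
#' @param thresholds Optional \code{\link{significance_thresholds}} result,
#'   echoed into the output.
#' @return List: \code{manhattan} (id, chrom, pos, cum_pos, neglog10_p),
#'   \code{qq} (expected, observed), \code{chrom_offsets},
#'   \code{thresholds}.
#' @export
manhattan_qq_data <- function(records, thresholds = NULL) {
  if (nrow(records) == 0) stop("no association records")
  rec <- records[order(.chrom_rank(records$chrom), records$pos), ]
  chroms <- unique(rec$chrom)
  lens <- vapply(chroms, function(ch) max(rec$pos[rec$chrom == ch]),
                 numeric(1))
  offsets <- stats::setNames(c(0, cumsum(lens))[seq_along(chroms)], chroms)
  man <- data.frame(id = rec$id, chrom = rec$chrom, pos = rec$pos,
                    cum_pos = rec$pos + offsets[rec$chrom],
                    neglog10_p = -log10(rec$wald_p),
                    stringsAsFactors = FALSE)
  p <- sort(rec$wald_p[!is.na(rec$wald_p)])
  m <- length(p)
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = sort(-log10(p), decreasing = TRUE))
  list(manhattan = man, qq = qq, chrom_offsets = offsets,
       thresholds = thresholds)
}
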