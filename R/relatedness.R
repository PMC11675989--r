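#' Genomic relationship matrix
#'
#' Centered flavor: K = (1/m) sum_i (x_i - xbar_i)(x_i - xbar_i)' over
#' markers. Variance-standardized flavor: each centered marker is
#' additionally divided by its observed dosage standard deviation before the
#' outer product; monomorphic markers (zero variance) are skipped and
#' counted.
#'
#' @param geno Complete dosage matrix (samples x variants).
#' @param flavor \code{"centered"} or \code{"variance_standardized"}.
#' @return A matrix of class \code{kinship} with attributes \code{flavor}
#'   and \code{n_markers_used}.
#' @export
compute_grm <- function(geno, flavor = c("centered", "variance_standardized")) {
  flavor <- match.arg(flavor)
  if (anyNA(geno)) stop("compute_grm requires complete genotypes")
  if (ncol(geno) < 1) stop("need at least 1 marker")
  Z <- scale(geno, center = TRUE, scale = FALSE)
  if (flavor == "variance_standardized") {
    sds <- apply(geno, 2, stats::sd)
    mono <- sds == 0
    if (any(mono)) {
      message(sum(mono), " monomorphic marker(s) skipped in ",
              "variance-standardized GRM")
      Z <- Z[, !mono, drop = FALSE]
      sds <- sds[!mono]
    }
    if (ncol(Z) < 1) stop("no polymorphic markers left")
    Z <- sweep(Z, 2, sds, "/")
  }
  m_used <- ncol(Z)
  K <- tcrossprod(Z) / m_used
  structure(K, flavor = flavor, n_markers_used = m_used, class = "kinship")
}

#' Principal components of a kinship matrix
#'
#' Top-k eigenvectors scaled by the square roots of their eigenvalues, with
#' a deterministic sign convention (the largest-magnitude entry of each
#' component is positive).
#'
#' @param K Symmetric kinship matrix.
#' @param k Number of components (default 2).
#' @return n x k coordinate matrix; eigenvalues as attribute
#'   \code{eigenvalues}.
#' @export
grm_pcs <- function(K, k = 2) {
  eig <- eigen(unclass(K), symmetric = TRUE)
  rank <- sum(eig$values > max(eig$values) * 1e-10)
  if (k > rank) stop("k = ", k, " exceeds the numerical rank (", rank, ")")
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (U[which.max(abs(U[, j])), j] < 0) U[, j] <- -U[, j]
  }
  coords <- U %*% diag(sqrt(eig$values[seq_len(k)]), k)
  rownames(coords) <- rownames(K)
  colnames(coords) <- paste0("PC", seq_len(k))
  attr(coords, "eigenvalues") <- eig$values[seq_len(k)]
  coords
}

#' Method-of-moments inbreeding coefficients (excess homozygosity)
#'
#' For each individual, F = (O_hom - E_hom) / (L - E_hom), where O_hom is
#' the observed homozygote count over the individual's non-missing markers,
#' L the number of such markers, and E_hom the expected homozygote count
#' under Hardy-Weinberg using small-sample-corrected within-group allele
#' frequencies: E_hom = sum_i [1 - 2 f_i (1 - f_i) n_i / (n_i - 1)] with f_i
#' the within-group minor-allele frequency and n_i the observed allele count
#' at marker i.
#'
#' @param geno Dosage matrix (missing allowed); rows restricted to
#'   \code{group} if given.
#' @param group Optional vector of sample ids or row indices defining the
#'   group within which frequencies are computed.
#' @return Object of class \code{ibc_result}: data frame \code{ibc} (id,
#'   o_hom, e_hom, n_markers, f_hat) plus \code{n_markers_used}.
#' @export
compute_ibc <- function(geno, group = NULL) {
  if (!is.null(group)) {
    geno <- geno[group, , drop = FALSE]
  }
  n <- nrow(geno)
  if (n < 2) stop("inbreeding estimation needs a group of at least 2")
  obs <- !is.na(geno)
  n_allele <- 2 * colSums(obs)
  usable <- n_allele >= 4  # frequency correction needs >= 2 observed dogs
  geno <- geno[, usable, drop = FALSE]
  obs <- obs[, usable, drop = FALSE]
  n_allele <- n_allele[usable]
  f <- colSums(geno, na.rm = TRUE) / n_allele
  e_term <- 1 - 2 * f * (1 - f) * n_allele / (n_allele - 1)

  hom <- (geno == 0 | geno == 2)
  o_hom <- rowSums(hom, na.rm = TRUE)
  e_hom <- as.vector(obs %*% e_term)
  L <- rowSums(obs)
  f_hat <- (o_hom - e_hom) / (L - e_hom)

  structure(list(ibc = data.frame(id = rownames(geno),
                                  o_hom = o_hom, e_hom = e_hom,
                                  n_markers = L, f_hat = f_hat,
                                  row.names = NULL),
                 n_markers_used = ncol(geno)),
            class = "ibc_result")
}

.group_summary <- function(x) {
  if (inherits(x, "ibc_result")) x <- x$ibc$f_hat
  if (is.list(x) && all(c("mean", "variance", "n") %in% names(x))) {
    return(list(mean = x$mean, variance = x$variance, n = x$n))
  }
  x <- as.numeric(x)
  list(mean = mean(x), variance = stats::var(x), n = length(x))
}

#' Compare inbreeding coefficients between two populations
#'
#' Two-tailed F-test of equality of variances (ratio of the larger to the
#' smaller sample variance, doubled tail); if the variances differ at
#' \code{alpha}, a Welch t-test with Welch-Satterthwaite degrees of freedom
#' is used, otherwise a pooled-variance t-test. Accepts raw F-hat vectors,
#' \code{\link{compute_ibc}} results, or summary statistics
#' (\code{list(mean=, variance=, n=)}) so published group summaries can be
#' re-tested directly.
#'
#' @param a,b The two groups (vector, \code{ibc_result}, or summary list).
#' @param alpha Significance level of the variance F-test gate.
#' @return Object of class \code{breed_comparison}: group means/variances/n,
#'   \code{f_test_p}, \code{variances_unequal}, \code{t_statistic},
#'   \code{degrees_of_freedom}, \code{t_test_p} (two-tailed).
#' @export
compare_ibc_groups <- function(a, b, alpha = 0.05) {
  sa <- .group_summary(a)
  sb <- .group_summary(b)
  if (sa$n < 2 || sb$n < 2) stop("both groups need at least 2 individuals")
  if (sa$variance == 0 && sb$variance == 0) {
    stop("zero variance in both groups; comparison undefined")
  }
  v_big <- max(sa$variance, sb$variance)
  v_small <- min(sa$variance, sb$variance)
  df_big <- ifelse(sa$variance >= sb$variance, sa$n, sb$n) - 1
  df_small <- ifelse(sa$variance >= sb$variance, sb$n, sa$n) - 1
  f_stat <- v_big / max(v_small, .Machine$double.xmin)
  f_p <- min(1, 2 * stats::pf(f_stat, df_big, df_small, lower.tail = FALSE))
  unequal <- f_p < alpha

  if (unequal) {
    se2 <- sa$variance / sa$n + sb$variance / sb$n
    t_stat <- (sa$mean - sb$mean) / sqrt(se2)
    df <- se2^2 / ((sa$variance / sa$n)^2 / (sa$n - 1) +
                     (sb$variance / sb$n)^2 / (sb$n - 1))
  } else {
    sp2 <- ((sa$n - 1) * sa$variance + (sb$n - 1) * sb$variance) /
      (sa$n + sb$n - 2)
    t_stat <- (sa$mean - sb$mean) / sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    df <- sa$n + sb$n - 2
  }
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)

  structure(list(mean_a = sa$mean, var_a = sa$variance, n_a = sa$n,
                 mean_b = sb$mean, var_b = sb$variance, n_b = sb$n,
                 f_statistic = f_stat, f_test_p = f_p,
                 variances_unequal = unequal,
                 t_statistic = t_stat, degrees_of_freedom = df,
                 t_test_p = p, alpha = alpha),
            class = "breed_comparison")
}

#' @export
print.breed_comparison <- function(x, ...) {
  cat(sprintf("Group A: mean %.6f (var %.6f), n = %d\n",
              x$mean_a, x$var_a, x$n_a))
  cat(sprintf("Group B: mean %.6f (var %.6f), n = %d\n",
              x$mean_b, x$var_b, x$n_b))
  cat(sprintf("F-test p = %.4g -> %s t-test\n", x$f_test_p,
              if (x$variances_unequal) "Welch" else "pooled"))
  cat(sprintf("t = %.4f, df = %.2f, two-tailed p = %.6g\n",
              x$t_statistic, x$degrees_of_freedom, x$t_test_p))
  invisible(x)
}

#' Published breed-level inbreeding summaries
#'
#' Mean, variance, and sample size of SNP-based inbreeding coefficients for
#' 16 dog breeds, each observed in two populations: a breed-background
#' reference population (group A) and a commercial-breeding cohort
#' (group B). These published group summaries serve as fixtures for the
#' two-population comparison: feeding each row through
#' \code{\link{compare_ibc_groups}} reproduces the published two-tailed
#' p-values and unequal-variance flags.
#'
#' @return Data frame: breed, mean_bg, var_bg, n_bg, mean_cb, var_cb, n_cb.
#' @export
breed_ibc_summaries <- function() {
  data.frame(
    breed = c("American Cocker Spaniel", "Australian Shepherd",
              "Bichon Frise", "Bullmastiff",
              "Cavalier King Charles Spaniel", "French Bulldog",
              "Golden Retriever", "Great Dane", "Labrador Retriever",
              "Miniature Schnauzer", "Pomeranian", "Shetland Sheepdog",
              "Shih Tzu", "Siberian Husky", "Toy Poodle",
              "Yorkshire Terrier"),
    mean_bg = c(0.072092, 0.05939, 0.045651, 0.030963, 0.045081, 0.020821,
                0.055963, 0.049074, 0.041517, 0.063033, 0.039109, 0.105334,
                0.051114, 0.049934, 0.041009, 0.052383),
    var_bg = c(0.008133, 0.009972, 0.006584, 0.007931, 0.007391, 0.002795,
               0.010229, 0.013713, 0.006761, 0.024241, 0.007194, 0.017431,
               0.012371, 0.007221, 0.0091, 0.014324),
    n_bg = c(16L, 277L, 101L, 43L, 254L, 65L, 471L, 97L, 1424L, 364L, 51L,
             60L, 93L, 131L, 30L, 371L),
    mean_cb = c(-0.03392, 0.005118, -0.02843, -0.00998, 0.019761, -0.00506,
                0.003179, -0.02324, 0.085459, -0.08533, 0.007014, -0.19236,
                -0.014, 0.010516, -0.02076, -0.00091),
    var_cb = c(0.004166, 0.004865, 0.008112, 0.002771, 0.00693, 0.007024,
               0.006466, 0.001514, 0.007521, 0.005618, 0.006416, 0.016604,
               0.004515, 0.004038, 0.001406, 0.003964),
    n_cb = c(34L, 14L, 36L, 15L, 44L, 22L, 22L, 14L, 25L, 20L, 15L, 16L,
             49L, 24L, 22L, 17L),
    stringsAsFactors = FALSE)
}

#' Run the two-population comparison over a breed summary table
#'
#' @param summaries Data frame in the \code{\link{breed_ibc_summaries}}
#'   layout.
#' @param alpha F-test gate level.
#' @return Data frame: breed, the input summaries, f_test_p,
#'   variances_unequal, t_statistic, degrees_of_freedom, t_test_p.
#' @export
compare_ibc_table <- function(summaries = breed_ibc_summaries(),
                              alpha = 0.05) {
  res <- lapply(seq_len(nrow(summaries)), function(i) {
    r <- summaries[i, ]
    cmp <- compare_ibc_groups(list(mean = r$mean_bg, variance = r$var_bg,
                                   n = r$n_bg),
                              list(mean = r$mean_cb, variance = r$var_cb,
                                   n = r$n_cb),
                              alpha = alpha)
    data.frame(breed = r$breed, f_test_p = cmp$f_test_p,
               variances_unequal = cmp$variances_unequal,
               t_statistic = cmp$t_statistic,
               degrees_of_freedom = cmp$degrees_of_freedom,
               t_test_p = cmp$t_test_p, stringsAsFactors = FALSE)
  })
  cbind(summaries, do.call(rbind, res)[, -1])
}

#' Cohort composition summary
#'
#' @param samples Sample table with a \code{sex} column ("F"/"M").
#' @return List: n_dogs, n_female, n_male, pct_female (percent, one
#'   decimal).
#' @export
summarize_cohort <- function(samples) {
  n <- nrow(samples)
  n_f <- sum(samples$sex == "F")
  list(n_dogs = n, n_female = n_f, n_male = n - n_f,
       pct_female = round(100 * n_f / n, 1))
}
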