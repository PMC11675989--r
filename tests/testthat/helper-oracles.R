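# Independent oracle implementations used across tests. These deliberately
# take the slow, direct route (dense matrices, exhaustive enumeration) so
# they share no code path with the package.

# dense restricted log-likelihood for y = Xb + g + e, g ~ N(0, sg*Kn),
# e ~ N(0, se*I), with Kn the relationship matrix scaled to unit mean
# diagonal (the parametrization reml_h2 reports in)
dense_reml_loglik <- function(sg, se, y, K, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  Kn <- unclass(K) / mean(diag(as.matrix(K)))
  V <- sg * Kn + se * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  -0.5 * (determinant(V)$modulus[1] + determinant(XtViX)$modulus[1] +
            drop(t(r) %*% Vi %*% r))
}

# dense GLS per-SNP effect and SE at a fixed variance ratio
dense_gls_assoc <- function(y, geno, K, ratio, W = NULL) {
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1)
  V <- ratio * unclass(K) + diag(n)
  Vi <- solve(V)
  t(vapply(seq_len(ncol(geno)), function(j) {
    x <- geno[, j]
    if (stats::sd(x) == 0) return(c(NA_real_, NA_real_))
    X <- cbind(W, x)
    A <- solve(t(X) %*% Vi %*% X)
    b <- drop(A %*% (t(X) %*% Vi %*% y))
    r <- y - X %*% b
    s2 <- drop(t(r) %*% Vi %*% r) / (n - ncol(X))
    c(b[length(b)], sqrt(A[nrow(A), ncol(A)] * s2))
  }, numeric(2)))
}

# whole-set greedy pruning oracle: repeatedly drop from the worst pair
brute_prune <- function(geno, r2_max = 0.6) {
  maf <- pmin(colMeans(geno) / 2, 1 - colMeans(geno) / 2)
  alive <- rep(TRUE, ncol(geno))
  repeat {
    idx <- which(alive)
    if (length(idx) < 2) break
    cc <- suppressWarnings(stats::cor(geno[, idx, drop = FALSE]))^2
    cc[is.na(cc)] <- 0
    diag(cc) <- 0
    mx <- which.max(cc)
    if (cc[mx] <= r2_max) break
    i <- idx[(mx - 1) %% length(idx) + 1]
    j <- idx[(mx - 1) %/% length(idx) + 1]
    drop_one <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else max(i, j)
    alive[drop_one] <- FALSE
  }
  colnames(geno)[alive]
}

# exhaustive count-based risk scorer for a single genotype vector
brute_cgrs_one <- function(dosages, betas) {
  total <- 0L
  for (k in seq_along(dosages)) {
    total <- total + if (betas[k] < 0) 2L - dosages[k] else dosages[k]
  }
  total
}

small_cohort <- function(seed = 7, n_breeds = 2, n_per_breed = 40,
                         n_snps = 300, ...) {
  cfg <- sim_config(n_breeds = n_breeds, n_per_breed = n_per_breed,
                    n_snps = n_snps, seed = seed, ...)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$geno, sim$samples, cfg)
  out <- sim
  out$behavior <- ph$behavior
  out$truth <- c(sim$truth, ph$truth)
  out$cfg <- cfg
  out
}
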