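# continuous 4-factor toy: 3 items per factor, known simple structure
make_factor_items <- function(n = 400, load = 0.85, seed = 19) {
  set.seed(seed)
  f <- matrix(rnorm(n * 4), n, 4)
  items <- list()
  for (k in 1:4) {
    for (j in 1:3) {
      items[[paste0("f", k, "_", j)]] <-
        load * f[, k] + sqrt(1 - load^2) * rnorm(n)
    }
  }
  list(behavior = as.data.frame(items), factors = f)
}

test_that("varimax rotation is orthonormal and variance-preserving", {
  sc <- small_cohort(seed = 5, n_per_breed = 150)
  fit <- fit_pca_varimax(sc$behavior)
  R <- fit$rotation
  expect_lt(max(abs(crossprod(R) - diag(ncol(R)))), 1e-8)
  expect_lt(abs(sum(fit$loadings^2) - sum(fit$rotated_loadings^2)), 1e-8)
  expect_setequal(fit$labels, c("SF", "FM", "NSF", "SR"))
})

test_that("rotated loadings recover a planted simple structure", {
  toy <- make_factor_items()
  groups <- list(g1 = paste0("f1_", 1:3), g2 = paste0("f2_", 1:3),
                 g3 = paste0("f3_", 1:3), g4 = paste0("f4_", 1:3))
  fit <- fit_pca_varimax(toy$behavior, item_groups = groups)
  true_load <- matrix(0, 12, 4,
                      dimnames = list(colnames(toy$behavior), names(groups)))
  for (k in 1:4) true_load[paste0("f", k, "_", 1:3), k] <- 0.85
  lam <- fit$rotated_loadings[, names(groups)]
  congruence <- vapply(1:4, function(k) {
    sum(lam[, k] * true_load[, k]) /
      sqrt(sum(lam[, k]^2) * sum(true_load[, k]^2))
  }, numeric(1))
  expect_true(all(abs(congruence) > 0.95))
})

test_that("constant items are rejected by name", {
  sc <- small_cohort(seed = 5, n_per_breed = 30)
  sc$behavior$mat <- 1L
  expect_error(fit_pca_varimax(sc$behavior), "mat")
})

test_that("KMO equals the direct anti-image formula", {
  # equicorrelated 6-item panel, population r = 0.8
  set.seed(23)
  n <- 500
  common <- rnorm(n)
  items <- as.data.frame(replicate(6, sqrt(0.8) * common +
                                     sqrt(0.2) * rnorm(n), simplify = FALSE))
  names(items) <- paste0("it", 1:6)
  R <- cor(as.matrix(items))
  P <- solve(R)
  q <- -P / sqrt(outer(diag(P), diag(P)))
  off <- upper.tri(R)
  expected <- sum(R[off]^2) / (sum(R[off]^2) + sum(q[off]^2))
  kmo <- compute_kmo(items)
  expect_equal(kmo, expected, tolerance = 1e-12)
  expect_gte(kmo, 0)
  expect_lte(kmo, 1)
})

test_that("two-item KMO reduces to the 2x2 anti-image closed form", {
  # for two variables the anti-image partial correlation equals r, so
  # KMO = r^2 / (r^2 + r^2) = 1/2 regardless of r
  set.seed(29)
  x <- rnorm(200)
  items <- data.frame(a = x + rnorm(200, 0, 0.5),
                      b = x + rnorm(200, 0, 0.8))
  expect_equal(compute_kmo(items), 0.5, tolerance = 1e-12)
})

test_that("regression-method scores behave on identity and toy cases", {
  # uncorrelated items with (near-)identity loadings: scores are the
  # standardized items themselves
  set.seed(37)
  items <- as.data.frame(matrix(rnorm(300 * 4), 300, 4))
  names(items) <- paste0("it", 1:4)
  Z <- scale(as.matrix(items))
  R <- cor(as.matrix(items))
  fake <- structure(list(rotated_loadings = diag(4), correlation = R),
                    class = "component_result")
  rownames(fake$rotated_loadings) <- names(items)
  S <- component_scores(fake, items)
  oracle <- Z %*% solve(R, diag(4))
  oracle <- sweep(oracle, 2, colMeans(oracle))
  expect_equal(unname(S), unname(oracle), tolerance = 1e-10)
  expect_lt(max(abs(colMeans(S))), 1e-10)

  # full fit: scores are centered and reproducible from the loadings
  sc <- small_cohort(seed = 5, n_per_breed = 150)
  fit <- fit_pca_varimax(sc$behavior)
  expect_lt(max(abs(colMeans(fit$scores))), 1e-10)
  expect_equal(unname(fit$scores),
               unname(component_scores(fit, sc$behavior)),
               tolerance = 1e-10)
})

test_that("phenotype adjustment removes planted facility shifts", {
  set.seed(41)
  n <- 400
  fac <- factor(sample(paste0("f", 1:8), n, replace = TRUE))
  shifts <- rnorm(8, 0, 2)
  y <- shifts[as.integer(fac)] + rnorm(n)
  samples <- data.frame(facility = as.character(fac))
  adj <- adjust_phenotype(y, samples)
  expect_true("facility" %in% adj$retained)
  between_var <- function(v) var(tapply(v, fac, mean))
  expect_lt(between_var(adj$residuals) / between_var(y), 0.05)
  # least-squares orthogonality to the retained design
  X <- model.matrix(~fac)
  expect_lt(max(abs(crossprod(X, adj$residuals))), 1e-8)
})

test_that("with no significant candidates the phenotype is only centered", {
  set.seed(43)
  n <- 300
  samples <- data.frame(facility = sample(paste0("f", 1:5), n, TRUE),
                        sex = sample(c("F", "M"), n, TRUE),
                        size_class = sample(c("S", "M", "L"), n, TRUE),
                        age = runif(n, 1, 10))
  y <- rnorm(n) + 5
  adj <- adjust_phenotype(y, samples, alpha = 1e-6)
  expect_length(adj$retained, 0)
  expect_equal(adj$residuals, y - mean(y))
})

test_that("single-observation factor levels are dropped with a warning", {
  set.seed(47)
  samples <- data.frame(facility = c(rep("a", 20), rep("b", 20), "lonely"))
  y <- rnorm(41)
  expect_warning(adjust_phenotype(y, samples), "lonely")
})

test_that("planted components are recovered end to end", {
  sc <- small_cohort(seed = 61, n_breeds = 2, n_per_breed = 300,
                     n_snps = 400, h2_target = 0.3)
  fit <- fit_pca_varimax(sc$behavior)
  for (k in c("SF", "NSF", "SR")) {
    expect_gt(cor(fit$scores[, k], sc$truth$latent[, k]), 0.8)
  }
})
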