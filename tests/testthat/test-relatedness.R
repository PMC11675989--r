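test_that("single-marker GRM equals the hand-computed outer product", {
  geno <- matrix(c(0L, 1L, 2L), 3, 1,
                 dimnames = list(paste0("d", 1:3), "v1"))
  K <- compute_grm(geno, "centered")
  xc <- c(-1, 0, 1)
  expect_equal(unclass(K), outer(xc, xc),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("GRM is symmetric, PSD, and maximal for duplicate individuals", {
  sc <- small_cohort(seed = 3, missing_rate = 0)
  geno <- rbind(sc$geno, dup = sc$geno[1, ])
  K <- compute_grm(geno, "centered")
  expect_lt(max(abs(K - t(K))), 1e-10)
  expect_gt(min(eigen(unclass(K), symmetric = TRUE,
                      only.values = TRUE)$values), -1e-8)
  n <- nrow(geno)
  expect_equal(K[n, 1], K[n, n], tolerance = 1e-8)
  expect_equal(K[1, 1], K[n, n], tolerance = 1e-8)
})

test_that("GRM flavors are proportional when all marker spectra match", {
  # columns are permutations of one dosage multiset -> equal sds
  set.seed(7)
  base <- c(rep(0L, 30), rep(1L, 40), rep(2L, 30))
  geno <- sapply(1:20, function(j) sample(base))
  rownames(geno) <- paste0("d", 1:100)
  colnames(geno) <- paste0("v", 1:20)
  Kc <- compute_grm(geno, "centered")
  Kv <- compute_grm(geno, "variance_standardized")
  ratio <- unclass(Kc) / unclass(Kv)
  off <- abs(unclass(Kv)) > 1e-8
  expect_lt(diff(range(ratio[off])), 1e-8)
})

test_that("GRM principal components separate simulated breeds", {
  sc <- small_cohort(seed = 9, n_breeds = 2, n_per_breed = 60,
                     n_snps = 500, fst_per_breed = 0.25, missing_rate = 0)
  K <- compute_grm(sc$geno, "variance_standardized")
  pcs <- grm_pcs(K, 2)
  b1 <- pcs[sc$samples$breed == "breed01", 1]
  b2 <- pcs[sc$samples$breed == "breed02", 1]
  expect_true(max(b1) < min(b2) || max(b2) < min(b1))
  ev <- attr(pcs, "eigenvalues")
  expect_true(all(diff(ev) <= 1e-12))
  expect_identical(pcs, grm_pcs(K, 2))
  expect_error(grm_pcs(diag(3), 4), "rank")
})

test_that("inbreeding estimator hits its boundary cases", {
  # fully homozygous individual: F = 1; fully heterozygous: F < 0
  geno <- rbind(hom = c(0L, 2L, 0L, 2L),
                het = c(1L, 1L, 1L, 1L),
                mix1 = c(0L, 1L, 1L, 2L),
                mix2 = c(1L, 2L, 0L, 1L))
  colnames(geno) <- paste0("v", 1:4)
  res <- compute_ibc(geno)
  expect_equal(res$ibc$f_hat[res$ibc$id == "hom"], 1)
  expect_lt(res$ibc$f_hat[res$ibc$id == "het"], 0)
  expect_error(compute_ibc(geno[1, , drop = FALSE]), "at least 2")
})

test_that("inbreeding estimates match a spreadsheet-style hand computation", {
  geno <- rbind(a = c(0L, 1L, 2L, 1L),
                b = c(2L, 2L, 2L, 0L),
                c = c(1L, 0L, 2L, NA))
  colnames(geno) <- paste0("v", 1:4)
  res <- compute_ibc(geno)

  # independent recomputation, marker by marker
  for (ind in rownames(geno)) {
    o_hom <- 0; e_hom <- 0; L <- 0
    for (j in 1:4) {
      x <- geno[ind, j]
      if (is.na(x)) next
      n_allele <- 2 * sum(!is.na(geno[, j]))
      f <- sum(geno[, j], na.rm = TRUE) / n_allele
      e_hom <- e_hom + (1 - 2 * f * (1 - f) * n_allele / (n_allele - 1))
      o_hom <- o_hom + as.integer(x != 1L)
      L <- L + 1
    }
    expect_equal(res$ibc$f_hat[res$ibc$id == ind],
                 (o_hom - e_hom) / (L - e_hom), tolerance = 1e-12)
  }
})

test_that("simulated inbreeding is recovered within 0.03 at 5000 markers", {
  cfg <- sim_config(n_breeds = 1, n_per_breed = 200, n_snps = 5000,
                    inbreeding_per_breed = 0.25, missing_rate = 0,
                    seed = 15)
  sim <- simulate_genotypes(cfg)
  res <- compute_ibc(sim$geno)
  expect_lt(abs(mean(res$ibc$f_hat) - 0.25), 0.03)
})

test_that("identical groups compare as a perfect null", {
  x <- c(0.1, 0.2, 0.05, 0.15, 0.12)
  cmp <- compare_ibc_groups(x, x)
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$t_test_p, 1)
  expect_false(cmp$variances_unequal)
  expect_error(compare_ibc_groups(c(1, 1), c(1, 1)), "zero variance")
  expect_error(compare_ibc_groups(1, c(1, 2)), "at least 2")
})

test_that("raw-vector and summary-statistic paths agree", {
  set.seed(17)
  a <- rnorm(30, 0.05, 0.08)
  b <- rnorm(20, -0.02, 0.03)
  c1 <- compare_ibc_groups(a, b)
  c2 <- compare_ibc_groups(list(mean = mean(a), variance = var(a), n = 30),
                           list(mean = mean(b), variance = var(b), n = 20))
  expect_equal(c1$t_test_p, c2$t_test_p, tolerance = 1e-12)
  expect_equal(c1$f_test_p, c2$f_test_p, tolerance = 1e-12)
})

test_that("the F-test gate agrees with var.test and t-tests with t.test", {
  set.seed(19)
  a <- rnorm(25, 0, 1)
  b <- rnorm(35, 0.5, 2)
  cmp <- compare_ibc_groups(a, b)
  expect_equal(cmp$f_test_p, var.test(a, b)$p.value, tolerance = 1e-10)
  ref <- t.test(a, b, var.equal = !cmp$variances_unequal)
  expect_equal(cmp$t_test_p, ref$p.value, tolerance = 1e-10)
  expect_equal(cmp$degrees_of_freedom, unname(ref$parameter),
               tolerance = 1e-8)
})

test_that("cohort summary reports the female percentage", {
  samples <- data.frame(sex = c(rep("F", 509), rep("M", 106)))
  s <- summarize_cohort(samples)
  expect_equal(s$n_dogs, 615)
  expect_equal(s$pct_female, 82.8)
})
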