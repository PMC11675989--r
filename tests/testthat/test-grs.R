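test_that("SD binning matches Gaussian tail expectations", {
  set.seed(3)
  x <- rnorm(10000)
  bins <- bin_by_sd(x)
  frac <- as.numeric(bins$sizes) / 10000
  expect_lt(abs(frac[1] - pnorm(-1)), 0.015)  # more fearful
  expect_lt(abs(frac[3] - pnorm(-1)), 0.015)  # less fearful
  # symmetric two-point phenotype: no intermediate dogs
  b2 <- bin_by_sd(rep(c(-2, 2), 10))
  expect_equal(sum(b2$label == "intermediate"), 0)
  expect_error(bin_by_sd(rep(1, 10)), "zero standard deviation")
  expect_error(bin_by_sd(c(1, 2)), "at least 3")
})

test_that("count GRS respects bounds and the negative-effect recoding", {
  geno <- matrix(2L, 3, 4, dimnames = list(paste0("d", 1:3),
                                           paste0("v", 1:4)))
  effects <- data.frame(id = paste0("v", 1:4), beta = c(1, 0.5, 0.2, 0.1))
  expect_equal(unname(compute_cgrs(geno, effects, paste0("v", 1:4))),
               rep(8L, 3))  # 2M with all effects positive
  neg <- data.frame(id = "v1", beta = -0.3)
  expect_equal(unname(compute_cgrs(geno[, 1, drop = FALSE], neg, "v1")),
               rep(0L, 3))  # risk-allele homozygote of a protective SNP
})

test_that("count GRS matches exhaustive enumeration on a mixed-sign panel", {
  betas <- c(0.4, -0.2, 0.9, -1.1, 0.05)
  combos <- as.matrix(expand.grid(rep(list(0:2), 5)))
  storage.mode(combos) <- "integer"
  rownames(combos) <- paste0("d", seq_len(nrow(combos)))
  colnames(combos) <- paste0("v", 1:5)
  effects <- data.frame(id = paste0("v", 1:5), beta = betas)
  got <- compute_cgrs(combos, effects, paste0("v", 1:5))
  want <- apply(combos, 1, brute_cgrs_one, betas = betas)
  expect_equal(unname(got), unname(want))
  expect_true(all(got >= 0 & got <= 10))
})

test_that("weighted GRS is the signed linear combination of dosages", {
  set.seed(11)
  geno <- matrix(sample(0:2, 60, replace = TRUE), 20, 3,
                 dimnames = list(paste0("d", 1:20), paste0("v", 1:3)))
  effects <- data.frame(id = paste0("v", 1:3), beta = c(0.5, -0.2, 1.0))
  w <- compute_wgrs(geno, effects, paste0("v", 1:3))
  hand <- 0.5 * geno[, 1] - 0.2 * geno[, 2] + 1.0 * geno[, 3]
  expect_equal(w, hand)
  # unit weights: wGRS = dosage sum = cGRS
  unit <- data.frame(id = paste0("v", 1:3), beta = c(1, 1, 1))
  expect_equal(unname(compute_wgrs(geno, unit, paste0("v", 1:3))),
               unname(rowSums(geno)))
  expect_equal(unname(compute_cgrs(geno, unit, paste0("v", 1:3))),
               as.integer(rowSums(geno)))
  zero <- data.frame(id = paste0("v", 1:3), beta = c(0, 0, 0))
  expect_equal(unname(compute_wgrs(geno, zero, paste0("v", 1:3))),
               rep(0, 20))
})

test_that("risk scores are linear and monotone in dosage", {
  set.seed(13)
  effects <- data.frame(id = paste0("v", 1:4),
                        beta = c(0.3, -0.6, 0.1, 0.8))
  g1 <- matrix(sample(0:2, 40, TRUE), 10, 4,
               dimnames = list(paste0("d", 1:10), paste0("v", 1:4)))
  g2 <- matrix(sample(0:2, 40, TRUE), 10, 4, dimnames = dimnames(g1))
  s <- paste0("v", 1:4)
  expect_equal(compute_wgrs(g1, effects, s) + compute_wgrs(g2, effects, s),
               compute_wgrs(g1 + g2, effects, s))
  # bumping a positive-effect SNP never decreases either score
  g3 <- g1
  g3[g3[, "v4"] < 2, "v4"] <- g3[g3[, "v4"] < 2, "v4"] + 1L
  expect_true(all(compute_wgrs(g3, effects, s) >=
                    compute_wgrs(g1, effects, s)))
  expect_true(all(compute_cgrs(g3, effects, s) >=
                    compute_cgrs(g1, effects, s)))
  expect_error(compute_cgrs(g1, effects, c("v1", "vX")), "vX")
})

test_that("group comparison is null for identical groups and sharp for separated ones", {
  set.seed(17)
  x <- rnorm(40)
  scores <- c(x, x)
  bins <- factor(rep(c("more_fearful", "less_fearful"), each = 40),
                 levels = c("more_fearful", "intermediate", "less_fearful"))
  cmp <- compare_grs_groups(scores, bins)
  expect_gt(min(cmp$tukey$p_adj), 0.95)

  y <- c(rnorm(30, 0, 0.01), rnorm(30, 1, 0.01), rnorm(30, 2, 0.01))
  b3 <- factor(rep(c("more_fearful", "intermediate", "less_fearful"),
                   each = 30),
               levels = c("more_fearful", "intermediate", "less_fearful"))
  cmp3 <- compare_grs_groups(y, b3, mode = "three_group")
  expect_true(all(cmp3$tukey$p_adj < 0.001))
  expect_equal(nrow(cmp3$tukey), 3)
  expect_equal(nrow(cmp3$group_summary), 3)
})

test_that("in-sample effect estimates separate the extreme phenotype bins", {
  # the expected circularity of in-sample risk scores: even a modest
  # cohort shows extreme-group wGRS separation in the right direction
  sc <- small_cohort(seed = 19, n_breeds = 1, n_per_breed = 300,
                     n_snps = 600, h2_target = 0.4, missing_rate = 0)
  y <- sc$truth$latent[, "SF"] - sc$truth$fixed_effect_values
  K <- compute_grm(sc$geno, "centered")
  rec <- suppressMessages(lmm_assoc(y, sc$geno, K, variants = sc$variants,
                                    mode = "null"))
  top <- rec$id[order(rec$wald_p)][1:20]
  wg <- compute_wgrs(sc$geno, rec, top)
  bins <- bin_by_sd(y)
  cmp <- compare_grs_groups(wg, bins)
  s <- cmp$group_summary
  expect_gt(s$mean[s$group == "less_fearful"],
            s$mean[s$group == "more_fearful"])
})

test_that("undersized groups are dropped with a warning", {
  scores <- c(rnorm(20), 5)
  bins <- factor(c(rep("more_fearful", 10), rep("less_fearful", 10),
                   "intermediate"),
                 levels = c("more_fearful", "intermediate", "less_fearful"))
  expect_warning(cmp <- compare_grs_groups(scores, bins,
                                           mode = "three_group"),
                 "intermediate")
  expect_equal(nrow(cmp$group_summary), 2)
})
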