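test_that("PLINK triplet round trip is bit-exact for all dosage patterns", {
  # exhaustive over small shapes, including n not divisible by 4, plus
  # missing entries
  set.seed(11)
  for (n in c(3, 4, 5, 8)) {
    geno <- matrix(sample(c(0L, 1L, 2L, NA), n * 6, replace = TRUE), n, 6)
    rownames(geno) <- paste0("d", seq_len(n))
    colnames(geno) <- paste0("v", 1:6)
    # keep at least one observed call per variant so the matrix is readable
    geno[1, ] <- 1L
    pre <- tempfile()
    write_plink(geno, pre)
    back <- read_plink(paste0(pre, ".bed"))
    expect_identical(back$geno, geno)
  }
})

test_that("bed decoding matches a hand-decoded 4-sample byte string", {
  # one variant, 4 samples, codes packed low-bits-first:
  # dosages (2, NA, 1, 0) -> codes (00, 01, 10, 11) -> byte 11100100 = 0xE4
  pre <- tempfile()
  writeLines(c("1\tv1\t0\t100\tA\tG"), paste0(pre, ".bim"))
  writeLines(sprintf("d%d\td%d\t0\t0\t2\t-9", 1:4, 1:4), paste0(pre, ".fam"))
  con <- file(paste0(pre, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xe4)), con)
  close(con)
  got <- read_plink(paste0(pre, ".bed"))
  expect_equal(unname(got$geno[, 1]), c(2L, NA, 1L, 0L))
})

test_that("inconsistent triplet files raise format errors", {
  geno <- matrix(1L, 4, 2, dimnames = list(paste0("d", 1:4), c("a", "b")))
  pre <- tempfile()
  write_plink(geno, pre)
  # .fam with an extra row no longer matches the .bed payload
  fam <- readLines(paste0(pre, ".fam"))
  writeLines(c(fam, "d5\td5\t0\t0\t2\t-9"), paste0(pre, ".fam"))
  expect_error(read_plink(paste0(pre, ".bed")), "does not match")

  bad <- tempfile(fileext = ".bed")
  writeBin(as.raw(c(0x00, 0x1b, 0x01)), bad)
  file.copy(paste0(pre, ".bim"), sub("\\.bed$", ".bim", bad))
  file.copy(paste0(pre, ".fam"), sub("\\.bed$", ".fam", bad))
  expect_error(read_plink(bad), "magic")
})

test_that("QC filters apply strict thresholds in removal order", {
  set.seed(21)
  n <- 40
  geno <- cbind(
    maf05 = c(rep(2L, 2), rep(1L, 0), rep(0L, 38)),  # maf exactly 0.05
    ok1 = sample(c(0L, 1L, 2L), n, replace = TRUE),
    mono = rep(0L, n),
    ok2 = sample(c(0L, 1L), n, replace = TRUE)
  )
  rownames(geno) <- paste0("d", 1:n)
  variants <- data.frame(id = colnames(geno), chrom = c("1", "1", "2", "X"),
                         pos = 1:4, polymorphic = c(TRUE, TRUE, FALSE, TRUE),
                         indel = FALSE)
  qc <- qc_filter(geno, variants)
  expect_equal(qc$report$n_removed_nonautosomal, 1)  # the X variant
  expect_equal(qc$report$n_removed_mono_or_indel, 1)
  expect_equal(qc$report$n_removed_maf, 1)           # maf == 0.05 is removed
  expect_equal(qc$variants$id, "ok1")
})

test_that("call-rate filter matches a direct count on a toy panel", {
  set.seed(33)
  n <- 50
  geno <- matrix(sample(0:2, n * 10, replace = TRUE), n, 10)
  colnames(geno) <- paste0("v", 1:10)
  rownames(geno) <- paste0("d", 1:n)
  low_cr <- c(2, 5, 9)
  for (j in low_cr) geno[sample(n, 8), j] <- NA  # call rate 0.84
  variants <- data.frame(id = colnames(geno), chrom = "1", pos = 1:10,
                         polymorphic = TRUE, indel = FALSE)
  qc <- qc_filter(geno, variants, maf_min = 0, call_rate_min = 0.90)
  expect_equal(qc$report$n_removed_callrate, 3)
  expect_setequal(qc$variants$id, paste0("v", setdiff(1:10, low_cr)))
})

test_that("QC accounting conserves the variant count", {
  for (seed in 1:4) {
    sc <- small_cohort(seed = seed, n_snps = 200,
                       missing_rate = 0.05)
    qc <- qc_filter(sc$geno, sc$variants)
    r <- qc$report
    expect_equal(r$n_removed_nonautosomal + r$n_removed_mono_or_indel +
                   r$n_removed_maf + r$n_removed_callrate + r$n_retained,
                 r$n_input)
  }
})

test_that("sporadic-missing fill imputes the per-variant mode only", {
  geno <- cbind(a = c(0L, 0L, 2L, NA), b = c(1L, 1L, 0L, 2L))
  rownames(geno) <- paste0("d", 1:4)
  filled <- fill_sporadic_missing(geno)
  expect_equal(filled[4, "a"], 0L)          # mode of {0,0,2}
  expect_identical(filled[, "b"], geno[, "b"])
  expect_identical(fill_sporadic_missing(filled), filled)

  allmiss <- cbind(a = c(0L, 1L), bad = c(NA_integer_, NA_integer_))
  expect_error(fill_sporadic_missing(allmiss), "bad")
})

test_that("duplicated variants are pruned down to a single copy", {
  set.seed(41)
  x <- sample(0:2, 100, replace = TRUE)
  geno <- cbind(v1 = x, v2 = x, v3 = sample(0:2, 100, replace = TRUE))
  rownames(geno) <- paste0("d", 1:100)
  kept <- ld_prune(geno, window = 3, step = 1)
  expect_equal(sum(c("v1", "v2") %in% kept), 1)
  expect_true("v3" %in% kept)
})

test_that("independent variants survive pruning", {
  set.seed(43)
  geno <- matrix(rbinom(500 * 30, 2, 0.4), 500, 30)
  colnames(geno) <- paste0("v", 1:30)
  rownames(geno) <- paste0("d", 1:500)
  expect_equal(length(ld_prune(geno, window = 30, step = 10)), 30)
})

test_that("greedy pruning matches the brute-force rule on a toy panel", {
  set.seed(47)
  base <- rbinom(200, 2, 0.5)
  geno <- matrix(rbinom(200 * 20, 2, 0.3), 200, 20)
  # one correlated triple: columns 5, 6, 7 are noisy copies of `base`
  for (j in 5:7) {
    x <- base
    swap <- sample(200, 15)
    x[swap] <- rbinom(15, 2, 0.5)
    geno[, j] <- x
  }
  colnames(geno) <- paste0("v", 1:20)
  rownames(geno) <- paste0("d", 1:200)
  kept <- ld_prune(geno, window = 20, step = 20)
  expect_setequal(kept, brute_prune(geno))
})

test_that("pruning an already-pruned panel removes nothing", {
  sc <- small_cohort(seed = 13, n_snps = 300, missing_rate = 0)
  kept <- ld_prune(sc$geno, sc$variants, window = 50, step = 20)
  again <- ld_prune(sc$geno[, kept, drop = FALSE],
                    sc$variants[match(kept, sc$variants$id), ],
                    window = 50, step = 20)
  expect_setequal(again, kept)
  expect_error(ld_prune(sc$geno, sc$variants, window = 1), "at least 2")
})
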