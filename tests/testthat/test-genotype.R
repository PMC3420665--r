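test_that("MAF computation counts minor alleles and reorients major-allele columns", {
  G <- genotype_matrix(cbind(a = c(0, 0, 1, 2)))
  expect_equal(G$maf, 3 / 8)

  G0 <- genotype_matrix(cbind(a = c(0, 0, 0, 0), b = c(0, 1, 0, 0)))
  expect_equal(G0$maf, c(0, 1 / 8))

  # column coded on the major allele: recode g -> 2 - g, complement the MAF
  Gf <- genotype_matrix(cbind(a = c(2, 2, 2, 1)))
  expect_equal(Gf$maf, 0.125)
  expect_equal(unname(Gf$values[, 1]), c(0, 0, 0, 1))

  expect_error(genotype_matrix(cbind(ok = c(0, 1), bad = c(NA, NA))), "bad")
  expect_error(genotype_matrix(cbind(c(0, 3, 1))), "0, 1, 2")
})

test_that("reorientation is idempotent", {
  set.seed(11)
  for (rep in 1:5) {
    v <- matrix(sample(c(0, 1, 2, NA), 40 * 6, replace = TRUE,
                       prob = c(0.2, 0.2, 0.5, 0.1)), 40, 6)
    v[1, ] <- 0  # keep at least one non-missing per column
    G1 <- genotype_matrix(v)
    G2 <- compute_maf(G1)
    expect_identical(G1$values, G2$values)
    expect_identical(G1$maf, G2$maf)
    expect_true(all(G1$maf <= 0.5))
  }
})

test_that("Hardy-Weinberg imputation fills only missing entries, reproducibly", {
  v <- cbind(a = c(0, 0, rep(NA, 6)),       # q = 0
             b = c(2, 2, 0, 0, NA, NA, NA, NA))
  G <- genotype_matrix(v)
  Gi <- impute_missing(G, seed = 5)
  expect_false(anyNA(Gi$values))
  expect_true(all(Gi$values[3:8, "a"] == 0))      # q = 0 imputes 0
  expect_equal(Gi$values[1:4, "b"], G$values[1:4, "b"])  # observed unchanged
  Gi2 <- impute_missing(G, seed = 5)
  expect_identical(Gi$values, Gi2$values)
})

test_that("imputed genotypes match the binomial mean at q = 0.5", {
  n <- 1e5
  v <- cbind(x = c(0, 2, rep(NA, n - 2)))   # observed MAF exactly 0.5
  G <- genotype_matrix(v)
  expect_equal(G$maf, 0.5)
  Gi <- impute_missing(G, seed = 9)
  expect_equal(mean(Gi$values[-(1:2), 1]), 1.0, tolerance = 0.01)
})

test_that("imputation preserves the expected MAF", {
  # q = 0.1 from 40 observed entries, 1e4 missing draws
  n <- 10040
  v <- cbind(x = c(rep(1, 8), rep(0, 32), rep(NA, 1e4)))
  G <- genotype_matrix(v)
  expect_equal(G$maf, 0.1)
  Gi <- impute_missing(G, seed = 21)
  realized <- mean(Gi$values[-(1:40), 1]) / 2
  mc_se <- sqrt(0.1 * 0.9 / (2 * 1e4))
  expect_lt(abs(realized - 0.1), 3 * mc_se)
})

test_that("monomorphic variants are removed, order preserved", {
  v <- cbind(m = rep(0, 100),
             a = c(rep(1, 20), rep(0, 80)),
             b = c(rep(1, 4), rep(0, 96)))
  G <- filter_monomorphic(genotype_matrix(v))
  expect_equal(G$variant_ids, c("a", "b"))
  expect_equal(G$maf, c(0.1, 0.02))

  Gp <- genotype_matrix(v[, 2:3])
  expect_identical(filter_monomorphic(Gp)$values, Gp$values)

  expect_error(filter_monomorphic(genotype_matrix(cbind(rep(0, 10)))),
               "monomorphic")
})

test_that("pooled-variable lattice matches the hand enumeration", {
  # MAFs 0.2, 0.04, 0.02, 0.005 over n = 100: thresholds {.05,.04,.02,.005};
  # member sets {2,3,4},{2,3,4},{3,4},{4}; after dedup (keep largest label)
  # and dropping the singleton that equals an original column: 2 pooled cols
  G <- toy_counts(100, c(40, 8, 4, 1))
  expect_equal(G$maf, c(0.2, 0.04, 0.02, 0.005))
  ad <- build_pooled_variables(G)
  expect_equal(length(ad$pooled_thresholds), 2L)
  expect_equal(ad$pooled_thresholds, c(0.05, 0.02))
  expect_equal(ad$pooled_members, list(c(2L, 3L, 4L), c(3L, 4L)))
  expect_equal(ad$origin, c(rep("original", 4), rep("pooled", 2)))
  # pooled column at t_max = row-sum of all columns with maf <= t_max
  expect_equal(unname(ad$matrix[, 5]),
               unname(rowSums(G$values[, 2:4])))
})

test_that("no pooled columns when every MAF exceeds t_max", {
  G <- toy_counts(100, c(40, 30))
  ad <- build_pooled_variables(G)
  expect_equal(length(ad$pooled_thresholds), 0L)
  expect_equal(ncol(ad$matrix), 2L)
})

test_that("every pooled column equals the row-sum of its members (property)", {
  set.seed(31)
  for (rep in 1:5) {
    v <- matrix(rbinom(200 * 12, 2, rep(runif(12, 0.002, 0.2), each = 200)),
                200, 12)
    for (j in which(colSums(v) == 0)) v[j, j] <- 1
    G <- genotype_matrix(v)
    ad <- build_pooled_variables(G)
    for (i in seq_along(ad$pooled_members)) {
      expect_equal(
        unname(ad$matrix[, sum(ad$origin == "original") + i]),
        unname(rowSums(G$values[, ad$pooled_members[[i]], drop = FALSE])))
    }
    # pooled columns pairwise distinct and distinct from every original
    np <- sum(ad$origin == "original")
    pooled_cols <- ad$matrix[, ad$origin == "pooled", drop = FALSE]
    if (ncol(pooled_cols) > 0) {
      expect_false(anyDuplicated(t(pooled_cols)) > 0)
      for (i in seq_len(ncol(pooled_cols)))
        for (j in seq_len(np))
          expect_false(all(pooled_cols[, i] == ad$matrix[, j]))
    }
    expect_true(all(ad$pooled_thresholds <= 0.05))
  }
})

test_that("matrix files round-trip and phenotypes align by id", {
  v <- cbind(v1 = c(0, 1), v2 = c(2, NA))
  G <- genotype_matrix(v, sample_ids = c("s1", "s2"))
  f <- tempfile(fileext = ".tsv")
  write_genotype_matrix(G, f)
  G2 <- load_genotypes(f, format = "matrix")
  expect_equal(G2$values, G$values)
  expect_equal(G2$maf, G$maf)

  pf <- tempfile(fileext = ".tsv")
  write_phenotype(c(s2 = 1.5, s1 = -0.5), pf)
  y <- load_phenotype(pf)
  expect_equal(align_phenotype(G, y), c(s1 = -0.5, s2 = 1.5))

  write_phenotype(c(s1 = 1, s3 = 2), pf)
  expect_error(align_phenotype(G, load_phenotype(pf)), "s3")

  writeLines(c("id\tvalue", "s1\t1.2", "s1\t0.3"), pf)
  expect_error(load_phenotype(pf), "duplicated")
  writeLines(c("id\tvalue", "s1\tabc", "s2\t0.3"), pf)
  expect_error(load_phenotype(pf), "s1")
})

test_that("VCF genotypes parse through GT with ./. as missing", {
  skip_if_not_installed("vcfR")
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t0/0\t0/1"), f)
  G <- load_genotypes(f)
  expect_equal(dim(G), c(3L, 2L))
  expect_equal(unname(G$values[, "rs1"]), c(0, 1, 2))
  expect_true(is.na(G$values["s1", "rs2"]))
  expect_equal(G$maf, c(0.5, 0.25))

  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\trs1\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t1/2"), f)
  expect_error(load_genotypes(f), "multiallelic")
})
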