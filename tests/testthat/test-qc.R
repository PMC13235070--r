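test_that("allele frequencies are dosage sums over called alleles", {
  expect_equal(allele_frequency(c(2, 2, 2)), 1.0)
  expect_equal(allele_frequency(c(0, 1, 2)), 0.5)
  expect_equal(allele_frequency(c(0, 0, 1, 1)), 0.25)
  expect_equal(allele_frequency(c(0, NA, 2)), 0.5)   # missing ignored
  expect_true(is.na(allele_frequency(c(NA, NA))))
  M <- cbind(a = c(0, 1, 2), b = c(2, 2, NA))
  expect_equal(allele_frequency(M), c(a = 0.5, b = 1))
})

test_that("exact HWE test agrees with direct enumeration", {
  expect_equal(hwe_exact_test(0, 1, 0), 1.0)
  # forced configurations and extremes
  expect_equal(hwe_exact_test(10, 10, 10), hwe_oracle(10, 10, 10),
               tolerance = 1e-12)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  expect_equal(hwe_exact_test(50, 0, 50), hwe_oracle(50, 0, 50),
               tolerance = 1e-12)
  # random triples with totals up to 100
  set.seed(71)
  for (i in 1:200) {
    n <- sample(2:100, 1)
    aa <- sample(0:n, 1)
    ab <- sample(0:(n - aa), 1)
    bb <- n - aa - ab
    expect_equal(hwe_exact_test(aa, ab, bb), hwe_oracle(aa, ab, bb),
                 tolerance = 1e-12)
  }
  expect_equal(hwe_exact_test(25, 0, 0), 1)          # monomorphic
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "positive")
})

test_that("the exact test is conservative under true equilibrium", {
  set.seed(72)
  n <- 200
  pvals <- replicate(10000, {
    p <- stats::runif(1, 0.1, 0.9)
    g <- sample(0:2, n, replace = TRUE,
                prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
    hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0))
  })
  expect_lte(mean(pvals < 0.05), 0.05 + 0.005)
})

test_that("SNP filtering applies strict MAF and HWE thresholds", {
  # three SNPs: maf 0.04 (out), maf exactly 0.05 in HWE (in), HWE p tiny (out)
  n <- 200
  make <- function(nAA, nAB, nBB) c(rep(2, nAA), rep(1, nAB), rep(0, nBB))
  set.seed(73)
  m1 <- make(0, 16, 184)          # maf 0.04
  m2 <- make(1, 18, 181)          # maf 0.05, near-HWE
  m3 <- make(100, 0, 100)         # maf 0.5, extreme HWE violation
  M <- cbind(snp1 = m1, snp2 = m2, snp3 = m3)
  rownames(M) <- sprintf("i%03d", 1:n)
  expect_equal(unname(pmin(allele_frequency(M), 1 - allele_frequency(M))),
               c(0.04, 0.05, 0.5))
  res <- filter_snps(M)
  expect_identical(res$kept, "snp2")
  expect_identical(res$summary$kept, c(FALSE, TRUE, FALSE))
  expect_lt(res$summary$hwe_p[3], 1e-6)
  # boundary: hwe_p exactly at threshold is retained (threshold = that p)
  p2 <- res$summary$hwe_p[2]
  res2 <- filter_snps(M[, "snp2", drop = FALSE], hwe_threshold = p2)
  expect_identical(res2$kept, "snp2")
  expect_error(filter_snps(M[, "snp1", drop = FALSE]), "removed")
})

test_that("filtering is per-SNP and order-invariant", {
  qs <- quick_sim(n_generations = 2, gen_size = 100, snps = 80, n_chr = 2,
                  seed = 74)
  M <- qs$geno$dosage
  res <- filter_snps(M)
  perm <- sample(ncol(M))
  res_p <- filter_snps(M[, perm])
  expect_identical(res_p$summary$snp, colnames(M)[perm])
  expect_equal(res_p$summary$maf,
               res$summary$maf[match(res_p$summary$snp, res$summary$snp)])
  expect_setequal(res_p$kept, res$kept)
})

test_that("trait descriptives match the independent estimators", {
  expect_equal(describe_trait(c(-1, 0, 1))$skewness, 0)
  set.seed(75)
  x <- stats::rgamma(500, shape = 2)
  d <- describe_trait(x, trait = "toy")
  expect_equal(d$mean, mean(x))
  expect_equal(d$sd, stats::sd(x))
  expect_equal(d$cv, 100 * stats::sd(x) / mean(x))
  expect_equal(d$se, stats::sd(x) / sqrt(500))
  expect_equal(d$skewness, e1071::skewness(x, type = 2))
  expect_equal(d$kurtosis, e1071::kurtosis(x, type = 2))
  expect_warning(describe_trait(rep(1, 10)), "zero variance")
  expect_error(describe_trait(c(1, NA, 3, 4)), "missing")
})
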