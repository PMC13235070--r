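make_ped <- function(id, sire, dam, generation) {
  data.frame(id = id, sire = sire, dam = dam, generation = generation,
             line = "A", stringsAsFactors = FALSE)
}

test_that("A-matrix reproduces the textbook closed forms", {
  # unrelated founders -> identity
  f <- make_ped(c("a", "b", "c"), NA, NA, 1)
  expect_equal(unname(a_matrix(f)), diag(3), ignore_attr = TRUE)

  # parent-offspring 0.5, full sibs 0.5, half sibs 0.25
  ped <- make_ped(c("s1", "s2", "d1", "o1", "o2", "o3"),
                  c(NA, NA, NA, "s1", "s1", "s2"),
                  c(NA, NA, NA, "d1", "d1", "d1"),
                  c(1, 1, 1, 2, 2, 2))
  ped$sex <- c("M", "M", "F", "M", "F", "F")
  A <- a_matrix(ped)
  expect_equal(A["s1", "o1"], 0.5)
  expect_equal(A["o1", "o2"], 0.5)    # full sibs
  expect_equal(A["o1", "o3"], 0.25)   # half sibs (share dam only)
  expect_equal(unname(diag(A)), rep(1, 6))

  # offspring of two full sibs: F = 0.25, diagonal 1.25
  ped2 <- make_ped(c("s", "d", "x", "y", "z"),
                   c(NA, NA, "s", "s", "x"),
                   c(NA, NA, "d", "d", "y"),
                   c(1, 1, 2, 2, 3))
  expect_equal(a_matrix(ped2)["z", "z"], 1.25)
})

test_that("tabular A-matrix equals the recursive-definition oracle", {
  for (s in 1:3) {
    ped <- random_pedigree(n_generations = 4, gen_size = 50, seed = 80 + s)
    A <- a_matrix(ped)
    O <- a_matrix_oracle(ped)
    expect_equal(A[ped$id, ped$id], O, tolerance = 1e-14,
                 ignore_attr = TRUE)
    expect_true(isSymmetric(unclass(A)))
    expect_true(all(diag(A) >= 1))
  }
})

test_that("VanRaden G matches hand evaluation and behaves linearly", {
  M <- rbind(a = 2, b = 0)
  colnames(M) <- "s1"
  G <- g_matrix(M, freqs = 0.5)
  expect_equal(unname(unclass(G)), rbind(c(2, -2), c(-2, 2)),
               ignore_attr = TRUE)

  qs <- quick_sim(n_generations = 2, gen_size = 50, snps = 60, n_chr = 2,
                  seed = 84)
  M2 <- qs$geno$dosage
  M2 <- rbind(M2, dup = M2[1, ])   # duplicated individual
  rownames(M2)[nrow(M2)] <- "dup"
  G2 <- g_matrix(M2)
  expect_equal(unname(G2["dup", ]), unname(G2[1, ]))
  # centered dosages have zero column means when freqs are observed
  Z <- sweep(M2, 2, 2 * allele_frequency(M2))
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_error(g_matrix(cbind(x = rep(2, 5))), "monomorphic")
})

test_that("G diagonal is near 1 for unrelated individuals at true frequencies", {
  cfg <- sim_config(n_generations = 1, gen_sizes = 1000, n_lines = 1,
                    n_chromosomes = 5, snps_per_chromosome = 100,
                    line_divergence = 0, seed = 85)
  ped <- sim_pedigree(cfg)
  geno <- sim_genotypes(ped, cfg)
  G <- g_matrix(geno, freqs = geno$founder_freq["A", ])
  expect_lt(abs(mean(diag(G)) - 1), 0.03)
  off <- G[upper.tri(G)]
  expect_lt(abs(mean(off)), 0.01)
})

test_that("marker relationships recover the pedigree expectation for parent-offspring", {
  cfg <- sim_config(n_generations = 2, gen_sizes = c(150, 500), n_lines = 1,
                    n_chromosomes = 5, snps_per_chromosome = 100, seed = 86)
  ped <- sim_pedigree(cfg)
  geno <- sim_genotypes(ped, cfg)
  G <- g_matrix(geno, freqs = geno$founder_freq["A", ])
  off <- ped$generation == 2
  po <- G[cbind(ped$id[off], ped$sire[off])]
  expect_lt(abs(mean(po) - 0.5), 0.05)
})

test_that("regularization shifts only ill-conditioned matrices", {
  A <- a_matrix(random_pedigree(3, 30, seed = 87))
  expect_identical(regularize_kinship(A), A)          # PD: untouched
  expect_equal(attr(regularize_kinship(A), "ridge"), 0)

  M <- matrix(stats::rbinom(40 * 60, 2, 0.4), 40, 60,
              dimnames = list(sprintf("i%02d", 1:40), sprintf("s%02d", 1:60)))
  M <- rbind(M, i41 = M[1, ])                          # exact duplicate
  G <- g_matrix(M)
  ev0 <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(ev0, 1e-8)
  expect_message(Gr <- regularize_kinship(G, ridge = 0.01), "ridge")
  ev1 <- min(eigen(Gr, symmetric = TRUE, only.values = TRUE)$values)
  expect_gte(ev1, 0.01 - 1e-8)
  expect_equal(attr(Gr, "ridge"), 0.01)
  # without the ridge, the REML solver must refuse the singular kernel
  y <- stats::setNames(stats::rnorm(41), rownames(G))
  expect_error(gblup(y, G), "regularize")
})

test_that("genotype PCA separates diverged lines and orders variance", {
  cfg <- sim_config(n_generations = 1, gen_sizes = 60, n_lines = 2,
                    n_chromosomes = 2, snps_per_chromosome = 150,
                    line_divergence = 1.5, seed = 88)
  ped <- sim_pedigree(cfg)
  geno <- sim_genotypes(ped, cfg)
  p <- geno_pca(geno, k = 4)
  expect_true(all(diff(p$variance_explained) <= 1e-10))
  expect_lte(sum(100 * p$sdev^2 / sum(p$sdev^2)), 100 + 1e-8)
  # k-means on PC1 recovers the line labels perfectly at strong divergence
  km <- stats::kmeans(p$scores[, 1], centers = 2, nstart = 10)
  agreement <- max(mean((km$cluster == 1) == (ped$line == "A")),
                   mean((km$cluster == 2) == (ped$line == "A")))
  expect_equal(agreement, 1)
  # scores of distinct components are orthogonal
  expect_lt(max(abs(crossprod(p$scores)[upper.tri(diag(4))])), 1e-6)
})

test_that("degenerate PCA inputs are flagged", {
  M <- matrix(1, 10, 20, dimnames = list(sprintf("i%d", 1:10),
                                         sprintf("s%d", 1:20)))
  expect_warning(p <- geno_pca(M, k = 2), "degenerate")
  expect_true(p$degenerate)
  qs <- quick_sim(n_generations = 1, gen_size = 5, snps = 30, n_chr = 1,
                  seed = 89)
  expect_warning(p2 <- geno_pca(qs$geno$dosage, k = 10), "truncating")
  expect_lte(ncol(p2$scores), 5)
})
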