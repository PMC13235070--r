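test_that("accuracy is the predictive correlation scaled by sqrt(h2)", {
  expect_equal(prediction_accuracy_from(0.29, 0.25)$accuracy, 0.58)
  expect_equal(round(prediction_accuracy_from(0.26, 0.46)$accuracy, 2), 0.38)
  expect_equal(prediction_accuracy_from(sqrt(0.4), 0.4)$accuracy, 1)
  expect_warning(out <- prediction_accuracy_from(0.3, 0), "undefined")
  expect_true(is.na(out$accuracy))
  set.seed(121)
  ebv <- stats::setNames(stats::rnorm(100), sprintf("i%d", 1:100))
  y <- ebv + stats::rnorm(100)
  pa <- prediction_accuracy(ebv, y, 0.25)
  expect_equal(pa$accuracy, stats::cor(ebv, y) / 0.5)
  expect_error(prediction_accuracy(ebv[1:10], y[1:10], 0.25), "at least 30")
})

test_that("dispersion bias is the whole-on-partial regression slope", {
  ids <- sprintf("i%d", 1:200)
  set.seed(122)
  partial <- stats::setNames(stats::rnorm(200), ids)
  expect_equal(dispersion_bias(partial, partial, ids), 1)
  expect_equal(dispersion_bias(2 * partial, partial, ids), 2)
  noisy <- 0.8 * partial + stats::rnorm(200, 0, 0.1)
  expect_equal(dispersion_bias(noisy, partial, ids),
               unname(stats::coef(stats::lm(noisy ~ partial))[2]))
  expect_warning(b <- dispersion_bias(partial, partial * 0, ids), "zero-variance")
  expect_true(is.na(b))
  expect_error(dispersion_bias(partial[1:10], partial, ids), "missing")
})

test_that("standardized bias follows the two-branch transform", {
  expect_equal(standardized_bias(0.81), 0.19)
  expect_equal(round(standardized_bias(1.22), 2), -0.18)
  expect_equal(standardized_bias(1), 0)
  expect_equal(standardized_bias(0), 1)
  # continuity at b = 1 from both sides
  eps <- 1e-10
  expect_lt(abs(standardized_bias(1 - eps) - standardized_bias(1 + eps)), 1e-9)
  # |b_std| monotone in |b - 1| on (0, 2]
  left <- standardized_bias(seq(0.99, 0.01, by = -0.01))
  right <- standardized_bias(seq(1.01, 2, by = 0.01))
  expect_true(all(diff(abs(left)) > 0))
  expect_true(all(diff(abs(right)) > 0))
  expect_true(all(abs(c(left, right)) <= 1))
  expect_warning(out <- standardized_bias(-0.5), "out of range")
  expect_gt(out, 1)
  expect_error(standardized_bias(Inf), "finite")
})

test_that("under a correctly specified model the dispersion slope is near 1", {
  bs <- numeric(10)
  for (s in 1:10) {
    qs <- quick_sim(n_generations = 3, gen_size = 130, snps = 80, n_chr = 3,
                    h2 = 0.3, seed = 130 + s, no_fixed_effects = TRUE)
    y <- stats::setNames(qs$pheno$T1 - mean(qs$pheno$T1), qs$pheno$id)
    K <- regularize_kinship(g_matrix(qs$geno))
    split <- mask_validation(qs$ped, 3)
    fit_p <- gblup(y[split$training_ids], K)
    fit_w <- gblup(y, K)
    bs[s] <- dispersion_bias(predict(fit_w), predict(fit_p), split$masked_ids)
  }
  expect_lt(abs(mean(bs) - 1), 0.1)
})

test_that("imputation accuracy handles exact and degenerate cases", {
  qs <- quick_sim(n_generations = 2, gen_size = 50, snps = 30, n_chr = 2,
                  seed = 140)
  ids <- qs$ped$id[1:20]
  acc <- imputation_accuracy(qs$geno, qs$geno, ids)
  defined <- acc$per_snp$correlation[!is.na(acc$per_snp$correlation)]
  expect_true(all(abs(defined - 1) < 1e-12))
  expect_equal(acc$genome_mean, 1)
  # constant imputation: undefined correlation, excluded but counted
  imp <- qs$geno
  imp$dosage[, 1] <- 1
  acc2 <- imputation_accuracy(qs$geno, imp, ids)
  expect_true(is.na(acc2$per_snp$correlation[1]))
  expect_gte(acc2$n_undefined, 1)
  expect_false(is.na(acc2$genome_mean))
  expect_length(acc2$chromosome_mean, 2)
  expect_error(imputation_accuracy(qs$geno, qs$geno, character(0)), "no masked")
})

test_that("validation reports have the two-kernel table shape", {
  qs <- quick_sim(n_generations = 3, gen_size = 120, snps = 80, n_chr = 2,
                  seed = 141)
  ph <- qs$pheno
  ph$T2 <- ph$T1 + stats::rnorm(nrow(ph), 0, 5)
  pcs <- list(T1 = precorrect(ph, "T1", factors = c("sexhatch", "damage")),
              T2 = precorrect(ph, "T2", factors = c("sexhatch", "damage")))
  kernels <- list(G = regularize_kinship(g_matrix(qs$geno)),
                  A = regularize_kinship(a_matrix(qs$ped)))
  rep <- forward_validate(pcs, kernels, qs$ped, 3)
  expect_s3_class(rep, "validation_report")
  expect_equal(nrow(rep), 4)    # 2 traits x 2 kernels
  expect_setequal(rep$matrix, c("G", "A"))
  # internal audit: the accuracy column reproduces r / sqrt(h2)
  expect_equal(rep$accuracy, rep$r_val / sqrt(rep$h2), tolerance = 1e-12)
  wide <- report_wide(rep)
  expect_equal(dim(wide), c(2, 13))   # trait + 2 x 6 metric columns
  expect_identical(names(wide)[1:4], c("trait", "h2_G", "se_G", "r_G"))
  expect_equal(rep$n_masked, rep(120, 4))
})
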