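# shared small instance: 3 generations, G kernel, moderate heritability
fit_instance <- function(seed, h2 = 0.3, gen_size = 150, snps = 100) {
  qs <- quick_sim(n_generations = 3, gen_size = gen_size, snps = snps,
                  n_chr = 3, h2 = h2, seed = seed, no_fixed_effects = TRUE)
  y <- stats::setNames(qs$pheno$T1 - mean(qs$pheno$T1), qs$pheno$id)
  K <- regularize_kinship(g_matrix(qs$geno))
  list(qs = qs, y = y, K = K)
}

test_that("profile REML log-likelihood matches the dense-matrix formula", {
  inst <- fit_instance(101, gen_size = 17, snps = 40)   # n = 51 -> use 50
  y <- inst$y[1:50]
  K <- regularize_kinship(inst$K[names(y), names(y)])
  for (vc in list(c(2, 5), c(10, 1), c(0.5, 0.5))) {
    expect_equal(reml_loglik(y, K, vc[1], vc[2]),
                 dense_reml_loglik(y, K, vc[1], vc[2]),
                 tolerance = 1e-6)
  }
})

test_that("BLUP solution equals the Henderson mixed-model equations", {
  inst <- fit_instance(102, gen_size = 20, snps = 60)   # 60 individuals
  # phenotype 40, leave 20 for prediction through their kernel rows
  y <- inst$y[1:40]
  K <- inst$K
  fit <- gblup(y, K)
  mme <- mme_solve(y, K, fit$vc$sigma2_g, fit$vc$sigma2_e)
  expect_equal(fit$mu, mme$mu, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$ebv, mme$u, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(fit$ebv - mme$u)), 1e-8)
})

test_that("the optimizer lands on the grid-scan REML maximum", {
  inst <- fit_instance(103, gen_size = 40)    # n = 120
  fit <- gblup(inst$y, inst$K)
  y <- inst$y
  K <- inst$K[names(y), names(y)]
  n <- length(y)
  # dense profile log-likelihood, scale variance profiled out analytically
  prof_dense <- function(h2) {
    W <- h2 * K + (1 - h2) * diag(n)
    Wi <- solve(W)
    x <- rep(1, n)
    xwx <- drop(crossprod(x, Wi %*% x))
    q <- drop(crossprod(y, Wi %*% y)) - drop(crossprod(x, Wi %*% y))^2 / xwx
    s2 <- q / (n - 1)
    -0.5 * ((n - 1) * log(s2) + determinant(W)$modulus[1] + log(xwx) + (n - 1))
  }
  grid <- seq(1e-4, 0.9999, length.out = 1000)
  prof <- vapply(grid, prof_dense, 0)
  # unimodal on this instance, and argmax within grid resolution of the fit
  peaks <- sum(diff(sign(diff(prof))) < 0)
  expect_lte(peaks, 1)
  expect_lt(abs(grid[which.max(prof)] - fit$vc$h2), 1.5 * diff(grid[1:2]))
})

test_that("REML estimates are scale-equivariant", {
  inst <- fit_instance(104, gen_size = 100)
  f1 <- gblup(inst$y, inst$K)
  f2 <- gblup(inst$y * 3, inst$K)
  expect_equal(f2$vc$h2, f1$vc$h2, tolerance = 1e-4)
  expect_equal(f2$vc$sigma2_g, 9 * f1$vc$sigma2_g, tolerance = 1e-3 * f1$vc$sigma2_g)
  expect_equal(f2$vc$sigma2_e, 9 * f1$vc$sigma2_e, tolerance = 1e-3 * f1$vc$sigma2_e)
  expect_equal(unname(f2$ebv), unname(3 * f1$ebv), tolerance = 1e-4)
})

test_that("null heritability shrinks estimates and EBVs towards zero", {
  h2s <- c()
  for (s in 1:3) {
    inst <- fit_instance(110 + s, h2 = 0, gen_size = 250)
    fit <- gblup(inst$y, inst$K)
    h2s <- c(h2s, fit$vc$h2)
    expect_lt(max(abs(fit$ebv)) / stats::sd(inst$y), 0.5)
  }
  expect_lt(stats::median(h2s), 0.05)
})

test_that("gblup objects expose the standard modelling surface", {
  inst <- fit_instance(105, gen_size = 60)
  fit <- gblup(inst$y, inst$K)
  expect_s3_class(fit, "gblup")
  expect_output(print(fit), "animal model")
  expect_output(print(summary(fit)), "Variance components")
  expect_named(coef(fit), "(Intercept)")
  expect_equal(fitted(fit) + residuals(fit), inst$y)
  expect_equal(as.numeric(logLik(fit)), fit$vc$loglik)
  expect_equal(predict(fit, type = "response") - predict(fit),
               rep(fit$mu, length(fit$ebv)), ignore_attr = TRUE)
  expect_error(predict(fit, ids = "ghost"), "absent")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n, 3))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
  expect_equal(fit$vc$h2,
               fit$vc$sigma2_g / (fit$vc$sigma2_g + fit$vc$sigma2_e))
  expect_true(is.finite(fit$vc$h2_se) && fit$vc$h2_se > 0)
})

test_that("masked individuals are predicted through their kernel rows", {
  inst <- fit_instance(106, gen_size = 120)
  qs <- inst$qs
  split <- mask_validation(qs$ped, 3)
  y_train <- inst$y[split$training_ids]
  fit <- gblup(y_train, inst$K)
  ebv_masked <- predict(fit, ids = split$masked_ids)
  expect_length(ebv_masked, 120)
  # predictions correlate with the (withheld) simulated true breeding values
  tbv <- stats::setNames(qs$truth$tbv_T1, qs$truth$id)[split$masked_ids]
  expect_gt(stats::cor(ebv_masked, tbv), 0.3)
})

test_that("degenerate inputs are rejected with clear errors", {
  inst <- fit_instance(107, gen_size = 40)
  expect_error(gblup(unname(inst$y), inst$K), "named")
  expect_error(gblup(inst$y[1:10], inst$K), "at least 30")
  y_bad <- inst$y
  names(y_bad)[1] <- "ghost"
  expect_error(gblup(y_bad, inst$K), "absent from K")
})
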