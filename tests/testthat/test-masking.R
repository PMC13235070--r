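test_that("forward split partitions the population", {
  qs <- quick_sim(n_generations = 3, gen_size = 50, seed = 41)
  sp <- mask_validation(qs$ped, 3, phenotypes = qs$pheno)
  expect_setequal(c(sp$training_ids, sp$masked_ids), qs$ped$id)
  expect_length(intersect(sp$training_ids, sp$masked_ids), 0)
  expect_equal(length(sp$masked_ids), 50)
  expect_equal(length(sp$training_ids), 100)
  # masked view withholds trait values but keeps ids/factors; truth intact
  expect_true(all(is.na(sp$masked$T1)))
  expect_false(anyNA(sp$masked_truth$T1))
  expect_identical(sp$masked$id, sp$masked_truth$id)
  # the stored phenotype table is untouched
  expect_false(anyNA(qs$pheno$T1))
})

test_that("degenerate split targets are rejected", {
  qs <- quick_sim(n_generations = 2, gen_size = 30, seed = 42)
  expect_error(mask_validation(qs$ped, 1), "first generation")
  expect_error(mask_validation(qs$ped, 9), "empty")
})

test_that("published line counts fall out of the line-shaped configs", {
  ped <- sim_pedigree(sim_config_line_a(seed = 43))
  sp <- mask_validation(ped, 6)
  expect_equal(length(sp$training_ids), 9579)
  expect_equal(length(sp$masked_ids), 4066)
})

test_that("low-density panel masking hides exactly the right entries", {
  qs <- quick_sim(n_generations = 2, gen_size = 120, snps = 60, n_chr = 2,
                  seed = 44)
  panel <- colnames(qs$geno$dosage)[seq(1, 120, by = 6)]  # 20-SNP panel
  mk <- mask_genotypes(qs$geno, n_individuals = 50, panel_snps = panel,
                       seed = 44)
  expect_length(mk$masked_ids, 50)
  view <- mk$masked_geno$dosage
  hidden <- setdiff(colnames(view), panel)
  expect_true(all(is.na(view[mk$masked_ids, hidden])))
  expect_false(anyNA(view[mk$masked_ids, panel]))
  expect_false(anyNA(view[setdiff(rownames(view), mk$masked_ids), ]))
  # truth preserves the original values
  expect_identical(mk$truth, qs$geno$dosage[mk$masked_ids, ])
  expect_error(mask_genotypes(qs$geno, 10000, panel), "exceeds")
  expect_error(mask_genotypes(qs$geno, 10, c(panel, "no_such_snp")), "subset")
})

test_that("an all-SNP panel hides nothing and evaluates to accuracy 1", {
  qs <- quick_sim(n_generations = 2, gen_size = 60, snps = 30, n_chr = 1,
                  seed = 45)
  mk <- mask_genotypes(qs$geno, 20, colnames(qs$geno$dosage), seed = 45)
  expect_identical(mk$masked_geno$dosage, qs$geno$dosage)
  acc <- imputation_accuracy(qs$geno, mk$masked_geno, mk$masked_ids)
  expect_equal(acc$genome_mean, 1)
})

test_that("the parent-average imputer beats the population-mean imputer", {
  # compared on overall dosage correlation over the hidden entries: the
  # population-mean fill is constant per SNP, so its per-SNP correlations are
  # all undefined and only the pooled correlation is comparable
  wins <- 0L
  for (rep in 1:20) {
    qs <- quick_sim(n_generations = 2, gen_size = 80, snps = 40, n_chr = 2,
                    seed = 500 + rep)
    offspring <- qs$ped$id[qs$ped$generation == 2]
    panel <- colnames(qs$geno$dosage)[seq(1, 80, by = 8)]
    # mask offspring only so parents stay fully genotyped
    mk <- mask_genotypes(qs$geno, 40, panel, seed = rep, ids = offspring)
    pa <- impute_parent_average(mk$masked_geno, qs$ped)
    pm <- impute_population_mean(mk$masked_geno)
    hidden <- setdiff(colnames(qs$geno$dosage), panel)
    truth <- as.vector(qs$geno$dosage[mk$masked_ids, hidden])
    r_pa <- stats::cor(truth, as.vector(pa$dosage[mk$masked_ids, hidden]))
    r_pm <- stats::cor(truth, as.vector(pm$dosage[mk$masked_ids, hidden]))
    wins <- wins + (r_pa > r_pm)
  }
  expect_gt(wins, 15)   # parent information must help on most replicates
})
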