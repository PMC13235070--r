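#' Forward-prediction split: mask a target generation
#'
#' Splits individuals into a training set (all generations before the target)
#' and a masked validation set (the target generation), the commercial
#' selection-candidate scenario: juveniles without phenotypes are predicted
#' from earlier phenotyped and genotyped generations. Only visibility changes;
#' no stored values are altered.
#'
#' @param ped Pedigree `data.frame`.
#' @param target_generation Generation whose phenotypes are withheld.
#' @param line Optional line restriction.
#' @param phenotypes Optional phenotype `data.frame` (column `id`) to split.
#' @return A list: `training_ids`, `masked_ids`, and when phenotypes are
#'   supplied, `training` and `masked` row subsets (the masked subset retains
#'   ids and factors but has all trait columns set `NA`), plus `masked_truth`
#'   with the withheld rows intact.
#' @examples
#' ped <- sim_pedigree(sim_config(n_generations = 3, gen_sizes = c(20, 30, 30),
#'                                n_lines = 1, seed = 21))
#' sp <- mask_validation(ped, target_generation = 3)
#' length(sp$masked_ids)
#' @export
mask_validation <- function(ped, target_generation, line = NULL,
                            phenotypes = NULL) {
  if (!is.null(line)) ped <- ped[ped$line %in% line, , drop = FALSE]
  gens <- ped$generation
  if (!target_generation %in% gens)
    stop(sprintf("target generation %s is empty", target_generation))
  if (target_generation <= min(gens))
    stop("target generation is the first generation: no earlier training data")
  masked_ids <- ped$id[gens == target_generation]
  training_ids <- ped$id[gens < target_generation]
  out <- list(training_ids = training_ids, masked_ids = masked_ids)
  if (!is.null(phenotypes)) {
    stopifnot("id" %in% names(phenotypes))
    out$training <- phenotypes[phenotypes$id %in% training_ids, , drop = FALSE]
    truth <- phenotypes[phenotypes$id %in% masked_ids, , drop = FALSE]
    masked <- truth
    trait_cols <- setdiff(names(masked),
                          c("id", "sexhatch", "damage", "pen"))
    masked[trait_cols] <- NA_real_
    out$masked <- masked
    out$masked_truth <- truth
  }
  out
}

#' Mask genotypes down to a low-density panel
#'
#' Emulates the evaluation protocol for imputation accuracy: a set of
#' individuals keeps only a low-density SNP panel (all other markers set
#' missing) while the withheld truth is stored for the evaluator
#' ([imputation_accuracy()]). Stored genotypes are never altered, only the
#' returned view.
#'
#' @param geno A [sim_genotypes()] result.
#' @param n_individuals Number of individuals to mask (sampled at random).
#' @param panel_snps Character vector of SNP ids retained on the low-density
#'   panel (must be a subset of the markers).
#' @param seed Integer seed for the individual draw.
#' @param ids Optional pool of candidate individuals to mask (default: all
#'   rows); the usual protocol masks the youngest genotyped birds while their
#'   ancestors stay fully observed.
#' @return A list: `masked_geno` (a `geno_matrix` whose dosage has `NA`
#'   outside the panel for the masked individuals), `masked_ids`, `truth`
#'   (the original dosage rows of the masked individuals).
#' @export
mask_genotypes <- function(geno, n_individuals, panel_snps, seed = 1L,
                           ids = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  M <- geno$dosage
  pool <- ids %||% rownames(M)
  if (!all(pool %in% rownames(M))) stop("'ids' must be genotyped individuals")
  if (n_individuals > length(pool))
    stop(sprintf("n_individuals (%d) exceeds candidate pool size (%d)",
                 n_individuals, length(pool)))
  if (!all(panel_snps %in% colnames(M)))
    stop("panel_snps must be a subset of the marker set")
  set.seed(seed)
  masked_ids <- sample(pool, n_individuals)
  truth <- M[masked_ids, , drop = FALSE]
  hidden <- setdiff(colnames(M), panel_snps)
  out <- geno
  out$dosage[masked_ids, hidden] <- NA_integer_
  list(masked_geno = out, masked_ids = masked_ids, truth = truth)
}

#' Naive baseline imputers
#'
#' Reference points for imputation-accuracy evaluation, not production
#' imputation. `impute_population_mean()` fills each missing dosage with the
#' SNP's mean observed dosage. `impute_parent_average()` fills it with the
#' average of the parents' (non-missing) dosages at that SNP, falling back to
#' the population mean when neither parent is available.
#'
#' @param geno A `geno_matrix` with missing dosages.
#' @param ped Pedigree `data.frame` (parent lookup).
#' @return A `geno_matrix` with no missing dosages.
#' @export
impute_population_mean <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  M <- geno$dosage
  storage.mode(M) <- "double"
  means <- colMeans(M, na.rm = TRUE)
  na <- which(is.na(M), arr.ind = TRUE)
  if (nrow(na)) M[na] <- means[na[, 2]]
  geno$dosage <- M
  geno
}

#' @rdname impute_population_mean
#' @export
impute_parent_average <- function(geno, ped) {
  stopifnot(inherits(geno, "geno_matrix"))
  M <- geno$dosage
  storage.mode(M) <- "double"
  means <- colMeans(M, na.rm = TRUE)
  fill <- M
  ped <- ped[match(rownames(M), ped$id), , drop = FALSE]
  for (i in seq_len(nrow(M))) {
    miss <- is.na(M[i, ])
    if (!any(miss)) next
    s <- ped$sire[i]; d <- ped$dam[i]
    ps <- if (!is.na(s) && s %in% rownames(M)) M[s, ] else rep(NA_real_, ncol(M))
    pd <- if (!is.na(d) && d %in% rownames(M)) M[d, ] else rep(NA_real_, ncol(M))
    pa <- rowMeans(cbind(ps, pd), na.rm = TRUE)   # NaN when both missing
    v <- ifelse(is.nan(pa), means, pa)
    fill[i, miss] <- v[miss]
  }
  geno$dosage <- fill
  geno
}
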