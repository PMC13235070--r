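#' Predictive correlation and accuracy
#'
#' Forward-prediction accuracy: the Pearson correlation `r` between predicted
#' breeding values and adjusted phenotypes over the validation individuals,
#' divided by the square root of the heritability estimated on the training
#' generations with the same relationship matrix.
#'
#' @param ebv Named vector of predicted breeding values (phenotype-masked
#'   fit), covering the validation individuals.
#' @param y_star Named vector of adjusted phenotypes for the validation
#'   individuals.
#' @param h2_training Training-generation heritability (> 0).
#' @return A list: `r_val`, `accuracy`.
#' @examples
#' # r = 0.29 at h2 = 0.25 gives accuracy 0.58
#' prediction_accuracy_from(r_val = 0.29, h2_training = 0.25)
#' @export
prediction_accuracy <- function(ebv, y_star, h2_training) {
  ids <- intersect(names(y_star), names(ebv))
  if (length(ids) < 30L) stop("need at least 30 validation individuals")
  r <- stats::cor(ebv[ids], y_star[ids])
  c(prediction_accuracy_from(r, h2_training), list(n = length(ids)))
}

#' @rdname prediction_accuracy
#' @param r_val A precomputed predictive correlation (used when the EBVs and
#'   phenotypes themselves are not at hand, e.g. recomputing published
#'   tables).
#' @export
prediction_accuracy_from <- function(r_val, h2_training) {
  if (is.na(h2_training) || h2_training <= 0) {
    warning("non-positive heritability: accuracy undefined")
    return(list(r_val = r_val, accuracy = NA_real_))
  }
  list(r_val = r_val, accuracy = r_val / sqrt(h2_training))
}

#' Dispersion bias of predicted breeding values
#'
#' The slope of the ordinary least-squares regression of whole-data EBVs
#' ("true" EBVs, estimated with the validation phenotypes unmasked) on
#' partial-data EBVs (validation phenotypes masked), over the validation
#' individuals, with both sets from the same relationship matrix. A slope of 1
#' is unbiased; below 1 the masked EBVs are overdispersed (overestimated),
#' above 1 underdispersed.
#'
#' @param ebv_whole,ebv_partial Named EBV vectors covering `validation_ids`.
#' @param validation_ids Individuals over which the regression runs.
#' @return The slope `b`.
#' @export
dispersion_bias <- function(ebv_whole, ebv_partial, validation_ids) {
  bad <- setdiff(validation_ids, intersect(names(ebv_whole), names(ebv_partial)))
  if (length(bad))
    stop("validation individuals missing from EBV sets: ",
         paste(utils::head(bad, 5), collapse = ", "))
  x <- ebv_partial[validation_ids]
  y <- ebv_whole[validation_ids]
  if (stats::var(x) == 0) {
    warning("zero-variance predictor EBVs: dispersion slope undefined")
    return(NA_real_)
  }
  unname(stats::coef(stats::lm(y ~ x))[2])
}

#' Standardized bias
#'
#' Maps the dispersion slope `b` onto a symmetric scale:
#' `1 - b` when `b < 1` and `1/b - 1` when `b >= 1`. Zero means unbiased;
#' positive values indicate overestimation, negative underestimation. The two
#' branches agree (both 0) at `b = 1`. For `b` in (0, 2\] the result lies in
#' (-1, 1\]; a negative `b` falls through the first branch and exceeds 1,
#' which is flagged with a warning rather than clipped.
#'
#' @param b Dispersion slope(s), finite.
#' @return `b_std`, same length as `b`.
#' @examples
#' standardized_bias(c(0.81, 1.22, 1))  # 0.19, -0.18, 0
#' @export
standardized_bias <- function(b) {
  if (any(!is.finite(b))) stop("'b' must be finite")
  if (any(b < 0))
    warning("negative dispersion slope: standardized bias exceeds 1 (out of range)")
  ifelse(b < 1, 1 - b, 1 / b - 1)
}

#' Imputation accuracy evaluator
#'
#' Per-SNP Pearson correlation between true and imputed dosages across the
#' masked individuals, with per-chromosome and genome-wide means. SNPs whose
#' true or imputed dosages have zero variance across the masked individuals
#' have undefined correlation; they are excluded from the means and counted.
#'
#' @param true_geno,imputed_geno Dosage matrices (or `geno_matrix` objects)
#'   sharing ids and SNP columns.
#' @param masked_ids Individuals whose genotypes were masked and imputed.
#' @param map Optional map `data.frame` (`snp`, `chr`) for chromosome means.
#' @return A list of class `imputation_accuracy`: `per_snp` (`data.frame` of
#'   `snp`, optional `chr`, `correlation`), `chromosome_mean`, `genome_mean`,
#'   `n_undefined`.
#' @export
imputation_accuracy <- function(true_geno, imputed_geno, masked_ids,
                                map = NULL) {
  Tm <- if (inherits(true_geno, "geno_matrix")) true_geno$dosage else as.matrix(true_geno)
  Im <- if (inherits(imputed_geno, "geno_matrix")) imputed_geno$dosage else as.matrix(imputed_geno)
  if (is.null(map) && inherits(true_geno, "geno_matrix")) map <- true_geno$map
  if (!length(masked_ids)) stop("no masked individuals")
  bad <- setdiff(masked_ids, intersect(rownames(Tm), rownames(Im)))
  if (length(bad))
    stop("masked individuals missing from genotype sets: ",
         paste(utils::head(bad, 5), collapse = ", "))
  snps <- intersect(colnames(Tm), colnames(Im))
  if (!length(snps)) stop("true and imputed matrices share no SNPs")
  Tm <- Tm[masked_ids, snps, drop = FALSE]
  Im <- Im[masked_ids, snps, drop = FALSE]
  corr <- vapply(seq_along(snps), function(j) {
    x <- Tm[, j]; y <- Im[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  }, 0)
  per_snp <- data.frame(snp = snps, correlation = corr,
                        stringsAsFactors = FALSE)
  chrom_mean <- NULL
  if (!is.null(map)) {
    per_snp$chr <- map$chr[match(snps, map$snp)]
    chrom_mean <- tapply(per_snp$correlation, per_snp$chr,
                         mean, na.rm = TRUE)
  }
  structure(list(per_snp = per_snp, chromosome_mean = chrom_mean,
                 genome_mean = mean(corr, na.rm = TRUE),
                 n_undefined = sum(is.na(corr))),
            class = "imputation_accuracy")
}

#' @export
print.imputation_accuracy <- function(x, ...) {
  cat(sprintf("Imputation accuracy over %d SNPs: genome mean r = %.4f (%d undefined)\n",
              nrow(x$per_snp), x$genome_mean, x$n_undefined))
  if (!is.null(x$chromosome_mean)) {
    cat("  per-chromosome means:\n")
    print(round(x$chromosome_mean, 4))
  }
  invisible(x)
}

#' Forward-prediction validation of an evaluation
#'
#' Runs the full forward-prediction protocol for one or more traits and
#' relationship matrices: fit the animal model on the training generations
#' only (phenotypes of the target generation masked), predict the masked
#' individuals' breeding values through their kernel rows, refit with all
#' phenotypes to obtain the whole-data ("true") EBVs, then compute the
#' predictive correlation, accuracy (using the training-fit heritability of
#' the matching kernel), dispersion slope `b` and standardized bias.
#'
#' @param y_star_list Named list (per trait) of adjusted-phenotype vectors
#'   covering training and validation individuals (see [precorrect_all()]).
#' @param kernels Named list of relationship matrices, e.g.
#'   `list(G = ..., A = ...)`; every matrix must cover all individuals.
#' @param ped Pedigree `data.frame` (defines the generations).
#' @param target_generation Generation to mask and predict.
#' @param line Optional line restriction.
#' @return A `data.frame` of class `validation_report`: one row per trait x
#'   kernel with `trait`, `matrix`, `h2`, `h2_se`, `r_val`, `accuracy`, `b`,
#'   `b_std`, `n_train`, `n_masked`.
#' @seealso [gblup()], [mask_validation()]
#' @export
forward_validate <- function(y_star_list, kernels, ped, target_generation,
                             line = NULL) {
  if (is.null(names(kernels))) stop("'kernels' must be a named list")
  split <- mask_validation(ped, target_generation, line = line)
  rows <- list()
  for (tn in names(y_star_list)) {
    y_all <- y_star_list[[tn]]
    if (inherits(y_all, "precorrect")) y_all <- y_all$y_star
    y_train <- y_all[intersect(names(y_all), split$training_ids)]
    val_ids <- intersect(names(y_all), split$masked_ids)
    for (kn in names(kernels)) {
      K <- kernels[[kn]]
      fit_partial <- gblup(y_train, K)
      fit_whole <- gblup(y_all, K)
      ebv_p <- predict(fit_partial)
      ebv_w <- predict(fit_whole)
      pa <- prediction_accuracy(ebv_p, y_all[val_ids], fit_partial$vc$h2)
      b <- dispersion_bias(ebv_w, ebv_p, val_ids)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tn, matrix = kn,
        h2 = fit_partial$vc$h2, h2_se = fit_partial$vc$h2_se,
        r_val = pa$r_val, accuracy = pa$accuracy,
        b = b, b_std = standardized_bias(b),
        n_train = length(y_train), n_masked = length(val_ids),
        stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, rows)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' Render a validation report in the two-kernel table layout
#'
#' One row per trait with the G-matrix column block followed by the A-matrix
#' block, each ordered `h2, se, r, acc, b, b_std` — the layout of published
#' genomic-selection validation tables.
#'
#' @param report A [forward_validate()] result (or same-shaped data.frame).
#' @param digits Rounding for display.
#' @return A `data.frame` in wide layout (invisible for the print method).
#' @export
report_wide <- function(report, digits = 2) {
  cols <- c("h2", "h2_se", "r_val", "accuracy", "b", "b_std")
  kinds <- intersect(c("G", "A"), unique(report$matrix))
  traits <- unique(report$trait)
  out <- data.frame(trait = traits, stringsAsFactors = FALSE)
  for (kn in kinds) {
    sub <- report[report$matrix == kn, , drop = FALSE]
    sub <- sub[match(traits, sub$trait), cols, drop = FALSE]
    names(sub) <- paste(c("h2", "se", "r", "acc", "b", "b_std"), kn, sep = "_")
    out <- cbind(out, round(sub, digits))
  }
  rownames(out) <- NULL
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Forward-prediction validation report\n")
  print(report_wide(x))
  # internal audit: accuracy column must equal r / sqrt(h2)
  drift <- max(abs(x$accuracy - x$r_val / sqrt(x$h2)), na.rm = TRUE)
  if (is.finite(drift) && drift > 1e-8)
    warning("internal inconsistency: accuracy != r/sqrt(h2)")
  invisible(x)
}
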