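#' Default fixed-effect model per trait
#'
#' The trait-to-model map used for pre-correction: juvenile weight, primary
#' feather length, gait and foot-pad score are corrected for `sexhatch` (the
#' sex-by-hatch interaction fitted as one combined factor) and dam-age class;
#' slaughter body weight and breast depth additionally for finishing `pen`,
#' with breast depth also carrying body weight as a covariate. Average daily
#' gain is not listed with either model in the source description; it defaults
#' to the sexhatch + dam-age terms and can be overridden.
#'
#' @return Named list of specs, each with `factors` and `covariates`.
#' @export
default_trait_models <- function() {
  eq1 <- list(factors = c("sexhatch", "damage"), covariates = character(0))
  eq2 <- list(factors = c("sexhatch", "damage", "pen"), covariates = character(0))
  list(JW = eq1, PRF = eq1, GAIT = eq1, FPD = eq1, ADG = eq1,
       BW = eq2,
       BD = list(factors = c("sexhatch", "damage", "pen"), covariates = "BW"))
}

#' Pre-correct phenotypes for fixed effects
#'
#' Fits an ordinary least-squares model with intercept, treatment-coded
#' factors and optional covariates, and returns the residuals `y*` — the
#' adjusted phenotypes subsequently used as the response of the single-kernel
#' animal model. Rows with missing response, factor or covariate values are
#' dropped. Aliased (rank-deficient) design columns are dropped with a
#' warning, as `lm()` does.
#'
#' @param phenotypes `data.frame` with `id`, the trait column and the model
#'   terms.
#' @param trait Name of the trait column.
#' @param factors Character vector of factor names (default from
#'   [default_trait_models()], falling back to `sexhatch` + `damage`).
#' @param covariates Character vector of numeric covariate names.
#' @return A list of class `precorrect`:
#'   \describe{
#'     \item{y_star}{named numeric vector of residuals (mean zero).}
#'     \item{model}{the underlying `lm` fit.}
#'     \item{spec}{list(trait, factors, covariates).}
#'   }
#' @examples
#' d <- data.frame(id = sprintf("x%d", 1:8), y = rnorm(8),
#'                 sexhatch = gl(2, 4), damage = gl(2, 2, 8))
#' pc <- precorrect(d, "y")
#' round(mean(pc$y_star), 12)
#' @export
precorrect <- function(phenotypes, trait,
                       factors = NULL, covariates = NULL) {
  stopifnot("id" %in% names(phenotypes), trait %in% names(phenotypes))
  if (is.null(factors)) {
    dm <- default_trait_models()[[trait]]
    factors <- if (!is.null(dm)) dm$factors else c("sexhatch", "damage")
    if (is.null(covariates)) covariates <- if (!is.null(dm)) dm$covariates
  }
  covariates <- covariates %||% character(0)
  if (trait %in% covariates) stop("a trait cannot be its own covariate")
  terms <- c(factors, covariates)
  missing_cols <- setdiff(terms, names(phenotypes))
  if (length(missing_cols))
    stop("missing model columns: ", paste(missing_cols, collapse = ", "))
  dat <- phenotypes[, c("id", trait, terms), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  for (f in factors) {
    dat[[f]] <- factor(dat[[f]])
    if (nlevels(dat[[f]]) < 1L) stop("factor with no observed levels: ", f)
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste0("`", trait, "` ~ ", rhs))
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit))))
    warning("rank-deficient design: aliased columns dropped")
  y_star <- stats::setNames(stats::residuals(fit), dat$id)
  structure(list(y_star = y_star, model = fit,
                 spec = list(trait = trait, factors = factors,
                             covariates = covariates)),
            class = "precorrect")
}

#' @export
print.precorrect <- function(x, ...) {
  cat(sprintf("Pre-correction for %s: %d records, terms: %s\n",
              x$spec$trait, length(x$y_star),
              paste(c(x$spec$factors, x$spec$covariates), collapse = " + ")))
  cat(sprintf("  residual SD %.4g, residual mean %.2e\n",
              stats::sd(x$y_star), mean(x$y_star)))
  invisible(x)
}

#' Pre-correct every trait in a phenotype table
#'
#' @param phenotypes Phenotype `data.frame` (see [sim_phenotypes()]).
#' @param traits Trait columns to adjust (default: every column that has a
#'   model in `models`).
#' @param models Trait-to-model map as from [default_trait_models()].
#' @return Named list of [precorrect()] results.
#' @export
precorrect_all <- function(phenotypes, traits = NULL,
                           models = default_trait_models()) {
  if (is.null(traits))
    traits <- intersect(names(models), names(phenotypes))
  out <- lapply(traits, function(tn) {
    dm <- models[[tn]] %||% list(factors = c("sexhatch", "damage"),
                                 covariates = character(0))
    precorrect(phenotypes, tn, dm$factors, dm$covariates)
  })
  stats::setNames(out, traits)
}
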