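#' Define a simulated trait architecture
#'
#' A trait is generated as `mean + fixed effects + TBV + residual`, where the
#' true breeding value (TBV) is a dosage-weighted sum of zero-mean normal
#' effects at `n_causal` randomly chosen markers, rescaled so that the realized
#' TBV variance is exactly `target_h2 * phenotypic_sd^2`, and the residual is
#' drawn with variance `(1 - target_h2) * phenotypic_sd^2`. Ordinal traits
#' (gait and foot-pad scores in the duck setting) can be generated as Gaussian
#' liabilities cut into five classes at equiprobable thresholds; downstream
#' models still analyse the scores as linear traits.
#'
#' @param trait_name Trait label (e.g. `"JW"`, `"BW"`, `"GAIT"`).
#' @param target_h2 Narrow-sense heritability in \[0, 1\] the generator aims at.
#' @param n_causal Number of causal markers.
#' @param phenotypic_mean,phenotypic_sd Trait mean and total SD (trait units).
#' @param fixed_effect_sizes Named list mapping factor name (`sexhatch`,
#'   `damage`, `pen`) to a numeric vector of per-level effects. `NULL` entries
#'   are drawn by the generator: per-level effects normal with SD equal to 25%
#'   (sexhatch) or 10% (dam age, pen) of the phenotypic SD — large enough that
#'   skipping pre-correction visibly corrupts downstream estimates, small
#'   enough to keep the phenotype scale recognisable.
#' @param ordinal Cut the continuous phenotype into `n_classes` ordinal scores?
#' @param n_classes Number of ordinal classes (default 5).
#' @return An object of class `trait_architecture`.
#' @examples
#' trait_architecture("JW", target_h2 = 0.23, n_causal = 100,
#'                    phenotypic_mean = 567.15, phenotypic_sd = 86.27)
#' @export
trait_architecture <- function(trait_name, target_h2, n_causal,
                               phenotypic_mean, phenotypic_sd,
                               fixed_effect_sizes = NULL,
                               ordinal = FALSE, n_classes = 5L) {
  if (target_h2 < 0 || target_h2 > 1) stop("'target_h2' must be in [0, 1]")
  if (phenotypic_sd <= 0) stop("'phenotypic_sd' must be positive")
  if (n_causal < 1L) stop("'n_causal' must be >= 1")
  structure(list(trait_name = trait_name, target_h2 = target_h2,
                 n_causal = as.integer(n_causal),
                 phenotypic_mean = phenotypic_mean,
                 phenotypic_sd = phenotypic_sd,
                 fixed_effect_sizes = fixed_effect_sizes,
                 ordinal = ordinal, n_classes = as.integer(n_classes)),
            class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf("Trait %s: h2 = %.2f, %d causal SNPs, mean %.2f, SD %.2f%s\n",
              x$trait_name, x$target_h2, x$n_causal, x$phenotypic_mean,
              x$phenotypic_sd,
              if (x$ordinal) sprintf(", ordinal 1-%d", x$n_classes) else ""))
  invisible(x)
}

#' Default duck trait architectures
#'
#' The seven traits recorded in the two Pekin duck lines the package emulates:
#' juvenile weight (JW, g), slaughter body weight (BW, g), ultrasonic breast
#' depth (BD, mm), primary feather length (PRF, mm), gait score (GAIT, 1-5),
#' average daily gain (ADG, g/day) and foot-pad dermatitis score (FPD, 1-5).
#' Means and SDs follow the published line descriptive statistics, and the
#' default heritability targets follow the published marker-based estimates
#' (line A: 0.23, 0.33, 0.17, 0.25, 0.07, 0.17, 0.25; line D analogous); see
#' [duck_reference_tables()].
#'
#' @param line `"A"` or `"D"`.
#' @param n_causal Causal markers per trait.
#' @param ordinal_scores Generate GAIT and FPD as 5-class ordinal scores
#'   (default) or keep them continuous.
#' @return Named list of [trait_architecture()] objects.
#' @export
duck_trait_architectures <- function(line = c("A", "D"), n_causal = 200L,
                                     ordinal_scores = TRUE) {
  line <- match.arg(line)
  ref <- merge(duck_reference_tables("descriptives"),
               duck_reference_tables("heritability")[, c("line", "trait", "h2_g")],
               by = c("line", "trait"))
  ref <- ref[ref$line == line, ]
  archs <- lapply(seq_len(nrow(ref)), function(i) {
    trait_architecture(ref$trait[i], target_h2 = ref$h2_g[i],
                       n_causal = n_causal,
                       phenotypic_mean = ref$mean[i],
                       phenotypic_sd = ref$sd[i],
                       ordinal = ordinal_scores && ref$trait[i] %in% c("GAIT", "FPD"))
  })
  stats::setNames(archs, ref$trait)
}

#' Simulate phenotypes and true breeding values
#'
#' Generates one phenotype column per trait architecture plus the fixed-effect
#' factors `sexhatch` (sex crossed with hatch batch), `damage` (dam-age class)
#' and `pen`, shared across traits. Factor levels are assigned at random per
#' bird; per-level effect sizes come from each architecture (or the generator
#' defaults, see [trait_architecture()]).
#'
#' @param ped Pedigree ([sim_pedigree()]).
#' @param geno Genotypes ([sim_genotypes()]) for the same individuals.
#' @param archs A single [trait_architecture()] or a (named) list of them.
#' @param config The [sim_config()] (supplies factor level counts).
#' @param seed Integer seed for all phenotype draws.
#' @return A list with
#'   \describe{
#'     \item{phenotypes}{`data.frame`: `id`, one column per trait, `sexhatch`,
#'       `damage`, `pen`.}
#'     \item{truth}{`data.frame`: `id` and `tbv_<trait>` columns (true
#'       simulated breeding values, centered; continuous even for ordinal
#'       traits).}
#'     \item{causal}{per-trait `data.frame` of causal SNP ids and effects
#'       (on the rescaled, trait-unit scale).}
#'     \item{fixed_effects}{per-trait list of realized per-level effects.}
#'   }
#' @examples
#' cfg <- sim_config(n_generations = 2, gen_sizes = c(30, 50), n_lines = 1,
#'                   n_chromosomes = 2, snps_per_chromosome = 50, seed = 5)
#' ped <- sim_pedigree(cfg)
#' geno <- sim_genotypes(ped, cfg)
#' arch <- trait_architecture("JW", 0.3, 20, 567, 86)
#' sim <- sim_phenotypes(ped, geno, arch, cfg, seed = 5)
#' head(sim$phenotypes)
#' @export
sim_phenotypes <- function(ped, geno, archs, config, seed = config$seed) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (inherits(archs, "trait_architecture")) archs <- list(archs)
  if (is.null(names(archs)))
    names(archs) <- vapply(archs, `[[`, "", "trait_name")
  M <- geno$dosage[ped$id, , drop = FALSE]
  n <- nrow(M)
  m <- ncol(M)
  set.seed(seed)

  hatch <- sample.int(config$n_hatches, n, replace = TRUE)
  sexhatch <- factor(paste0(ped$sex, hatch),
                     levels = paste0(rep(c("F", "M"), each = config$n_hatches),
                                     seq_len(config$n_hatches)))
  damage <- factor(sample.int(config$n_dam_age_classes, n, replace = TRUE),
                   levels = seq_len(config$n_dam_age_classes))
  pen <- factor(sample.int(config$n_pens, n, replace = TRUE),
                levels = seq_len(config$n_pens))
  fac <- list(sexhatch = sexhatch, damage = damage, pen = pen)

  pheno <- data.frame(id = ped$id, stringsAsFactors = FALSE)
  truth <- data.frame(id = ped$id, stringsAsFactors = FALSE)
  causal_out <- list()
  fe_out <- list()

  default_fe_sd <- c(sexhatch = 0.25, damage = 0.10, pen = 0.10)

  for (tn in names(archs)) {
    a <- archs[[tn]]
    if (a$n_causal > m) stop("n_causal exceeds number of markers")
    cidx <- sample.int(m, a$n_causal)
    eff <- stats::rnorm(a$n_causal)
    Z <- scale(M[, cidx, drop = FALSE], center = TRUE, scale = FALSE)
    g <- drop(Z %*% eff)
    vg <- stats::var(g)
    target_vg <- a$target_h2 * a$phenotypic_sd^2
    sc <- if (vg > 0 && target_vg > 0) sqrt(target_vg / vg) else 0
    tbv <- g * sc
    tbv <- tbv - mean(tbv)

    fe_total <- numeric(n)
    fe_real <- list()
    for (f in names(fac)) {
      lev <- levels(fac[[f]])
      sizes <- a$fixed_effect_sizes[[f]]
      if (is.null(sizes))
        sizes <- stats::rnorm(length(lev), 0, default_fe_sd[[f]] * a$phenotypic_sd)
      if (length(sizes) != length(lev))
        stop(sprintf("fixed_effect_sizes$%s must have %d levels", f, length(lev)))
      names(sizes) <- lev
      fe_real[[f]] <- sizes
      fe_total <- fe_total + sizes[as.character(fac[[f]])]
    }

    e <- stats::rnorm(n, 0, sqrt((1 - a$target_h2)) * a$phenotypic_sd)
    y <- a$phenotypic_mean + fe_total + tbv + e
    if (a$ordinal) {
      br <- stats::quantile(y, probs = seq(0, 1, length.out = a$n_classes + 1L))
      br[1] <- -Inf; br[length(br)] <- Inf
      y <- as.numeric(cut(y, breaks = br, labels = FALSE, include.lowest = TRUE))
    }
    pheno[[tn]] <- unname(y)
    truth[[paste0("tbv_", tn)]] <- tbv
    causal_out[[tn]] <- data.frame(snp = colnames(M)[cidx],
                                   effect = eff * sc,
                                   stringsAsFactors = FALSE)
    fe_out[[tn]] <- fe_real
  }

  pheno$sexhatch <- sexhatch
  pheno$damage <- damage
  pheno$pen <- pen
  list(phenotypes = pheno, truth = truth, causal = causal_out,
       fixed_effects = fe_out)
}
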