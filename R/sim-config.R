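#' Simulation configuration for a closed breeding program
#'
#' Describes a breeding program with discrete, non-overlapping generations and
#' open-pen random mating: every non-founder draws one sire and one dam at
#' random from the previous generation of its own line. Lines are simulated as
#' independent founder pools whose founder allele frequencies are allowed to
#' diverge, which is what separates the lines on the first genotype principal
#' component.
#'
#' @param n_generations Number of discrete generations (>= 1). Founders are
#'   generation 1; parents are unknown only in generation 1.
#' @param gen_sizes Integer vector of length `n_generations`: number of birds
#'   born into each generation *per line*.
#' @param n_lines Number of independent lines (default 2).
#' @param n_chromosomes Number of chromosomes carrying markers.
#' @param snps_per_chromosome Markers per chromosome, evenly spaced on the
#'   genetic map.
#' @param chromosome_length_morgan Genetic length of each chromosome in Morgan
#'   (default 1); recombination follows a Haldane (no-interference) model.
#' @param founder_maf_range Lower and upper bound of the uniform law from which
#'   founder minor allele frequencies are drawn; both in (0, 0.5].
#' @param line_divergence Standard deviation, on the logit-frequency scale, of
#'   independent per-line perturbations applied to the shared ancestral
#'   frequencies. 0 gives identical founder pools; around 1 gives clearly
#'   separated lines.
#' @param n_hatches Number of hatch batches per generation (crossed with sex to
#'   form the `sexhatch` fixed effect).
#' @param n_pens Number of finishing pens.
#' @param n_dam_age_classes Number of dam-age classes (categorical).
#' @param seed Integer seed recorded in the configuration; all simulation draws
#'   are reproducible from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_generations = 3, gen_sizes = c(50, 80, 80),
#'                   n_chromosomes = 2, snps_per_chromosome = 100, seed = 1)
#' cfg
#' @export
sim_config <- function(n_generations = 4,
                       gen_sizes = rep(500L, n_generations),
                       n_lines = 2L,
                       n_chromosomes = 10L,
                       snps_per_chromosome = 200L,
                       chromosome_length_morgan = 1,
                       founder_maf_range = c(0.05, 0.5),
                       line_divergence = 0.8,
                       n_hatches = 4L,
                       n_pens = 10L,
                       n_dam_age_classes = 5L,
                       seed = 1L) {
  n_generations <- as.integer(n_generations)
  gen_sizes <- as.integer(gen_sizes)
  if (n_generations < 1L) stop("'n_generations' must be >= 1")
  if (length(gen_sizes) != n_generations)
    stop("'gen_sizes' must have length 'n_generations'")
  if (any(gen_sizes <= 0L)) stop("all generation sizes must be positive")
  if (n_lines < 1L) stop("'n_lines' must be >= 1")
  if (n_chromosomes < 1L || snps_per_chromosome < 1L)
    stop("marker map must contain at least one chromosome and one SNP")
  if (length(founder_maf_range) != 2L ||
      founder_maf_range[1] <= 0 || founder_maf_range[2] > 0.5 ||
      founder_maf_range[1] > founder_maf_range[2])
    stop("'founder_maf_range' must satisfy 0 < low <= high <= 0.5")
  if (chromosome_length_morgan <= 0) stop("chromosome length must be positive")
  cfg <- list(
    n_generations = n_generations,
    gen_sizes = gen_sizes,
    n_lines = as.integer(n_lines),
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chromosome = as.integer(snps_per_chromosome),
    chromosome_length_morgan = chromosome_length_morgan,
    founder_maf_range = founder_maf_range,
    line_divergence = line_divergence,
    n_hatches = as.integer(n_hatches),
    n_pens = as.integer(n_pens),
    n_dam_age_classes = as.integer(n_dam_age_classes),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Breeding-program simulation configuration\n")
  cat(sprintf("  lines: %d, generations: %d, sizes per line: %s\n",
              x$n_lines, x$n_generations, paste(x$gen_sizes, collapse = ", ")))
  cat(sprintf("  markers: %d chromosomes x %d SNPs (%.1f M each, Haldane)\n",
              x$n_chromosomes, x$snps_per_chromosome, x$chromosome_length_morgan))
  cat(sprintf("  founder MAF ~ U(%.2f, %.2f), line divergence %.2f, seed %d\n",
              x$founder_maf_range[1], x$founder_maf_range[2],
              x$line_divergence, x$seed))
  invisible(x)
}

#' Line-shaped default configurations
#'
#' Configurations shaped like the two commercial Pekin duck lines the package
#' emulates: line A has six generations with 9,579 birds in generations 1-5 and
#' 4,066 selection candidates in generation 6; line D has five generations with
#' 8,134 birds in generations 1-4 and 4,885 in generation 5. Only those totals
#' are published; the per-generation split used here is an invented breakdown
#' that sums to them.
#'
#' These are single-line configurations at full population scale, intended for
#' structural work (pedigree shape, masking counts). Marker counts default to a
#' small map; scale `snps_per_chromosome` up as needed.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @examples
#' ped <- sim_pedigree(sim_config_line_a(seed = 7))
#' table(ped$generation)
#' @export
sim_config_line_a <- function(...) {
  defaults <- list(n_generations = 6L,
                   gen_sizes = c(1361L, 1640L, 1804L, 2254L, 2520L, 4066L),
                   n_lines = 1L, seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

#' @rdname sim_config_line_a
#' @export
sim_config_line_d <- function(...) {
  defaults <- list(n_generations = 5L,
                   gen_sizes = c(1121L, 1648L, 2004L, 3361L, 4885L),
                   n_lines = 1L, seed = 2L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
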