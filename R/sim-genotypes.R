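#' Simulate SNP genotypes by gene dropping
#'
#' Drops alleles down the pedigree. Founder haplotypes are drawn per SNP from
#' the line's founder allele frequencies; every descendant receives one
#' recombined gamete from each parent. Recombination follows the Haldane
#' (no-interference) model on a uniform genetic map: crossovers per chromosome
#' are Poisson with mean equal to the map length in Morgan, at positions
#' uniform on the chromosome, and the starting parental haplotype of each
#' gamete is chosen at random.
#'
#' Founder frequencies are built from a shared ancestral frequency per SNP
#' (uniform on `config$founder_maf_range`) perturbed independently per line on
#' the logit scale with standard deviation `config$line_divergence`, so lines
#' drift apart as that parameter grows.
#'
#' @param ped A pedigree from [sim_pedigree()] (or of the same shape).
#' @param config The [sim_config()] describing the marker map.
#' @param keep_haplotypes Keep the two haplotype matrices in the result (used
#'   by transmission checks; doubles memory).
#' @param founder_freq Optional founder allele-frequency override: a vector
#'   (one frequency per SNP, recycled across lines) or a lines x SNPs matrix
#'   in \[0, 1\]. Replaces the drawn frequencies; a frequency of 1 fixes the
#'   alternate allele.
#' @return An object of class `geno_matrix`: a list with
#'   \describe{
#'     \item{dosage}{individuals x SNPs integer matrix of alternate-allele
#'       dosages 0/1/2, dimnames = (ids, SNP ids); no missing values.}
#'     \item{map}{`data.frame` with `snp`, `chr`, `pos_morgan`, `pos_bp`,
#'       `ref`, `alt`.}
#'     \item{founder_freq}{per-line matrix of founder alternate-allele
#'       frequencies (lines x SNPs).}
#'     \item{haplotypes}{if requested, list of two 0/1 matrices.}
#'   }
#' @examples
#' cfg <- sim_config(n_generations = 2, gen_sizes = c(20, 30), n_lines = 1,
#'                   n_chromosomes = 2, snps_per_chromosome = 25, seed = 3)
#' geno <- sim_genotypes(sim_pedigree(cfg), cfg)
#' dim(geno$dosage)
#' @export
sim_genotypes <- function(ped, config, keep_haplotypes = FALSE,
                          founder_freq = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_pedigree(ped)
  m_chr <- config$snps_per_chromosome
  n_chr <- config$n_chromosomes
  m <- m_chr * n_chr
  if (m < 1L) stop("empty marker map")
  L <- config$chromosome_length_morgan
  set.seed(config$seed + 1L)

  map <- data.frame(
    snp = sprintf("chr%d_snp%d", rep(seq_len(n_chr), each = m_chr),
                  rep(seq_len(m_chr), n_chr)),
    chr = rep(seq_len(n_chr), each = m_chr),
    pos_morgan = rep(seq(0, L, length.out = m_chr), n_chr),
    stringsAsFactors = FALSE
  )
  map$pos_bp <- as.integer(round(map$pos_morgan * 1e6)) + 1L
  map$ref <- "A"
  map$alt <- "B"

  # ancestral frequencies, perturbed per line on the logit scale
  lines <- sort(unique(ped$line))
  p_anc <- stats::runif(m, config$founder_maf_range[1], config$founder_maf_range[2])
  flip <- stats::runif(m) < 0.5   # minor allele is ref or alt at random
  p_anc[flip] <- 1 - p_anc[flip]
  if (is.null(founder_freq)) {
    founder_freq <- matrix(NA_real_, length(lines), m,
                           dimnames = list(lines, map$snp))
    for (l in lines) {
      eps <- stats::rnorm(m, 0, config$line_divergence)
      founder_freq[l, ] <- stats::plogis(stats::qlogis(p_anc) + eps)
    }
  } else {
    if (!is.matrix(founder_freq)) {
      if (length(founder_freq) != m)
        stop("'founder_freq' must supply one frequency per SNP (per line)")
      founder_freq <- matrix(founder_freq, length(lines), m, byrow = TRUE)
    }
    if (ncol(founder_freq) != m || nrow(founder_freq) != length(lines))
      stop("'founder_freq' must supply one frequency per SNP (per line)")
    if (any(founder_freq < 0 | founder_freq > 1))
      stop("'founder_freq' values must lie in [0, 1]")
    dimnames(founder_freq) <- list(lines, map$snp)
  }

  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  h1 <- matrix(0L, n, m, dimnames = list(ped$id, map$snp))
  h2 <- h1
  chr_pos <- split(seq_len(m), map$chr)
  founder_gen <- stats::ave(ped$generation, ped$line, FUN = min)

  gamete <- function(pa, pb) {
    # one recombined gamete from haplotypes pa, pb (integer vectors length m)
    g <- integer(m)
    for (cp in chr_pos) {
      pos <- map$pos_morgan[cp]
      k <- stats::rpois(1L, L)
      phase0 <- stats::rbinom(1L, 1L, 0.5)
      if (k == 0L) {
        phase <- rep.int(phase0, length(cp))
      } else {
        xo <- sort(stats::runif(k, 0, L))
        phase <- (phase0 + findInterval(pos, xo)) %% 2L
      }
      g[cp] <- pa[cp]
      from_b <- cp[phase == 1L]
      g[from_b] <- pb[from_b]
    }
    g
  }

  for (i in seq_len(n)) {
    if (ped$generation[i] == founder_gen[i]) {
      p <- founder_freq[ped$line[i], ]
      h1[i, ] <- stats::rbinom(m, 1L, p)
      h2[i, ] <- stats::rbinom(m, 1L, p)
    } else {
      si <- idx[[ped$sire[i]]]
      di <- idx[[ped$dam[i]]]
      h1[i, ] <- gamete(h1[si, ], h2[si, ])
      h2[i, ] <- gamete(h1[di, ], h2[di, ])
    }
  }

  out <- list(dosage = h1 + h2, map = map, founder_freq = founder_freq)
  if (keep_haplotypes) out$haplotypes <- list(h1 = h1, h2 = h2)
  class(out) <- "geno_matrix"
  out
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("SNP genotypes: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chr))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing: %.2f%%; dosage coding 0/1/2 (alt-allele count)\n",
              100 * miss))
  invisible(x)
}

#' Subset a genotype object
#'
#' @param x A `geno_matrix`.
#' @param ids,snps Identifiers (or logical/integer indices) of rows / markers
#'   to keep; `NULL` keeps all.
#' @return A `geno_matrix` restricted to the selection.
#' @export
subset_geno <- function(x, ids = NULL, snps = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  if (is.null(ids)) ids <- rownames(x$dosage)
  if (is.null(snps)) snps <- colnames(x$dosage)
  x$dosage <- x$dosage[ids, snps, drop = FALSE]
  keep <- match(colnames(x$dosage), x$map$snp)
  x$map <- x$map[keep, , drop = FALSE]
  if (!is.null(x$founder_freq))
    x$founder_freq <- x$founder_freq[, colnames(x$dosage), drop = FALSE]
  if (!is.null(x$haplotypes))
    x$haplotypes <- lapply(x$haplotypes,
                           function(h) h[ids, snps, drop = FALSE])
  x
}
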