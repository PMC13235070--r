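#' Allele frequency from dosages
#'
#' Frequency of the counted (alternate) allele, `sum(dosage) / (2 * n_called)`,
#' ignoring missing calls.
#'
#' @param x A dosage vector (one SNP) or an individuals x SNPs dosage matrix.
#' @return A frequency in \[0, 1\], or a per-SNP named vector for a matrix.
#'   SNPs with no non-missing call return `NA`.
#' @examples
#' allele_frequency(c(0, 1, 2))        # 0.5
#' allele_frequency(c(0, 0, 1, 1))     # 0.25
#' @export
allele_frequency <- function(x) {
  if (is.matrix(x)) {
    called <- colSums(!is.na(x))
    f <- colSums(x, na.rm = TRUE) / (2 * called)
    f[called == 0L] <- NA_real_
    return(f)
  }
  called <- sum(!is.na(x))
  if (called == 0L) return(NA_real_)
  sum(x, na.rm = TRUE) / (2 * called)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of Hardy-Weinberg proportions: conditioning on the
#' observed allele counts, the p-value is the total probability of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count (Wigginton-style enumeration, no mid-p correction).
#' Monomorphic SNPs return p = 1 by convention.
#'
#' @param nAA,nAB,nBB Genotype counts (non-negative; total > 0).
#' @return The exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(0, 1, 0)    # 1: the only configuration with one of each allele
#' hwe_exact_test(50, 0, 50)  # extreme heterozygote deficit, p << 1e-6
#' @export
hwe_exact_test <- function(nAA, nAB, nBB) {
  if (any(c(nAA, nAB, nBB) < 0)) stop("genotype counts must be non-negative")
  n <- nAA + nAB + nBB
  if (n == 0) stop("total genotype count must be positive")
  nA <- 2L * nAA + nAB
  nB <- 2L * nBB + nAB
  r <- min(nA, nB)                       # rare allele count
  if (r == 0L) return(1)                 # monomorphic
  # heterozygote counts share the parity of r and range up to r
  het <- seq.int(r %% 2L, r, by = 2L)
  # log conditional probability up to a constant:
  # P(nAB | nA, n) ~ n! / (nAA! nAB! nBB!) * 2^nAB
  aa <- (nA - het) / 2L
  bb <- (nB - het) / 2L
  logp <- het * log(2) - lgamma(aa + 1) - lgamma(het + 1) - lgamma(bb + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(nAB, het)]
  if (is.na(obs)) stop("observed heterozygote count inconsistent with allele counts")
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' SNP quality control
#'
#' Removes SNPs whose minor allele frequency falls below `maf_min` (strict
#' inequality) or whose exact Hardy-Weinberg p-value falls below
#' `hwe_threshold` (strict). Boundary values equal to either threshold are
#' retained. Filtering is per-SNP and order-preserving.
#'
#' @param geno A [sim_genotypes()] result, or a dosage matrix.
#' @param maf_min Minimum minor allele frequency retained (default 0.05).
#' @param hwe_threshold Minimum exact HWE p-value retained (default 1e-6).
#' @return A list with
#'   \describe{
#'     \item{kept}{character vector of retained SNP ids, original order.}
#'     \item{summary}{`data.frame` per SNP: `snp`, `chr` (if known), `maf`,
#'       `hwe_p`, `n_called`, `kept`.}
#'     \item{geno}{the input restricted to the kept SNPs (same type).}
#'   }
#' @examples
#' cfg <- sim_config(n_generations = 2, gen_sizes = c(50, 50), n_lines = 1,
#'                   n_chromosomes = 2, snps_per_chromosome = 50, seed = 11)
#' geno <- sim_genotypes(sim_pedigree(cfg), cfg)
#' qc <- filter_snps(geno)
#' table(qc$summary$kept)
#' @export
filter_snps <- function(geno, maf_min = 0.05, hwe_threshold = 1e-6) {
  M <- if (inherits(geno, "geno_matrix")) geno$dosage else as.matrix(geno)
  if (length(M) == 0L) stop("empty genotype matrix")
  freq <- allele_frequency(M)
  maf <- pmin(freq, 1 - freq)
  hwe_p <- apply(M, 2, function(d) {
    d <- d[!is.na(d)]
    if (!length(d)) return(NA_real_)
    hwe_exact_test(sum(d == 2L), sum(d == 1L), sum(d == 0L))
  })
  n_called <- colSums(!is.na(M))
  kept <- !is.na(maf) & maf >= maf_min & hwe_p >= hwe_threshold
  summ <- data.frame(snp = colnames(M),
                     maf = unname(maf), hwe_p = unname(hwe_p),
                     n_called = unname(n_called), kept = unname(kept),
                     stringsAsFactors = FALSE)
  if (inherits(geno, "geno_matrix"))
    summ <- cbind(summ[, "snp", drop = FALSE],
                  chr = geno$map$chr[match(summ$snp, geno$map$snp)],
                  summ[, -1, drop = FALSE])
  if (!any(kept))
    stop(sprintf("all %d SNPs removed by QC (min MAF seen %.3g, min HWE p %.3g)",
                 ncol(M), suppressWarnings(min(maf, na.rm = TRUE)),
                 suppressWarnings(min(hwe_p, na.rm = TRUE))))
  out_geno <- if (inherits(geno, "geno_matrix")) {
    subset_geno(geno, snps = colnames(M)[kept])
  } else M[, kept, drop = FALSE]
  list(kept = colnames(M)[kept], summary = summ, geno = out_geno)
}

#' Descriptive statistics for a trait
#'
#' The computable columns of a line descriptive-statistics table: n, mean,
#' sample SD (n-1 denominator), bias-corrected sample skewness, bias-corrected
#' excess kurtosis, coefficient of variation `100 * sd / mean` (%), and
#' standard error of the mean `sd / sqrt(n)`.
#'
#' @param x Numeric vector, no missing values, length > 3.
#' @param trait Optional trait label carried into the result.
#' @return A one-row `data.frame`: `trait`, `n`, `mean`, `sd`, `skewness`,
#'   `kurtosis`, `cv`, `se`. With zero variance, skewness and kurtosis are
#'   `NA` with a warning.
#' @examples
#' describe_trait(c(-1, 0, 1))  # symmetric: skewness 0
#' @export
describe_trait <- function(x, trait = NA_character_) {
  if (anyNA(x)) stop("missing values in trait vector")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    warning("zero variance: skewness and kurtosis undefined")
    g1 <- G1 <- g2 <- G2 <- NA_real_
  } else {
    m2 <- mean((x - m)^2)
    g1 <- mean((x - m)^3) / m2^1.5
    g2 <- mean((x - m)^4) / m2^2 - 3
    # bias-corrected sample estimators (as reported by SAS and friends)
    G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
    G2 <- if (n > 3L) ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)) else NA_real_
  }
  data.frame(trait = trait, n = n, mean = m, sd = s,
             skewness = G1, kurtosis = G2,
             cv = if (m != 0) 100 * s / m else NA_real_,
             se = s / sqrt(n), stringsAsFactors = FALSE)
}
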