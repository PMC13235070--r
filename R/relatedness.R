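#' Pedigree numerator relationship matrix (A)
#'
#' Expected additive relationships from the pedigree by the tabular method:
#' individuals are processed parents-before-offspring, each new row is the
#' average of the parental rows (`A[i, j] = 0.5 * (A[i, s(j)] + A[i, d(j)])`,
#' unknown parents contributing zero) and the diagonal is
#' `1 + 0.5 * A[s(j), d(j)]`, i.e. one plus the inbreeding coefficient.
#'
#' @param ped A pedigree `data.frame` (`id`, `sire`, `dam`, `generation`,
#'   `line`); sorted internally so parents precede offspring.
#' @return A symmetric matrix with `dimnames` set to the pedigree ids,
#'   attribute `kind = "A"` and `ridge = 0`.
#' @examples
#' ped <- data.frame(id = c("s", "d", "o"), sire = c(NA, NA, "s"),
#'                   dam = c(NA, NA, "d"), generation = c(1, 1, 2),
#'                   line = "A")
#' a_matrix(ped)["s", "o"]  # parent-offspring: 0.5
#' @export
a_matrix <- function(ped) {
  validate_pedigree(ped)
  ord <- order(ped$generation)
  ped <- ped[ord, , drop = FALSE]
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]   # NA where unknown
  di <- idx[ped$dam]
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1L) {
      prev <- seq_len(j - 1L)
      rs <- if (!is.na(s)) A[prev, s] else 0
      rd <- if (!is.na(d)) A[prev, d] else 0
      aj <- 0.5 * (rs + rd)
      A[prev, j] <- aj
      A[j, prev] <- aj
    }
    A[j, j] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  structure(A, kind = "A", ridge = 0)
}

#' VanRaden genomic relationship matrix (G)
#'
#' Method 1 of VanRaden: with `M` the dosage matrix and `P` the row of twice
#' the allele frequencies, `Z = M - 2P` and
#' `G = Z Z' / (2 * sum(p * (1 - p)))`. Missing dosages are mean-imputed per
#' SNP before centering. By default frequencies are observed frequencies
#' computed from all individuals supplied (training and validation birds are
#' all genotyped in the breeding program this models; base-population
#' frequencies are unavailable).
#'
#' @param geno A [sim_genotypes()] result or dosage matrix (post-QC).
#' @param freqs Optional per-SNP allele frequencies in (0, 1); defaults to
#'   observed frequencies.
#' @return A symmetric matrix with individual ids as `dimnames`, attribute
#'   `kind = "G"` and `ridge = 0`.
#' @examples
#' M <- rbind(a = c(2, 0), b = c(0, 2))
#' colnames(M) <- c("s1", "s2")
#' g_matrix(M, freqs = c(0.5, 0.5))
#' @export
g_matrix <- function(geno, freqs = NULL) {
  M <- if (inherits(geno, "geno_matrix")) geno$dosage else as.matrix(geno)
  if (is.null(freqs)) freqs <- allele_frequency(M)
  if (length(freqs) != ncol(M)) stop("one frequency per SNP required")
  if (anyNA(freqs)) stop("undefined allele frequencies (all-missing SNPs?)")
  denom <- 2 * sum(freqs * (1 - freqs))
  if (denom <= 0)
    stop("all SNPs monomorphic at the supplied frequencies: G undefined")
  if (anyNA(M)) {
    means <- colMeans(M, na.rm = TRUE)
    na <- which(is.na(M), arr.ind = TRUE)
    M[na] <- means[na[, 2]]
  }
  Z <- sweep(M, 2, 2 * freqs)
  G <- tcrossprod(Z) / denom
  structure(G, kind = "G", ridge = 0)
}

#' Ridge-regularize a relationship matrix
#'
#' Adds `ridge` to the diagonal only when the smallest eigenvalue falls below
#' `tol`, recording the amount in the `ridge` attribute and emitting a
#' message. This is the package's sole conditioning device ahead of REML/BLUP;
#' no blending of G with A is performed.
#'
#' @param K Symmetric relationship matrix ([a_matrix()], [g_matrix()] or
#'   plain).
#' @param ridge Diagonal increment (default 0.01).
#' @param tol Smallest admissible eigenvalue (default 1e-8).
#' @return `K`, possibly shifted, with updated `ridge` attribute.
#' @export
regularize_kinship <- function(K, ridge = 0.01, tol = 1e-8) {
  if (!isSymmetric(unclass(K), tol = 1e-8)) stop("K must be symmetric")
  lam_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (lam_min >= tol) {
    attr(K, "ridge") <- attr(K, "ridge") %||% 0
    return(K)
  }
  message(sprintf(
    "regularize_kinship: smallest eigenvalue %.3g < %.1g; adding ridge %g to diagonal",
    lam_min, tol, ridge))
  out <- K + diag(ridge, nrow(K))
  dimnames(out) <- dimnames(K)
  attr(out, "kind") <- attr(K, "kind")
  attr(out, "ridge") <- (attr(K, "ridge") %||% 0) + ridge
  out
}

#' Principal component analysis of SNP genotypes
#'
#' PCA of the column-centered dosage matrix (optionally standardized by
#' `sqrt(2p(1-p))` per SNP), as used to visualise population structure.
#'
#' @param geno A [sim_genotypes()] result or dosage matrix.
#' @param k Number of components to keep (truncated to the rank, with a
#'   warning, if larger).
#' @param standardize `"center"` (default, visualization-style) or `"freq"`
#'   (frequency-standardized).
#' @return A list of class `geno_pca`: `scores` (individuals x k),
#'   `variance_explained` (percent per retained component, non-increasing) and
#'   `sdev` (all singular values / sqrt(n - 1)).
#' @examples
#' cfg <- sim_config(n_generations = 1, gen_sizes = 40, n_lines = 2,
#'                   n_chromosomes = 2, snps_per_chromosome = 100,
#'                   line_divergence = 2, seed = 9)
#' p <- geno_pca(sim_genotypes(sim_pedigree(cfg), cfg), k = 2)
#' p$variance_explained
#' @export
geno_pca <- function(geno, k = 10, standardize = c("center", "freq")) {
  standardize <- match.arg(standardize)
  M <- if (inherits(geno, "geno_matrix")) geno$dosage else as.matrix(geno)
  if (nrow(M) < 2L || ncol(M) < 2L) stop("need at least 2 individuals and 2 SNPs")
  if (anyNA(M)) {
    means <- colMeans(M, na.rm = TRUE)
    na <- which(is.na(M), arr.ind = TRUE)
    M[na] <- means[na[, 2]]
  }
  X <- scale(M, center = TRUE, scale = FALSE)
  if (standardize == "freq") {
    p <- allele_frequency(M)
    s <- sqrt(2 * p * (1 - p))
    keep <- s > 0
    X <- sweep(X[, keep, drop = FALSE], 2, s[keep], "/")
  }
  total_var <- sum(X^2) / (nrow(X) - 1)
  if (total_var == 0) {
    warning("all individuals identical: degenerate PCA, zero total variance")
    return(structure(list(scores = matrix(0, nrow(M), 0),
                          variance_explained = numeric(0), sdev = numeric(0),
                          degenerate = TRUE), class = "geno_pca"))
  }
  pr <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  rank <- sum(pr$sdev > pr$sdev[1] * 1e-12)
  if (k > rank) {
    warning(sprintf("k = %d exceeds rank %d; truncating", k, rank))
    k <- rank
  }
  scores <- pr$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(M)
  ve <- 100 * pr$sdev[seq_len(k)]^2 / sum(pr$sdev^2)
  structure(list(scores = scores, variance_explained = ve, sdev = pr$sdev,
                 degenerate = FALSE), class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Genotype PCA: degenerate (zero total variance)\n")
    return(invisible(x))
  }
  cat(sprintf("Genotype PCA: %d individuals, %d components retained\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  variance explained (%):",
      paste(sprintf("%.2f", x$variance_explained), collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
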