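#' Read and write the package's tabular formats
#'
#' Pedigrees and phenotypes travel as tab-separated text with a header.
#' Pedigree columns: `id sire dam generation line sex`, missing parents
#' encoded `0`. Phenotype tables: `id`, one column per trait, then the factor
#' columns.
#'
#' @param ped,phenotypes Objects to write.
#' @param file Path.
#' @name tsv_io
#' @return Readers return a `data.frame` (pedigree with class `pedigree`);
#'   writers return the path invisibly.
NULL

#' @rdname tsv_io
#' @export
write_pedigree <- function(ped, file) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname tsv_io
#' @export
read_pedigree <- function(file) {
  ped <- utils::read.delim(file, stringsAsFactors = FALSE,
                           colClasses = c(id = "character", sire = "character",
                                          dam = "character"))
  ped$sire[ped$sire %in% "0"] <- NA_character_
  ped$dam[ped$dam %in% "0"] <- NA_character_
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' @rdname tsv_io
#' @export
write_phenotypes <- function(phenotypes, file) {
  utils::write.table(phenotypes, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname tsv_io
#' @export
read_phenotypes <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE,
                    colClasses = c(id = "character"))
}

#' Write genotypes as VCF
#'
#' Emits a biallelic VCF (GT field only) through the vcfR package. Missing
#' dosages become `./.`; dosage 1 is written as the unphased heterozygote
#' `0/1`.
#'
#' @param geno A `geno_matrix` (see [sim_genotypes()]).
#' @param file Output path; vcfR writes gzip-compressed VCF, so a `.vcf.gz`
#'   name is conventional.
#' @return The path, invisibly.
#' @export
write_vcf <- function(geno, file) {
  stopifnot(inherits(geno, "geno_matrix"))
  M <- geno$dosage
  map <- geno$map
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", ncol(M), nrow(M),
               dimnames = list(NULL, rownames(M)))
  ok <- !is.na(t(M))
  gt[ok] <- gt_code[as.character(t(M)[ok])]
  fix <- cbind(CHROM = as.character(map$chr), POS = as.character(map$pos_bp),
               ID = map$snp, REF = map$ref, ALT = map$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  meta <- c("##fileformat=VCFv4.2",
            "##source=gsforward",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  vcf <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                      meta = meta, fix = fix,
                      gt = cbind(FORMAT = "GT", gt))
  vcfR::write.vcf(vcf, file = file)
  invisible(file)
}

#' Read genotypes from VCF
#'
#' Reads a biallelic VCF with vcfR and converts GT calls to alternate-allele
#' dosages 0/1/2 (`NA` for missing).
#'
#' @param file VCF path (plain or gzipped).
#' @return A `geno_matrix` (without founder frequencies).
#' @export
read_vcf <- function(file) {
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(g) {
    out <- rep(NA_integer_, length(g))
    known <- !is.na(g) & !grepl("\\.", g)
    alleles <- strsplit(gsub("\\|", "/", g[known]), "/", fixed = FALSE)
    out[known] <- vapply(alleles, function(a) sum(a == "1"), 0L)
    out
  }
  dos <- apply(gt, 2, count_alt)
  rownames(dos) <- rownames(gt)
  M <- t(dos)
  fix <- vcfR::getFIX(vcf)
  map <- data.frame(snp = fix[, "ID"], chr = as.integer(fix[, "CHROM"]),
                    pos_morgan = NA_real_,
                    pos_bp = as.integer(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  colnames(M) <- map$snp
  structure(list(dosage = M, map = map, founder_freq = NULL),
            class = "geno_matrix")
}

#' Write and read PLINK text PED/MAP
#'
#' The classic whitespace-separated PLINK text pair: `.map` with
#' `chr snp cM bp` and `.ped` with `FID IID PAT MAT SEX PHENO` followed by two
#' allele columns per SNP (`A` = reference, `B` = alternate; missing genotype
#' `0 0`).
#'
#' @param geno A `geno_matrix`.
#' @param prefix Path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @param ped Optional pedigree supplying parent/sex columns.
#' @return `write_plink()` the prefix, invisibly; `read_plink()` a
#'   `geno_matrix`.
#' @name plink_io
#' @export
write_plink <- function(geno, prefix, ped = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  M <- geno$dosage
  map <- geno$map
  utils::write.table(
    data.frame(map$chr, map$snp, map$pos_morgan * 100, map$pos_bp),
    paste0(prefix, ".map"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(M)
  ids <- rownames(M)
  if (!is.null(ped)) {
    ped <- ped[match(ids, ped$id), , drop = FALSE]
    pat <- ifelse(is.na(ped$sire), "0", ped$sire)
    mat <- ifelse(is.na(ped$dam), "0", ped$dam)
    sex <- ifelse(ped$sex == "M", 1L, 2L)
  } else {
    pat <- mat <- rep("0", n)
    sex <- rep(0L, n)
  }
  # dosage -> two allele columns per SNP
  a1 <- matrix("0", n, ncol(M))
  a2 <- matrix("0", n, ncol(M))
  a1[M == 0] <- "A"; a2[M == 0] <- "A"
  a1[M == 1] <- "A"; a2[M == 1] <- "B"
  a1[M == 2] <- "B"; a2[M == 2] <- "B"
  alleles <- matrix("", n, 2L * ncol(M))
  alleles[, seq(1, 2 * ncol(M), by = 2)] <- a1
  alleles[, seq(2, 2 * ncol(M), by = 2)] <- a2
  out <- cbind(FID = "0", IID = ids, PAT = pat, MAT = mat,
               SEX = sex, PHENO = "-9", alleles)
  utils::write.table(out, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname plink_io
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                           col.names = c("chr", "snp", "cM", "pos_bp"),
                           stringsAsFactors = FALSE)
  raw <- utils::read.table(paste0(prefix, ".ped"), header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  ids <- raw[[2]]
  al <- as.matrix(raw[, -(1:6), drop = FALSE])
  m <- nrow(map)
  if (ncol(al) != 2L * m) stop("PED allele columns do not match MAP")
  a1 <- al[, seq(1, 2 * m, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * m, by = 2), drop = FALSE]
  dos <- (a1 == "B") + (a2 == "B")
  dos[a1 == "0" | a2 == "0"] <- NA
  dimnames(dos) <- list(ids, map$snp)
  mapdf <- data.frame(snp = map$snp, chr = map$chr,
                      pos_morgan = map$cM / 100, pos_bp = map$pos_bp,
                      ref = "A", alt = "B", stringsAsFactors = FALSE)
  structure(list(dosage = dos, map = mapdf, founder_freq = NULL),
            class = "geno_matrix")
}

#' Write a relationship matrix in long format
#'
#' @param K Relationship matrix with id dimnames.
#' @param file Output TSV path (`id_i`, `id_j`, `value`; upper triangle
#'   including the diagonal).
#' @return The path, invisibly.
#' @export
write_kinship_long <- function(K, file) {
  ut <- upper.tri(K, diag = TRUE)
  idx <- which(ut, arr.ind = TRUE)
  out <- data.frame(id_i = rownames(K)[idx[, 1]],
                    id_j = colnames(K)[idx[, 2]],
                    value = K[ut], stringsAsFactors = FALSE)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
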