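#' Published reference values for the two Pekin duck lines
#'
#' Summary tables reported for the two commercial Pekin duck lines (A and D)
#' whose breeding program this package emulates; the underlying records are
#' commercially confidential, so only these printed summaries are available.
#' They serve two purposes: as default parameters for the synthetic-data
#' generator ([duck_trait_architectures()]) and as worked-example inputs for
#' the arithmetic the package implements (coefficient of variation, standard
#' error, heritability ratios, prediction accuracy and standardized bias).
#'
#' @param which One of
#'   \describe{
#'     \item{`"descriptives"`}{per-line trait descriptive statistics: `n`,
#'       `mean`, `sd` (sample SD), `skewness`, `kurtosis` (excess), `cv` (%)
#'       and `se`, as printed. Note the line D JW `se` of 0.06 is inconsistent
#'       with `sd/sqrt(n)` (≈ 0.58) and is carried as printed; treat it as a
#'       known misprint.}
#'     \item{`"heritability"`}{whole-data heritability estimates per trait from
#'       the marker-based (G) and pedigree (A) animal models, their SEs and the
#'       printed G/A ratio.}
#'     \item{`"forward_metrics"`}{forward-prediction results per line, trait
#'       and relationship matrix: training-generation heritability `h2` and
#'       `se`, predictive correlation `r`, accuracy `acc = r/sqrt(h2)`,
#'       dispersion slope `b` and standardized bias `b_std`.}
#'   }
#' @return A `data.frame`.
#' @examples
#' head(duck_reference_tables("heritability"))
#' @export
duck_reference_tables <- function(which = c("descriptives", "heritability",
                                            "forward_metrics")) {
  which <- match.arg(which)
  file <- switch(which,
                 descriptives = "duck_descriptive_stats.tsv",
                 heritability = "duck_heritability.tsv",
                 forward_metrics = "duck_forward_metrics.tsv")
  path <- system.file("extdata", file, package = "gsforward", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
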