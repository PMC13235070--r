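#' Simulate a multi-generation pedigree
#'
#' Builds a pedigree with discrete, non-overlapping generations under open-pen
#' random mating: each non-founder draws one sire and one dam uniformly from
#' the males and females of the previous generation of its own line. Sexes are
#' assigned in (near-)equal numbers within each generation, so every generation
#' used as parents contains both sexes.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` of class `c("pedigree", "data.frame")` with columns
#'   `id`, `sire`, `dam` (NA for founders), `generation` (1-based; parents are
#'   unknown iff generation 1), `line` and `sex` (`"M"`/`"F"`).
#' @examples
#' ped <- sim_pedigree(sim_config(n_generations = 3, gen_sizes = c(10, 20, 20),
#'                                n_lines = 1, seed = 42))
#' head(ped)
#' @seealso [sim_genotypes()], [a_matrix()]
#' @export
sim_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  out <- vector("list", config$n_lines)
  for (l in seq_len(config$n_lines)) {
    line <- LETTERS[l]
    gens <- vector("list", config$n_generations)
    prev <- NULL
    for (g in seq_len(config$n_generations)) {
      n <- config$gen_sizes[g]
      id <- sprintf("%s_G%d_%04d", line, g, seq_len(n))
      # balanced sexes in random order; guarantees parents of both sexes
      sex <- sample(rep_len(c("M", "F"), n))
      if (g == 1L) {
        sire <- dam <- NA_character_
      } else {
        males <- prev$id[prev$sex == "M"]
        females <- prev$id[prev$sex == "F"]
        if (length(males) < 1L || length(females) < 1L)
          stop(sprintf("generation %d of line %s lacks parents of both sexes",
                       g - 1L, line))
        sire <- sample(males, n, replace = TRUE)
        dam <- sample(females, n, replace = TRUE)
      }
      gens[[g]] <- data.frame(id = id, sire = sire, dam = dam,
                              generation = g, line = line, sex = sex,
                              stringsAsFactors = FALSE)
      prev <- gens[[g]]
    }
    out[[l]] <- do.call(rbind, gens)
  }
  ped <- do.call(rbind, out)
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate pedigree structure
#'
#' Checks the invariants every pedigree consumed by the package must satisfy:
#' unique ids; parents unknown exactly for the founder (first) generation of
#' each line; every known parent recorded in the immediately preceding
#' generation of the same line (which rules out cycles); sexes consistent with
#' parental roles when known.
#'
#' @param ped A pedigree `data.frame` (columns `id`, `sire`, `dam`,
#'   `generation`, `line`; `sex` optional).
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_pedigree <- function(ped) {
  req <- c("id", "sire", "dam", "generation", "line")
  if (!all(req %in% names(ped)))
    stop("pedigree must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(ped$id)) stop("pedigree ids are not unique")
  gen <- ped$generation
  row <- seq_len(nrow(ped))
  idx <- stats::setNames(row, ped$id)
  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    known <- !is.na(p) & p != "0" & p != ""
    founder_gen <- stats::ave(gen, ped$line, FUN = min)
    if (any(!known & gen > founder_gen))
      stop("non-founder rows with unknown ", col)
    if (any(known & gen == founder_gen))
      stop("founder rows with a known ", col)
    if (any(known)) {
      pi <- idx[p[known]]
      if (anyNA(pi)) stop("unknown ", col, " id(s): ",
                          paste(utils::head(p[known][is.na(pi)], 5), collapse = ", "))
      if (any(gen[pi] >= gen[known]))
        stop(col, " not in a strictly earlier generation")
      if (any(ped$line[pi] != ped$line[known]))
        stop(col, " from a different line")
      if ("sex" %in% names(ped)) {
        want <- if (col == "sire") "M" else "F"
        if (any(ped$sex[pi] != want)) stop(col, "s with inconsistent sex")
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d individuals, %d line(s), generations %d-%d\n",
              nrow(x), length(unique(x$line)), min(x$generation),
              max(x$generation)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
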