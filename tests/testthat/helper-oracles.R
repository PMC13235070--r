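# Independent oracles and small fixture builders. Each oracle is a direct,
# slow implementation of the definition, kept free of the code paths it
# checks.

# random multi-generation pedigree: parents drawn from the previous generation
random_pedigree <- function(n_generations, gen_size, seed = 1L) {
  sim_pedigree(sim_config(n_generations = n_generations,
                          gen_sizes = rep(gen_size, n_generations),
                          n_lines = 1L, seed = seed))
}

# additive relationship by the recursive definition, memoized; ids assumed
# sorted parents-before-offspring is NOT required (pure recursion on parents)
a_matrix_oracle <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  memo <- matrix(NA_real_, n, n)
  rel <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    val <- if (i == j) {
      1 + 0.5 * (if (!is.na(si[i]) && !is.na(di[i])) rel(si[i], di[i]) else 0)
    } else {
      # recurse on the younger individual (larger generation, else larger row)
      if (ped$generation[i] < ped$generation[j]) {
        a <- if (!is.na(si[j])) rel(i, si[j]) else 0
        b <- if (!is.na(di[j])) rel(i, di[j]) else 0
        0.5 * (a + b)
      } else {
        a <- if (!is.na(si[i])) rel(j, si[i]) else 0
        b <- if (!is.na(di[i])) rel(j, di[i]) else 0
        0.5 * (a + b)
      }
    }
    memo[i, j] <<- val
    memo[j, i] <<- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- rel(i, j)
  A
}

# exact HWE p-value by direct enumeration of every genotype configuration
# consistent with the allele counts, probabilities from choose()
hwe_oracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  if (min(nA, 2 * n - nA) == 0) return(1)
  het <- seq.int(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(het, function(ab) {
    aa <- (nA - ab) / 2
    bb <- n - aa - ab
    choose(n, aa) * choose(n - aa, ab) * 2^ab
  }, 0)
  pr <- pr / sum(pr)
  obs <- pr[match(nAB, het)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# dense-matrix REML log-likelihood of the intercept animal model
dense_reml_loglik <- function(y, K, sigma2_g, sigma2_e) {
  n <- length(y)
  X <- matrix(1, n, 1)
  V <- sigma2_g * K[names(y), names(y)] + sigma2_e * diag(n)
  Vi <- solve(V)
  XVX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  -0.5 * ((n - 1) * log(2 * pi) + determinant(V)$modulus[1] +
            log(XVX[1, 1]) + drop(t(y) %*% P %*% y))
}

# Henderson mixed-model equations: phenotyped individuals carry records,
# every individual in K gets a breeding value
mme_solve <- function(y, K, sigma2_g, sigma2_e) {
  ids <- rownames(K)
  n <- length(y)
  q <- length(ids)
  X <- matrix(1, n, 1)
  Z <- matrix(0, n, q, dimnames = list(names(y), ids))
  Z[cbind(seq_len(n), match(names(y), ids))] <- 1
  lambda <- sigma2_e / sigma2_g
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * solve(K)))
  rhs <- rbind(crossprod(X, y), crossprod(Z, y))
  sol <- solve(C, rhs)
  list(mu = sol[1, 1], u = stats::setNames(sol[-1, 1], ids))
}

# one-call simulated data set: pedigree, genotypes, a single continuous trait
quick_sim <- function(n_generations = 3, gen_size = 150, n_lines = 1,
                      n_chr = 3, snps = 100, h2 = 0.3, n_causal = 50,
                      mean = 100, sd = 10, seed = 1, ordinal = FALSE,
                      line_divergence = 0.8, no_fixed_effects = FALSE,
                      keep_haplotypes = FALSE) {
  cfg <- sim_config(n_generations = n_generations,
                    gen_sizes = rep(gen_size, n_generations),
                    n_lines = n_lines, n_chromosomes = n_chr,
                    snps_per_chromosome = snps,
                    line_divergence = line_divergence, seed = seed)
  ped <- sim_pedigree(cfg)
  geno <- sim_genotypes(ped, cfg, keep_haplotypes = keep_haplotypes)
  fe <- if (no_fixed_effects)
    list(sexhatch = rep(0, 2 * cfg$n_hatches),
         damage = rep(0, cfg$n_dam_age_classes),
         pen = rep(0, cfg$n_pens))
  n_causal <- min(n_causal, n_chr * snps)
  arch <- trait_architecture("T1", h2, n_causal, mean, sd,
                             fixed_effect_sizes = fe, ordinal = ordinal)
  sim <- sim_phenotypes(ped, geno, arch, cfg, seed = seed + 1000L)
  list(cfg = cfg, ped = ped, geno = geno, sim = sim,
       pheno = sim$phenotypes, truth = sim$truth)
}
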