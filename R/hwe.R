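# Hardy-Weinberg exact testing (Monte-Carlo, Guo & Thompson style) and
# Brookfield null-allele estimation.

# log conditional probability of a genotype array given allele counts:
# P = n! / prod(n_ij!) * 2^h * prod(n_a!) / (2n)!
log_array_prob <- function(pairs) {
  n <- nrow(pairs)
  het <- pairs[, 1] != pairs[, 2]
  mx <- max(pairs) + 1
  key <- pairs[, 1] * mx + pairs[, 2]
  gcounts <- tabulate(match(key, unique(key)))
  ac <- c(pairs)
  acounts <- tabulate(match(ac, unique(ac)))
  lfactorial(n) - sum(lfactorial(gcounts)) + sum(het) * log(2) +
    sum(lfactorial(acounts)) - lfactorial(2 * n)
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Within one (population, locus) cell, repeatedly shuffles the observed gene
#' copies into random diploid pairings and compares the conditional
#' probability of each shuffled genotype array with the observed one;
#' `p = (# shuffles with probability <= observed + 1) / (n_perm + 1)`
#' (the observed array counted once in numerator and denominator, so p > 0).
#' Monomorphic cells return p = 1 by convention.
#'
#' @param gm genotype_matrix
#' @param population population label
#' @param locus locus name or index
#' @param n_perm number of Monte-Carlo shuffles (default 10000)
#' @param seed RNG seed
#' @return list of class `hwe_result`
#' @export
hwe_exact_test <- function(gm, population, locus, n_perm = 10000L, seed = NULL) {
  a <- alleles_at(gm, locus)[gm$pop == population, , drop = FALSE]
  a <- a[!is.na(a[, 1]), , drop = FALSE]
  if (nrow(a) < 2L) stop("need at least 2 typed individuals")
  res <- list(population = population,
              locus = if (is.character(locus)) locus else gm$loci$name[locus],
              n = nrow(a), n_perm = n_perm, seed = seed)
  if (length(unique(c(a))) < 2L) {
    res$p_value <- 1
    class(res) <- "hwe_result"
    return(res)
  }
  obs <- log_array_prob(a)
  copies <- c(t(a))
  hits <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      s <- sample(copies)
      m <- matrix(s, ncol = 2L, byrow = TRUE)
      m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
      if (log_array_prob(m) <= obs + 1e-12) hits <- hits + 1L
    }
  })
  res$p_value <- (hits + 1) / (n_perm + 1)
  class(res) <- "hwe_result"
  res
}

#' HWE tests across all (population, locus) cells
#'
#' Applies [hwe_exact_test()] to every cell with at least `min_n` typed
#' individuals; significance flags use a Bonferroni correction within each
#' population across its locus tests (`alpha / n_loci_tested`), mirroring
#' per-population adjustment rather than a dataset-wide one.
#'
#' @param gm genotype_matrix
#' @param n_perm Monte-Carlo shuffles per test
#' @param alpha nominal level before within-population Bonferroni
#' @param min_n minimum typed individuals per cell
#' @param seed RNG seed
#' @return data.frame with population, locus, p_value, significant
#' @export
hwe_test_all <- function(gm, n_perm = 10000L, alpha = 0.05, min_n = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  rows <- list()
  for (p in levels(gm$pop)) {
    pvals <- c(); loci <- c()
    for (j in seq_len(n_loci(gm))) {
      a <- alleles_at(gm, j)[gm$pop == p, , drop = FALSE]
      if (sum(!is.na(a[, 1])) < min_n) next
      r <- hwe_exact_test(gm, p, j, n_perm = n_perm)
      pvals <- c(pvals, r$p_value); loci <- c(loci, gm$loci$name[j])
    }
    if (length(pvals))
      rows[[p]] <- data.frame(population = p, locus = loci, p_value = pvals,
                              significant = pvals < alpha / length(pvals),
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Brookfield null-allele frequency estimators
#'
#' Estimator 1: `r1 = (He - Ho) / (1 + He)`. Estimator 2 additionally treats
#' observed non-amplifying individuals (both alleles missing) as putative
#' null homozygotes: with `b` the proportion of such blanks,
#' `r2 = (He - Ho + 2b) / (1 + He + 2b)`; with zero recorded blanks the two
#' estimators coincide. Significance is judged by a bootstrap over
#' individuals: the estimate is flagged when the 95% CI excludes zero.
#' Raw and zero-truncated estimates are both reported.
#'
#' @param gm genotype_matrix
#' @param population population label
#' @param locus locus name or index
#' @param n_boot bootstrap replicates (default 1000)
#' @param seed RNG seed
#' @return list of class `null_allele_estimate`
#' @export
null_allele_estimate <- function(gm, population, locus, n_boot = 1000L, seed = NULL) {
  idx <- which(gm$pop == population)
  a <- alleles_at(gm, locus)[idx, , drop = FALSE]
  typed <- !is.na(a[, 1])
  est <- function(av, nblank, ntot) {
    av <- av[!is.na(av[, 1]), , drop = FALSE]
    n <- nrow(av)
    if (n < 2L) return(c(NA_real_, NA_real_))
    ho <- mean(av[, 1] != av[, 2])
    p <- table(c(av)) / (2 * n)
    he <- (2 * n) / (2 * n - 1) * (1 - sum(p^2))
    b <- nblank / ntot
    c((he - ho) / (1 + he), (he - ho + 2 * b) / (1 + he + 2 * b))
  }
  nblank <- sum(!typed); ntot <- nrow(a)
  r <- est(a, nblank, ntot)
  flag_unstable <- sum(typed) * 2L < 4L
  boot <- matrix(NA_real_, n_boot, 2L)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      ii <- sample(ntot, replace = TRUE)
      boot[b, ] <- est(a[ii, , drop = FALSE], sum(is.na(a[ii, 1])), ntot)
    }
  })
  ci1 <- quantile(boot[, 1], c(0.025, 0.975), na.rm = TRUE)
  ci2 <- quantile(boot[, 2], c(0.025, 0.975), na.rm = TRUE)
  structure(list(population = population,
                 locus = if (is.character(locus)) locus else gm$loci$name[locus],
                 r1_raw = r[1], r1 = max(0, r[1]),
                 r2_raw = r[2], r2 = max(0, r[2]),
                 ci1 = ci1, ci2 = ci2,
                 significant = is.finite(ci2[1]) && ci2[1] > 0,
                 n_blank = nblank, unstable = flag_unstable,
                 n_boot = n_boot, seed = seed),
            class = "null_allele_estimate")
}
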