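# Two-locus linkage analysis on unphased genotypes: EM likelihood-ratio
# permutation test within populations, and Ohta's (1982) variance
# decomposition of linkage disequilibrium in a subdivided population.

# EM haplotype-frequency estimation for one population and one locus pair.
# A, B: n x 2 allele-index matrices (no missing rows).
em_haplotypes <- function(A, B, max_iter = 50L, tol = 1e-7) {
  aA <- max(A); aB <- max(B)
  # collapse identical two-locus genotypes (numeric keys for speed)
  key <- ((A[, 1] * aA + A[, 2]) * aB + B[, 1]) * aB + B[, 2]
  uk <- unique(key)
  gi <- match(key, uk)
  w <- tabulate(gi, length(uk))
  first <- match(seq_along(uk), gi)
  ug <- cbind(A[first, 1], A[first, 2], B[first, 1], B[first, 2])
  pA <- tabulate(c(A), aA) / (2 * nrow(A))
  pB <- tabulate(c(B), aB) / (2 * nrow(B))
  h <- outer(pA, pB)
  dhet <- ug[, 1] != ug[, 2] & ug[, 3] != ug[, 4]
  loglik <- function(h) {
    p1 <- h[cbind(ug[, 1], ug[, 3])] * h[cbind(ug[, 2], ug[, 4])]
    p2 <- h[cbind(ug[, 1], ug[, 4])] * h[cbind(ug[, 2], ug[, 3])]
    samehap <- ug[, 1] == ug[, 2] & ug[, 3] == ug[, 4]
    pr <- ifelse(dhet, 2 * (p1 + p2), ifelse(samehap, p1, 2 * p1))
    sum(w * log(pmax(pr, 1e-300)))
  }
  ll0 <- loglik(h)
  ll_old <- ll0
  # linear indices of the four haplotype cells touched by each genotype
  i11 <- (ug[, 3] - 1L) * aA + ug[, 1]; i22 <- (ug[, 4] - 1L) * aA + ug[, 2]
  i12 <- (ug[, 4] - 1L) * aA + ug[, 1]; i21 <- (ug[, 3] - 1L) * aA + ug[, 2]
  idx_all <- c(i11, i22, i12, i21)
  for (it in seq_len(max_iter)) {
    p1 <- h[i11] * h[i22]
    p2 <- h[i12] * h[i21]
    f1 <- ifelse(dhet, p1 / pmax(p1 + p2, 1e-300), 1)
    w1 <- w * f1; w2 <- w * (1 - f1)
    rs <- rowsum(c(w1, w1, w2, w2), idx_all)
    cnt <- numeric(aA * aB)
    cnt[as.integer(rownames(rs))] <- rs
    h <- matrix(cnt / sum(cnt), aA, aB)
    ll <- loglik(h)
    if (ll - ll_old < tol) break
    ll_old <- ll
  }
  list(h = h, loglik_full = ll_old, loglik_null = ll0)
}

#' Likelihood-ratio permutation test of linkage disequilibrium
#'
#' Within one population, two-locus haplotype frequencies are estimated by EM
#' from unphased genotypes; the statistic is
#' `2 (lnL_full - lnL_equilibrium)`, where the equilibrium likelihood uses
#' the product of single-locus allele frequencies. Significance comes from
#' permuting one locus's genotypes across individuals (breaking the
#' between-locus association while preserving single-locus genotype arrays).
#'
#' @param gm genotype_matrix
#' @param population population label
#' @param locus_pair length-2 vector of locus names or indices
#' @param n_perm permutations (default 1000)
#' @param seed RNG seed
#' @return list of class `ld_test_result`
#' @export
ld_test <- function(gm, population, locus_pair, n_perm = 1000L, seed = NULL) {
  j1 <- locus_pair[1]; j2 <- locus_pair[2]
  sel <- gm$pop == population
  A <- alleles_at(gm, j1)[sel, , drop = FALSE]
  B <- alleles_at(gm, j2)[sel, , drop = FALSE]
  ok <- !is.na(A[, 1]) & !is.na(B[, 1])
  A <- A[ok, , drop = FALSE]; B <- B[ok, , drop = FALSE]
  if (nrow(A) < 5L) stop("need >= 5 individuals typed at both loci")
  lab <- function(j) if (is.character(j)) j else gm$loci$name[j]
  res <- list(population = population, locus_pair = c(lab(j1), lab(j2)),
              n = nrow(A), n_perm = n_perm, seed = seed)
  toidx <- function(M) matrix(match(M, sort(unique(c(M)))), ncol = 2L)
  Ai <- toidx(A); Bi <- toidx(B)
  if (length(unique(c(Ai))) < 2L || length(unique(c(Bi))) < 2L) {
    res$statistic <- 0; res$p_value <- 1
    class(res) <- "ld_test_result"
    return(res)
  }
  lr <- function(Ai, Bi) {
    e <- em_haplotypes(Ai, Bi)
    max(0, 2 * (e$loglik_full - e$loglik_null))
  }
  obs <- lr(Ai, Bi)
  hits <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      if (lr(Ai, Bi[sample(nrow(Bi)), , drop = FALSE]) >= obs - 1e-9) hits <- hits + 1L
    }
  })
  res$statistic <- obs
  res$p_value <- (hits + 1) / (n_perm + 1)
  class(res) <- "ld_test_result"
  res
}

# Burrows composite two-locus "gamete" frequencies and allele dosages for a
# set of individuals: returns list(g = aA x aB matrix summing to 1,
# x, y = marginal allele freqs) computed on the pair-complete subset.
burrows_gametes <- function(A, B, aA, aB) {
  n <- nrow(A)
  X <- matrix(0, n, aA); Y <- matrix(0, n, aB)
  X[cbind(seq_len(n), A[, 1])] <- X[cbind(seq_len(n), A[, 1])] + 1
  X[cbind(seq_len(n), A[, 2])] <- X[cbind(seq_len(n), A[, 2])] + 1
  Y[cbind(seq_len(n), B[, 1])] <- Y[cbind(seq_len(n), B[, 1])] + 1
  Y[cbind(seq_len(n), B[, 2])] <- Y[cbind(seq_len(n), B[, 2])] + 1
  g <- crossprod(X, Y) / (4 * n)
  list(g = g, x = colMeans(X) / 2, y = colMeans(Y) / 2, X = X, Y = Y)
}

#' Ohta's D-statistics for a locus pair in a subdivided population
#'
#' Decomposes squared linkage disequilibrium into within- and
#' between-population variance components (Ohta 1982), using Burrows
#' composite gamete-frequency estimates appropriate for unphased data.
#' With `g_ijk` the composite frequency of gamete (i, j) in population k,
#' `x_ik`, `y_jk` the allele frequencies, and bars denoting unweighted
#' averages over populations:
#' `D2_IS = E_k sum_ij (g_ijk - x_ik y_jk)^2`,
#' `D2_ST = E_k sum_ij (x_ik y_jk - xbar_i ybar_j)^2`,
#' `Dp2_IS = E_k sum_ij (g_ijk - gbar_ij)^2`,
#' `Dp2_ST = sum_ij (gbar_ij - xbar_i ybar_j)^2`,
#' `D2_IT = E_k sum_ij (g_ijk - xbar_i ybar_j)^2`.
#' The identity `D2_IT = Dp2_IS + Dp2_ST` holds exactly.
#'
#' @param gm genotype_matrix
#' @param locus_pair length-2 locus names or indices
#' @param grouping factor (default populations)
#' @param min_n minimum pair-complete individuals for a population to enter
#' @return list of class `ohta_d` with the five components, the
#'   `D2_ST/D2_IS` ratio (and primed variant) and its log.
#' @export
ohta_components <- function(gm, locus_pair, grouping = gm$pop, min_n = 2L) {
  grouping <- factor(grouping)
  A <- alleles_at(gm, locus_pair[1]); B <- alleles_at(gm, locus_pair[2])
  ok <- !is.na(A[, 1]) & !is.na(B[, 1])
  sizesA <- sort(unique(c(A[ok, ]))); sizesB <- sort(unique(c(B[ok, ])))
  aA <- length(sizesA); aB <- length(sizesB)
  glist <- list(); xs <- list(); ys <- list()
  for (p in levels(grouping)) {
    sel <- ok & grouping == p
    if (sum(sel) < min_n) next
    Ai <- matrix(match(A[sel, ], sizesA), ncol = 2L)
    Bi <- matrix(match(B[sel, ], sizesB), ncol = 2L)
    bg <- burrows_gametes(Ai, Bi, aA, aB)
    glist[[p]] <- bg$g; xs[[p]] <- bg$x; ys[[p]] <- bg$y
  }
  r <- length(glist)
  if (r == 0L) stop("no population with enough pair-complete individuals")
  gbar <- Reduce(`+`, glist) / r
  xbar <- Reduce(`+`, xs) / r
  ybar <- Reduce(`+`, ys) / r
  xy_bar <- outer(xbar, ybar)
  d2_is <- mean(vapply(names(glist), function(p)
    sum((glist[[p]] - outer(xs[[p]], ys[[p]]))^2), 0))
  d2_st <- mean(vapply(names(glist), function(p)
    sum((outer(xs[[p]], ys[[p]]) - xy_bar)^2), 0))
  dp2_is <- mean(vapply(names(glist), function(p)
    sum((glist[[p]] - gbar)^2), 0))
  dp2_st <- sum((gbar - xy_bar)^2)
  d2_it <- mean(vapply(names(glist), function(p)
    sum((glist[[p]] - xy_bar)^2), 0))
  if (r == 1L) d2_st <- dp2_st <- 0
  lab <- function(j) if (is.character(j)) j else gm$loci$name[j]
  # The between/within diagnostic ratio follows Ohta's drift-vs-selection
  # comparison of D'2_ST against D2_IS (the pair GENETIX reports for this
  # purpose); the fully unprimed ratio is kept alongside.
  structure(list(locus_pair = c(lab(locus_pair[1]), lab(locus_pair[2])),
                 D2_IS = d2_is, D2_ST = d2_st,
                 Dp2_IS = dp2_is, Dp2_ST = dp2_st, D2_IT = d2_it,
                 ratio_ST_IS = dp2_st / d2_is,
                 ratio_ST_IS_unprimed = d2_st / d2_is,
                 log_ratio = log(dp2_st / d2_is),
                 n_pops = r),
            class = "ohta_d")
}
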