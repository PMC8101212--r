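# Weir & Cockerham (1984) variance components, combined by ratio-of-sums
# across alleles and loci (the hierfstat convention).

# Per (locus, group) sufficient statistics: individuals typed, allele counts,
# and per-allele heterozygote counts.
wc_sufficient <- function(gm, grouping) {
  grouping <- factor(grouping)
  L <- n_loci(gm)
  out <- vector("list", L)
  for (j in seq_len(L)) {
    a <- alleles_at(gm, j)
    ok <- !is.na(a[, 1])
    sizes <- sort(unique(c(a[ok, ])))
    G <- nlevels(grouping)
    n_i <- integer(G)
    cnt <- het <- matrix(0, length(sizes), G, dimnames = list(sizes, levels(grouping)))
    for (g in seq_len(G)) {
      idx <- which(grouping == levels(grouping)[g] & ok)
      n_i[g] <- length(idx)
      if (!length(idx)) next
      av <- a[idx, , drop = FALSE]
      cnt[, g] <- tabulate(match(c(av), sizes), nbins = length(sizes))
      hz <- av[av[, 1] != av[, 2], , drop = FALSE]
      if (nrow(hz))
        het[, g] <- tabulate(match(c(hz), sizes), nbins = length(sizes))
    }
    out[[j]] <- list(n = n_i, cnt = cnt, het = het)
  }
  names(out) <- gm$loci$name
  out
}

# a, b, c component sums for one locus over the given group columns.
wc_abc_locus <- function(suff_j, cols = NULL) {
  n_i <- suff_j$n; cnt <- suff_j$cnt; het <- suff_j$het
  if (!is.null(cols)) { n_i <- n_i[cols]; cnt <- cnt[, cols, drop = FALSE]; het <- het[, cols, drop = FALSE] }
  use <- n_i > 0
  r <- sum(use)
  if (r < 2) return(c(a = 0, b = 0, c = 0))
  n_i <- n_i[use]; cnt <- cnt[, use, drop = FALSE]; het <- het[, use, drop = FALSE]
  nbar <- mean(n_i)
  if (nbar <= 1) return(c(a = 0, b = 0, c = 0))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  p <- sweep(cnt, 2L, 2 * n_i, "/")
  h <- sweep(het, 2L, n_i, "/")
  pbar <- as.numeric(p %*% n_i) / (r * nbar)
  s2 <- as.numeric(((p - pbar)^2) %*% n_i) / ((r - 1) * nbar)
  hbar <- as.numeric(h %*% n_i) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = sum(a), b = sum(b), c = sum(cc))
}

#' Weir-Cockerham F-statistics
#'
#' Estimates FST (theta), FIS (f) and FIT (F) from the Weir & Cockerham
#' (1984) a, b, c variance components, combining alleles and loci by
#' ratio-of-sums. Optional significance by permuting individuals among
#' groups (FST only), with the +1 permutation correction.
#'
#' @param gm genotype_matrix
#' @param grouping factor over individuals (default populations)
#' @param n_perm number of label permutations (0 = none)
#' @param seed RNG seed for permutations
#' @return object of class `fstats` with per-locus and overall estimates.
#' @export
wc_fstats <- function(gm, grouping = gm$pop, n_perm = 0L, seed = NULL) {
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2L) stop("FST undefined for a single group")
  suff <- wc_sufficient(gm, grouping)
  abc <- t(vapply(suff, wc_abc_locus, c(a = 0, b = 0, c = 0)))
  tot <- colSums(abc)
  ratio <- function(v) {
    den <- sum(v)
    c(fst = unname(v[1] / den),
      fit = unname((v[1] + v[2]) / den),
      fis = unname(v[2] / (v[2] + v[3])))
  }
  per_locus <- t(apply(abc, 1L, ratio))
  overall <- ratio(tot)
  p_fst <- NA_real_
  if (n_perm > 0L) {
    with_seed(seed, {
      obs <- overall["fst"]
      hits <- 0L
      for (b in seq_len(n_perm)) {
        gp <- sample(grouping)
        sp <- wc_sufficient(gm, gp)
        tp <- colSums(t(vapply(sp, wc_abc_locus, c(a = 0, b = 0, c = 0))))
        if (tp[1] / sum(tp) >= obs) hits <- hits + 1L
      }
      p_fst <- (hits + 1) / (n_perm + 1)
    })
  }
  structure(list(per_locus = per_locus, overall = overall, components = abc,
                 p_fst = p_fst, n_perm = n_perm),
            class = "fstats")
}

#' @export
print.fstats <- function(x, ...) {
  cat(sprintf("Weir-Cockerham overall: FST = %.4f  FIS = %.4f  FIT = %.4f\n",
              x$overall["fst"], x$overall["fis"], x$overall["fit"]))
  invisible(x)
}

#' Pairwise FST matrix across populations
#'
#' Weir-Cockerham theta for every population pair, with optional permutation
#' p-values (individuals shuffled between the two populations of a pair).
#' Raw (possibly negative) estimates are stored; `truncate = TRUE` returns a
#' view clamped at zero.
#'
#' @param gm genotype_matrix
#' @param n_perm permutations per pair (0 = none)
#' @param seed RNG seed
#' @param grouping factor (default populations)
#' @return list of class `pairwise_fst` with symmetric matrices `fst`
#'   (raw values, zero diagonal) and `p` (NA when `n_perm = 0`).
#' @export
pairwise_fst_matrix <- function(gm, n_perm = 0L, seed = NULL, grouping = gm$pop) {
  grouping <- factor(grouping)
  G <- nlevels(grouping)
  if (G < 2L) stop("need at least two populations")
  suff <- wc_sufficient(gm, grouping)
  lev <- levels(grouping)
  fst <- matrix(0, G, G, dimnames = list(lev, lev))
  pmat <- matrix(NA_real_, G, G, dimnames = list(lev, lev))
  small <- tabulate(grouping, G) < 2L
  pair_theta <- function(suff, i, k) {
    tot <- c(0, 0, 0)
    for (j in seq_along(suff)) tot <- tot + wc_abc_locus(suff[[j]], cols = c(i, k))
    tot[1] / sum(tot)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  for (i in seq_len(G - 1L)) for (k in (i + 1L):G) {
    if (small[i] || small[k]) { fst[i, k] <- fst[k, i] <- NA_real_; next }
    th <- pair_theta(suff, i, k)
    fst[i, k] <- fst[k, i] <- th
    if (n_perm > 0L) {
      idx <- which(grouping %in% lev[c(i, k)])
      sub <- gm[idx]
      glab <- droplevels(grouping[idx])
      hits <- 0L
      for (b in seq_len(n_perm)) {
        sp <- wc_sufficient(sub, sample(glab))
        if (pair_theta(sp, 1L, 2L) >= th) hits <- hits + 1L
      }
      pmat[i, k] <- pmat[k, i] <- (hits + 1) / (n_perm + 1)
    }
  }
  structure(list(fst = fst, p = pmat, n_perm = n_perm), class = "pairwise_fst")
}

#' Linearised FST distance matrix
#'
#' `FST / (1 - FST)` on the truncated-at-zero pairwise matrix, as used for
#' isolation-by-distance analyses.
#'
#' @param pf a `pairwise_fst` object (or raw symmetric matrix)
#' @return symmetric matrix
#' @export
linearised_fst <- function(pf) {
  m <- if (inherits(pf, "pairwise_fst")) pf$fst else pf
  m <- pmax(m, 0)
  m / (1 - m)
}
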