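# Hierarchical analysis of molecular variance (AMOVA) on allele-mismatch
# distances between gene copies, with exact unbalanced nested-ANOVA
# expected-mean-square coefficients and per-level permutation tests.
#
# Derivation used here: with d2 the 0/1 allele-mismatch distance between two
# gene copies, the within-cluster sum of squares of a cluster u is
# SSD(u) = (1/m_u) sum_{i<j in u} d2_ij (computable from allele counts).
# Writing W_l for the summed SSD over all clusters of level l (W_0 = total,
# W_K = 0 at the copy level), the level-k sum of squares is
# SS_k = W_{k-1} - W_k = T'_k - T'_{k-1} with T'_l the uncorrected sums of a
# scalar nested ANOVA, whose expectation is
# E[T'_l] = N mu^2 + sum_j c_{l,j} sigma2_j,
# c_{l,j} = sum_{u at l} sum_{v at j} m_{u n v}^2 / m_u.
# Components are obtained by solving the resulting linear system; the
# formula for c is exact for unbalanced nested designs.

ssd_of_clusters <- function(alleles, cluster) {
  tot <- 0
  for (cl in split(alleles, cluster)) {
    m <- length(cl)
    if (m < 2L) next
    cnt <- table(cl)
    tot <- tot + (choose(m, 2) - sum(choose(cnt, 2))) / m
  }
  tot
}

# c_{l,j}: fl, fj are factors over copies, NULL = grand level, "copies" =
# one unit per copy.
amova_coef <- function(fl, fj, n_copies) {
  if (identical(fj, "copies")) {
    if (is.null(fl)) return(1)
    if (identical(fl, "copies")) return(n_copies)
    return(nlevels(droplevels(fl)))
  }
  if (identical(fl, "copies")) return(n_copies)
  if (is.null(fl))
    return(sum(tapply(rep(1, n_copies), fj, sum)^2) / n_copies)
  m_l <- tapply(rep(1, n_copies), fl, sum)
  tab <- table(fj, fl)
  sum(colSums(tab^2)[names(m_l)] / m_l, na.rm = TRUE)
}

# Core decomposition for one clustering of the copies of all loci.
# copy_factors(gm) supplies, per locus, the list of level factors over the
# typed copies plus the allele values.
amova_decompose <- function(locus_data, K) {
  SS <- numeric(K); Mmat <- matrix(0, K, K); dfv <- numeric(K)
  for (ld in locus_data) {
    copies <- ld$copies; lev <- ld$levels
    Ncop <- length(copies)
    Ts <- numeric(K + 1L)
    Ts[1] <- ssd_of_clusters(copies, factor(rep(1, Ncop)))
    for (l in seq_len(K - 1L)) Ts[l + 1L] <- ssd_of_clusters(copies, lev[[l]])
    Ts[K + 1L] <- 0
    for (k in seq_len(K)) SS[k] <- SS[k] + Ts[k] - Ts[k + 1L]
    for (k in seq_len(K)) for (jj in seq_len(K)) {
      fl_bot <- if (k == K) "copies" else lev[[k]]
      fl_top <- if (k == 1L) NULL else lev[[k - 1L]]
      fj <- if (jj == K) "copies" else lev[[jj]]
      Mmat[k, jj] <- Mmat[k, jj] +
        amova_coef(fl_bot, fj, Ncop) - amova_coef(fl_top, fj, Ncop)
    }
    dfs <- c(vapply(lev, function(f) nlevels(droplevels(f)), 0L), Ncop)
    dfv <- dfv + diff(c(1, dfs))
  }
  sigma2 <- solve(Mmat, SS)
  list(sigma2 = sigma2, SS = SS, df = dfv)
}

amova_locus_data <- function(gm, facs) {
  lapply(seq_len(n_loci(gm)), function(j) {
    a <- alleles_at(gm, j)
    ok <- !is.na(a[, 1])
    cop_ind <- rep(which(ok), each = 2L)
    list(copies = c(t(a[ok, , drop = FALSE])),
         levels = c(lapply(facs, function(f) f[cop_ind]),
                    list(factor(cop_ind))))
  })
}

#' Analysis of molecular variance
#'
#' Decomposes allele-mismatch distances between gene copies into hierarchical
#' variance components. The hierarchy is given as grouping names (top to
#' bottom): `"population"` refers to the population factor, any other name is
#' looked up in the population metadata (e.g. `c("subcontinent",
#' "population")` or `c("provenance", "population")`). Levels for individuals
#' and the two copies within each individual are implicit, so a two-factor
#' hierarchy yields four components: between groups, between populations
#' within groups, between individuals within populations, within individuals.
#' Negative variance components are reported as estimated (not zeroed).
#'
#' Permutation tests (default 99 permutations): populations among groups for
#' the top component, individuals among populations (within groups) for the
#' population component, and gene copies among individuals within
#' populations for the individual component.
#'
#' @param gm genotype_matrix
#' @param hierarchy character vector of level names, top to bottom
#' @param n_perm permutations (0 disables testing)
#' @param seed RNG seed
#' @return object of class `amova_result`
#' @export
amova <- function(gm, hierarchy = c("population"), n_perm = 99L, seed = NULL) {
  facs <- lapply(hierarchy, function(h) {
    if (h == "population") gm$pop
    else {
      if (is.null(gm$meta) || !h %in% names(gm$meta))
        stop("hierarchy level not found in metadata: ", h)
      factor(gm$meta[[h]][match(as.character(gm$pop), gm$meta$population)])
    }
  })
  names(facs) <- hierarchy
  nl <- length(facs)
  K <- nl + 2L
  lv_names <- c(if (nl == 2L) "between_groups",
                if (nl == 2L) "between_pops_within_groups" else "between_pops",
                "between_inds_within_pops", "within_inds")
  base <- amova_decompose(amova_locus_data(gm, facs), K)
  sigma2 <- base$sigma2
  tot <- sum(sigma2)
  phi <- if (nl == 2L) {
    c(phi_CT = sigma2[1] / tot,
      phi_SC = sigma2[2] / sum(sigma2[2:4]),
      phi_IS = sigma2[3] / sum(sigma2[3:4]),
      phi_IT = sum(sigma2[1:3]) / tot)
  } else {
    c(phi_ST = sigma2[1] / tot,
      phi_IS = sigma2[2] / sum(sigma2[2:3]),
      phi_IT = sum(sigma2[1:2]) / tot)
  }
  pvals <- rep(NA_real_, K)
  if (n_perm > 0L) {
    with_seed(seed, {
      pops <- facs[[nl]]
      k_pop <- nl; k_ind <- nl + 1L
      hits <- numeric(K)
      for (b in seq_len(n_perm)) {
        # individuals among populations (within top group if present)
        if (nl == 2L) {
          newpop <- pops
          for (gl in levels(facs[[1]])) {
            ii <- which(facs[[1]] == gl)
            newpop[ii] <- pops[ii][sample(length(ii))]
          }
          fp <- facs; fp[[2]] <- newpop
        } else {
          fp <- list(sample(pops))
        }
        rp <- amova_decompose(amova_locus_data(gm, fp), K)
        if (rp$sigma2[k_pop] >= sigma2[k_pop] - 1e-12) hits[k_pop] <- hits[k_pop] + 1
        # gene copies among individuals within populations
        gm2 <- gm
        for (j in seq_len(n_loci(gm))) {
          cols <- c(2L * j - 1L, 2L * j)
          for (p in levels(gm$pop)) {
            ii <- which(gm$pop == p & !is.na(gm$alleles[, cols[1]]))
            if (length(ii) < 2L) next
            vals <- c(t(gm$alleles[ii, cols]))
            vals <- sample(vals)
            gm2$alleles[ii, cols] <- matrix(vals, ncol = 2L, byrow = TRUE)
          }
        }
        ri <- amova_decompose(amova_locus_data(gm2, facs), K)
        if (ri$sigma2[k_ind] >= sigma2[k_ind] - 1e-12) hits[k_ind] <- hits[k_ind] + 1
        # populations among groups
        if (nl == 2L) {
          pl <- levels(pops)
          gmap <- as.character(facs[[1]][match(pl, as.character(pops))])
          gshuf <- sample(gmap)
          fg <- facs
          fg[[1]] <- factor(gshuf[match(as.character(pops), pl)])
          rg <- amova_decompose(amova_locus_data(gm, fg), K)
          if (rg$sigma2[1L] >= sigma2[1L] - 1e-12) hits[1L] <- hits[1L] + 1
        }
      }
      pvals[k_pop] <- (hits[k_pop] + 1) / (n_perm + 1)
      pvals[k_ind] <- (hits[k_ind] + 1) / (n_perm + 1)
      if (nl == 2L) pvals[1L] <- (hits[1L] + 1) / (n_perm + 1)
    })
  }
  structure(list(levels = lv_names,
                 components = setNames(sigma2, lv_names),
                 percent = setNames(100 * sigma2 / tot, lv_names),
                 phi = phi, ss = base$SS, df = base$df,
                 p_values = setNames(pvals, lv_names), n_perm = n_perm),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  df <- data.frame(level = x$levels, sigma2 = round(x$components, 5),
                   percent = round(x$percent, 2), p = round(x$p_values, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
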