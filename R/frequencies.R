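#' Per-group allele frequencies and gene counts
#'
#' Tabulates allele counts per (group, locus) cell from non-missing calls.
#' Gene counts are twice the number of individuals typed at the locus in the
#' group (calls are always pairs, so gene counts are even).
#'
#' @param gm genotype_matrix
#' @param grouping factor over individuals (default the population factor).
#' @return object of class `freq_table`: per locus an allele-count matrix
#'   (alleles x groups, rownames = allele sizes in bp) plus a
#'   `gene_count` matrix (groups x loci).
#' @export
allele_frequencies <- function(gm, grouping = gm$pop) {
  grouping <- factor(grouping)
  if (length(grouping) != n_ind(gm)) stop("grouping must cover all individuals")
  L <- n_loci(gm); G <- nlevels(grouping)
  counts <- vector("list", L)
  gc <- matrix(0L, G, L, dimnames = list(levels(grouping), gm$loci$name))
  for (j in seq_len(L)) {
    a <- alleles_at(gm, j)
    sizes <- sort(unique(c(a[!is.na(a)])))
    m <- matrix(0L, length(sizes), G, dimnames = list(sizes, levels(grouping)))
    for (g in seq_len(G)) {
      vals <- c(a[grouping == levels(grouping)[g], ])
      vals <- vals[!is.na(vals)]
      gc[g, j] <- length(vals)
      if (length(vals)) {
        tb <- table(factor(vals, levels = sizes))
        m[, g] <- as.integer(tb)
      }
    }
    counts[[j]] <- m
  }
  names(counts) <- gm$loci$name
  structure(list(counts = counts, gene_count = gc,
                 groups = levels(grouping), loci = gm$loci$name),
            class = "freq_table")
}

#' Extract relative frequencies from a freq_table cell
#'
#' @param ft freq_table
#' @param locus locus name or index
#' @param group group name or index (NULL for all groups)
#' @return matrix of relative frequencies (alleles x groups); columns of
#'   cells with zero gene copies are `NaN` (flagged empty cells).
#' @export
cell_frequencies <- function(ft, locus, group = NULL) {
  m <- ft$counts[[locus]]
  if (!is.null(group)) m <- m[, group, drop = FALSE]
  sweep(m, 2L, colSums(m), "/")
}

#' Diversity statistics per (group, locus) and margins
#'
#' Observed heterozygosity H_O is the fraction of heterozygous calls among
#' non-missing calls; expected heterozygosity H_E uses Nei's unbiased
#' correction `n/(n-1) * (1 - sum p^2)` with `n` the gene count. `A_U` is,
#' per locus, the proportion of that locus's alleles observed exactly once
#' dataset-wide; private alleles are counted per group (alleles present in
#' exactly one group).
#'
#' @param gm genotype_matrix
#' @param grouping factor (default populations)
#' @return list of class `diversity_table` with matrices `n_alleles`, `ho`,
#'   `he` (groups x loci), vectors `a_u` and `n_alleles_total` per locus,
#'   `private_alleles` per group, and convenience margins.
#' @export
diversity_table <- function(gm, grouping = gm$pop) {
  ft <- allele_frequencies(gm, grouping)
  G <- length(ft$groups); L <- length(ft$loci)
  na <- ho <- he <- matrix(NA_real_, G, L, dimnames = list(ft$groups, ft$loci))
  a_u <- n_tot <- numeric(L)
  priv <- setNames(numeric(G), ft$groups)
  grouping <- factor(grouping)
  for (j in seq_len(L)) {
    cnt <- ft$counts[[j]]
    tot <- rowSums(cnt)
    n_tot[j] <- sum(tot > 0)
    a_u[j] <- if (n_tot[j] > 0) mean(tot[tot > 0] == 1) else NA_real_
    pres <- cnt > 0
    one_grp <- rowSums(pres) == 1L
    if (any(one_grp)) {
      owner <- apply(pres[one_grp, , drop = FALSE], 1L, which)
      tb <- table(factor(ft$groups[owner], levels = ft$groups))
      priv <- priv + as.numeric(tb)
    }
    a <- alleles_at(gm, j)
    het <- a[, 1] != a[, 2]
    for (g in seq_len(G)) {
      ng <- ft$gene_count[g, j]
      if (ng < 2L) next
      p <- cnt[, g] / ng
      na[g, j] <- sum(cnt[, g] > 0)
      he[g, j] <- ng / (ng - 1) * (1 - sum(p^2))
      hh <- het[grouping == ft$groups[g]]
      ho[g, j] <- mean(hh, na.rm = TRUE)
    }
  }
  names(a_u) <- names(n_tot) <- ft$loci
  structure(list(n_alleles = na, ho = ho, he = he,
                 n_alleles_total = n_tot, a_u = a_u,
                 private_alleles = priv,
                 mean_alleles_per_locus = mean(n_tot),
                 mean_alleles_per_group = rowSums(na, na.rm = TRUE),
                 gene_count = ft$gene_count),
            class = "diversity_table")
}

#' Rarefied allelic richness
#'
#' Hypergeometric expectation of the number of alleles in a subsample of `g`
#' gene copies: `A_R = sum_a [1 - C(N - N_a, g) / C(N, g)]` per
#' (group, locus) cell, with `N` the cell gene count and `N_a` the copies of
#' allele `a`. The default `g = 10` corresponds to five diploid individuals.
#'
#' @param gm genotype_matrix
#' @param g gene copies to rarefy to (default 10)
#' @param grouping factor (default populations)
#' @return list with matrix `ar` (groups x loci) and per-group means across
#'   loci (`mean_ar`).
#' @export
rarefied_allelic_richness <- function(gm, g = 10L, grouping = gm$pop) {
  ft <- allele_frequencies(gm, grouping)
  gc <- ft$gene_count
  short <- which(gc < g & gc > 0, arr.ind = TRUE)
  if (nrow(short))
    stop("g exceeds gene count in cells: ",
         paste(apply(short, 1L, function(ij)
           paste0(rownames(gc)[ij[1]], "/", colnames(gc)[ij[2]])), collapse = ", "))
  ar <- matrix(NA_real_, length(ft$groups), length(ft$loci),
               dimnames = list(ft$groups, ft$loci))
  for (j in seq_along(ft$loci)) {
    cnt <- ft$counts[[j]]
    for (gi in seq_along(ft$groups)) {
      N <- gc[gi, j]
      if (N == 0L) next
      Na <- cnt[, gi]; Na <- Na[Na > 0]
      ar[gi, j] <- sum(1 - exp(lchoose_safe(N - Na, g) - lchoose(N, g)))
    }
  }
  list(ar = ar, mean_ar = rowMeans(ar, na.rm = TRUE), g = g)
}
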