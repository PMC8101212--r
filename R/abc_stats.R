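# Summary statistics for ABC, in the style of microsatellite reference-table
# engines: one-sample statistics per group (mean number of alleles, mean
# unbiased expected heterozygosity, mean allele-size variance) and
# two-sample statistics per group pair (pooled versions of the three, the
# shared-allele distance, the mean classification index in both directions,
# Weir-Cockerham FST, and Goldstein's (delta mu)^2 distance).

one_sample_stats <- function(a_list) {
  # a_list: per locus an n x 2 matrix of sizes (no missing) for one group
  nal <- het <- vsz <- numeric(length(a_list))
  for (j in seq_along(a_list)) {
    v <- c(a_list[[j]])
    ng <- length(v)
    cnt <- tabulate(match(v, unique(v)))
    p <- cnt / ng
    nal[j] <- length(p)
    het[j] <- if (ng > 1) ng / (ng - 1) * (1 - sum(p^2)) else 0
    vsz[j] <- var(v)
  }
  c(NAL = mean(nal), HET = mean(het), VAR = mean(vsz))
}

# mean proportion of shared alleles between all cross-group genotype pairs
# at one locus (multiset intersection of the two allele pairs / 2)
mean_share <- function(A, B) {
  c1 <- outer(A[, 1], B[, 1], "==") + outer(A[, 1], B[, 2], "==")
  c2 <- outer(A[, 2], B[, 1], "==") + outer(A[, 2], B[, 2], "==")
  hetA <- A[, 1] != A[, 2]
  s <- pmin(c1, 1) + pmin(c2, 1)          # heterozygous A rows
  if (any(!hetA)) s[!hetA, ] <- pmin(c1[!hetA, , drop = FALSE], 2)
  mean(s) / 2
}

#' Summary-statistic vector for ABC
#'
#' Computes the one-sample statistics for every group and, for every
#' unordered group pair, the pooled one-sample statistics, the shared-allele
#' distance `DAS = 1 - mean proportion of alleles shared between
#' cross-group individual pairs`, the mean classification index `LIK`
#' (mean over individuals of one group of the log-likelihood of their
#' genotype under the other group's allele frequencies, add-one smoothed;
#' both directions), Weir-Cockerham `FST`, and Goldstein's
#' `(delta mu)^2` (mean over loci of the squared difference of mean allele
#' sizes).
#'
#' @param gm genotype_matrix
#' @param groups ordered vector of population labels to use (default all)
#' @return named numeric vector (fixed ordering given the group design)
#' @export
summary_statistics <- function(gm, groups = levels(gm$pop)) {
  if (!length(groups)) stop("need at least one group")
  L <- n_loci(gm)
  idx_of <- split(seq_len(n_ind(gm)), gm$pop)
  per_group <- lapply(groups, function(g) {
    idx <- idx_of[[g]]
    if (!length(idx)) stop("empty group: ", g)
    vector("list", L)
  })
  names(per_group) <- groups
  for (j in seq_len(L)) {
    aj <- alleles_at(gm, j)
    for (g in groups) {
      a <- aj[idx_of[[g]], , drop = FALSE]
      per_group[[g]][[j]] <- a[!is.na(a[, 1]), , drop = FALSE]
    }
  }
  suff <- if (length(groups) >= 2L) wc_sufficient(gm, gm$pop) else NULL
  out <- c()
  for (g in groups) {
    s <- one_sample_stats(per_group[[g]])
    names(s) <- paste0(names(s), ".", g)
    out <- c(out, s)
  }
  if (length(groups) >= 2L) {
    for (i in seq_along(groups)[-length(groups)]) for (k in (i + 1):length(groups)) {
      g1 <- groups[i]; g2 <- groups[k]
      pooled <- lapply(seq_len(L), function(j)
        rbind(per_group[[g1]][[j]], per_group[[g2]][[j]]))
      s <- one_sample_stats(pooled)
      names(s) <- paste0(names(s), "2.", g1, ".", g2)
      out <- c(out, s)
      # DAS
      das_l <- numeric(L)
      for (j in seq_len(L)) {
        A <- per_group[[g1]][[j]]; B <- per_group[[g2]][[j]]
        das_l[j] <- if (!nrow(A) || !nrow(B)) NA_real_ else mean_share(A, B)
      }
      out <- c(out, setNames(1 - mean(das_l, na.rm = TRUE),
                             paste0("DAS.", g1, ".", g2)))
      # LIK both directions
      lik <- function(from, to) {
        tot <- 0; cnt <- 0
        for (j in seq_len(L)) {
          B <- per_group[[to]][[j]]
          sizes <- sort(unique(c(B, per_group[[from]][[j]])))
          f <- (tabulate(match(c(B), sizes), length(sizes)) + 1) /
            (2 * nrow(B) + length(sizes))
          A <- per_group[[from]][[j]]
          i1 <- match(A[, 1], sizes); i2 <- match(A[, 2], sizes)
          tot <- tot + sum(log(f[i1]) + log(f[i2]) + (i1 != i2) * log(2))
          cnt <- cnt + nrow(A)
        }
        tot / max(cnt / L, 1)  # mean per individual (loci summed)
      }
      out <- c(out, setNames(lik(g1, g2), paste0("LIK.", g1, ".", g2)),
               setNames(lik(g2, g1), paste0("LIK.", g2, ".", g1)))
      # FST (Weir-Cockerham on the pair, from the shared sufficient stats)
      tot <- c(0, 0, 0)
      cols <- match(c(g1, g2), levels(gm$pop))
      for (j in seq_len(L)) tot <- tot + wc_abc_locus(suff[[j]], cols = cols)
      out <- c(out, setNames(tot[1] / sum(tot), paste0("FST.", g1, ".", g2)))
      # Goldstein (delta mu)^2
      dmu <- numeric(L)
      for (j in seq_len(L))
        dmu[j] <- (mean(per_group[[g1]][[j]]) - mean(per_group[[g2]][[j]]))^2
      out <- c(out, setNames(mean(dmu), paste0("DM2.", g1, ".", g2)))
    }
  }
  out
}
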