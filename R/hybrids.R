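# Hybrid and first-generation backcross classification between two parental
# gene pools, in the spirit of ancestry-coefficient mixture analysis.

#' Classify individuals as parentals, F1 hybrids or first-generation backcrosses
#'
#' Five ancestry classes are modelled with expected parental contribution
#' `alpha` of gene pool A: pure_A (1), BC_A (0.75), F1 (0.5), BC_B (0.25),
#' pure_B (0). Each class has expected allele frequencies
#' `f_c = alpha f_A + (1 - alpha) f_B` per locus and genotype likelihoods
#' under Hardy-Weinberg proportions at `f_c`; class posteriors come from an
#' EM over the class mixing proportions. Parental frequencies are estimated
#' from the declared parental sets with add-one (Laplace) smoothing; setting
#' `update_parents = TRUE` re-estimates them jointly from posterior-weighted
#' query individuals as well.
#'
#' @param gm genotype_matrix
#' @param parent_a,parent_b disjoint index vectors (or id vectors) of
#'   reference parental individuals, each >= 5
#' @param query index/id vector of individuals to classify (default: all
#'   individuals not in either parental set)
#' @param update_parents jointly re-estimate parental frequencies (default
#'   FALSE; with mostly-hybrid query sets re-estimation can erode the pools)
#' @param smoothing pseudo-count added per allele to parental frequency
#'   estimates (default 0.5, Jeffreys-style; keeps unseen alleles possible
#'   without flattening well-sampled pools)
#' @param max_iter,tol EM controls
#' @return object of class `hybrid_class_result` with `posterior`
#'   (query x 5 classes), `assignment`, and the class table.
#' @export
hybrid_classify <- function(gm, parent_a, parent_b, query = NULL,
                            update_parents = FALSE, smoothing = 0.5,
                            max_iter = 100L, tol = 1e-8) {
  resolve <- function(v) if (is.character(v)) match(v, rownames(gm$alleles)) else v
  ia <- resolve(parent_a); ib <- resolve(parent_b)
  if (length(intersect(ia, ib))) stop("parental sets must be disjoint")
  if (length(ia) < 5L || length(ib) < 5L) stop("each parental set needs >= 5 individuals")
  iq <- resolve(query %||% setdiff(seq_len(n_ind(gm)), c(ia, ib)))
  classes <- c(pure_A = 1, BC_A = 0.75, F1 = 0.5, BC_B = 0.25, pure_B = 0)
  ix <- gm_index(gm)
  L <- n_loci(gm)
  # parental frequencies with add-one smoothing over the locus's allele set
  pfreq <- function(rows) {
    lapply(seq_len(L), function(j) {
      cols <- (ix$offsets[j] + 1):ix$offsets[j + 1]
      cnt <- colSums(ix$dosage[rows, cols, drop = FALSE]) + smoothing
      cnt / sum(cnt)
    })
  }
  fa <- pfreq(ia); fb <- pfreq(ib)
  class_loglik <- function(fa, fb) {
    lf <- lapply(seq_len(L), function(j) {
      fc <- outer(fa[[j]], classes) + outer(fb[[j]], 1 - classes)
      log(fc)
    })
    geno_loglik(ix, lf)[iq, , drop = FALSE]
  }
  ll <- class_loglik(fa, fb)
  pi_c <- rep(1 / length(classes), length(classes))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- sweep(ll, 2L, log(pi_c), "+")
    lse <- row_logsumexp(lp)
    z <- exp(lp - lse)
    logL <- sum(lse)
    pi_c <- pmax(colMeans(z), 1e-12); pi_c <- pi_c / sum(pi_c)
    if (update_parents) {
      # posterior-weighted contribution of query genotypes to each pool
      wA <- as.numeric(z %*% classes); wB <- 1 - wA
      fa <- lapply(seq_len(L), function(j) {
        cols <- (ix$offsets[j] + 1):ix$offsets[j + 1]
        cnt <- colSums(ix$dosage[ia, cols, drop = FALSE]) +
          colSums(ix$dosage[iq, cols, drop = FALSE] * wA) + 1
        cnt / sum(cnt)
      })
      fb <- lapply(seq_len(L), function(j) {
        cols <- (ix$offsets[j] + 1):ix$offsets[j + 1]
        cnt <- colSums(ix$dosage[ib, cols, drop = FALSE]) +
          colSums(ix$dosage[iq, cols, drop = FALSE] * wB) + 1
        cnt / sum(cnt)
      })
      ll <- class_loglik(fa, fb)
    }
    if (abs(logL - ll_old) < tol) break
    ll_old <- logL
  }
  colnames(z) <- names(classes)
  rownames(z) <- rownames(gm$alleles)[iq]
  structure(list(posterior = z,
                 assignment = factor(names(classes)[max.col(z)],
                                     levels = names(classes)),
                 classes = classes, pi = setNames(pi_c, names(classes)),
                 query = iq),
            class = "hybrid_class_result")
}
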