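# Maximum-likelihood mixture clustering of multilocus genotypes under
# Hardy-Weinberg cluster frequencies, fitted by EM, with information-
# criterion model selection (AIC / BIC / KIC).

# Allele index representation: for each locus the sorted allele sizes and
# per-individual index pairs; plus the 0/1/2 dosage matrix over all alleles.
gm_index <- function(gm) {
  L <- n_loci(gm); n <- n_ind(gm)
  sizes <- vector("list", L)
  A1 <- A2 <- matrix(NA_integer_, n, L)
  blocks <- integer(L)
  for (j in seq_len(L)) {
    a <- alleles_at(gm, j)
    sizes[[j]] <- sort(unique(c(a[!is.na(a)])))
    A1[, j] <- match(a[, 1], sizes[[j]])
    A2[, j] <- match(a[, 2], sizes[[j]])
    blocks[j] <- length(sizes[[j]])
  }
  tot <- sum(blocks)
  dos <- matrix(0, n, tot)
  off <- c(0L, cumsum(blocks))
  cn <- character(tot)
  for (j in seq_len(L)) {
    ok <- which(!is.na(A1[, j]))
    idx1 <- cbind(ok, off[j] + A1[ok, j])
    idx2 <- cbind(ok, off[j] + A2[ok, j])
    dos[idx1] <- dos[idx1] + 1
    dos[idx2] <- dos[idx2] + 1
    cn[(off[j] + 1):off[j + 1]] <- paste0(gm$loci$name[j], ".", sizes[[j]])
  }
  colnames(dos) <- cn
  list(sizes = sizes, A1 = A1, A2 = A2, dosage = dos,
       blocks = blocks, offsets = off, typed = !is.na(A1))
}

# genotype log-likelihood matrix (n x K) given per-locus log-frequency
# matrices lf[[j]] (a_j x K)
geno_loglik <- function(ix, lf) {
  n <- nrow(ix$A1); K <- ncol(lf[[1]])
  ll <- matrix(0, n, K)
  log2c <- log(2)
  for (j in seq_along(lf)) {
    ok <- which(ix$typed[, j])
    if (!length(ok)) next
    a1 <- ix$A1[ok, j]; a2 <- ix$A2[ok, j]
    ll[ok, ] <- ll[ok, ] + lf[[j]][a1, , drop = FALSE] +
      lf[[j]][a2, , drop = FALSE] + (a1 != a2) * log2c
  }
  ll
}

# M-step: posterior-weighted allele frequencies with a small floor to keep
# the support positive.
mstep_freqs <- function(ix, z, floor = 1e-9) {
  cnts <- crossprod(ix$dosage, z)              # (sum a_l) x K
  lapply(seq_along(ix$blocks), function(j) {
    rows <- (ix$offsets[j] + 1):ix$offsets[j + 1]
    m <- cnts[rows, , drop = FALSE] + floor
    log(sweep(m, 2L, colSums(m), "/"))
  })
}

#' EM mixture clustering of multilocus genotypes
#'
#' Fits a K-component mixture in which each cluster has its own allele
#' frequencies per locus and genotypes follow Hardy-Weinberg proportions
#' within clusters: `P(genotype | cluster) = prod_l p^2` (homozygote) or
#' `2 p q` (heterozygote). The E-step computes membership posteriors, the
#' M-step re-estimates frequencies from posterior-weighted allele counts.
#' The first start is k-means on leading principal components of the allele
#' dosage matrix; remaining starts are random. The best of `n_restarts` runs
#' by log-likelihood is returned. The parameter count is
#' `nu = (K - 1) + K sum_l (a_l - 1)`.
#'
#' @param gm genotype_matrix
#' @param K number of clusters (>= 1)
#' @param n_restarts EM restarts (default 10)
#' @param seed RNG seed
#' @param max_iter maximum EM iterations (default 200)
#' @param tol log-likelihood convergence tolerance (default 1e-6)
#' @return object of class `cluster_model` with posteriors `z`, mixing
#'   proportions `pi`, per-locus log frequencies, `logL`, `nu`, criteria
#'   AIC/BIC/KIC, assignment vector, convergence flag, and the logL trace of
#'   the best run.
#' @export
em_cluster <- function(gm, K, n_restarts = 10L, seed = NULL,
                       max_iter = 200L, tol = 1e-6) {
  stopifnot(K >= 1L, K <= n_ind(gm))
  ix <- gm_index(gm)
  n <- n_ind(gm)
  if (!is.null(seed)) set.seed(as.integer(seed))
  run_em <- function(z0) {
    z <- z0; pi_k <- colMeans(z)
    ll_old <- -Inf; trace <- c(); converged <- FALSE
    for (it in seq_len(max_iter)) {
      lf <- mstep_freqs(ix, z)
      pi_k <- pmax(colMeans(z), 1e-12); pi_k <- pi_k / sum(pi_k)
      ll <- geno_loglik(ix, lf)
      ll <- sweep(ll, 2L, log(pi_k), "+")
      lse <- row_logsumexp(ll)
      logL <- sum(lse)
      z <- exp(ll - lse)
      # guard against empty clusters
      dead <- colSums(z) < 1e-8
      if (any(dead)) {
        for (k in which(dead)) z[sample(n, max(2L, n %/% K)), k] <- 1
        z <- z / rowSums(z)
      }
      trace <- c(trace, logL)
      if (is.finite(ll_old) && abs(logL - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- logL
    }
    list(z = z, pi = pi_k, lf = lf, logL = logL, trace = trace,
         converged = converged)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    z0 <- matrix(0, n, K)
    if (K == 1L) {
      z0[, 1] <- 1
    } else if (r == 1L) {
      npc <- min(10L, n - 1L, ncol(ix$dosage))
      pc <- prcomp(ix$dosage, rank. = npc)$x
      km <- suppressWarnings(kmeans(pc, centers = K, nstart = 3L))
      z0[cbind(seq_len(n), km$cluster)] <- 1
    } else {
      z0[cbind(seq_len(n), sample(K, n, replace = TRUE))] <- 1
    }
    # make sure no start has an empty cluster
    for (k in seq_len(K)) if (sum(z0[, k]) == 0) z0[sample(n, 1L), ] <- as.numeric(seq_len(K) == k)
    fit <- run_em(z0)
    if (is.null(best) || fit$logL > best$logL) best <- fit
    if (K == 1L) break
  }
  a_l <- vapply(ix$sizes, length, 0L)
  nu <- (K - 1) + K * sum(a_l - 1)
  structure(list(K = K, z = best$z, pi = best$pi, log_freqs = best$lf,
                 logL = best$logL, nu = nu,
                 AIC = -2 * best$logL + 2 * nu,
                 BIC = -2 * best$logL + nu * log(n),
                 KIC = -2 * best$logL + 3 * (nu + 1),
                 assignment = max.col(best$z),
                 converged = best$converged, trace = best$trace),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("mixture model: K = %d, logL = %.2f, nu = %d, KIC = %.2f\n",
              x$K, x$logL, x$nu, x$KIC))
  invisible(x)
}

#' Select the number of clusters by information criterion
#'
#' Runs [em_cluster()] across `K_range` and returns the argmin of the chosen
#' criterion (KIC by default, Cavanaugh's Kullback information criterion
#' `-2 logL + 3 (nu + 1)`). Ties break toward smaller K; non-converged fits
#' are flagged and excluded from the argmin.
#'
#' @param gm genotype_matrix
#' @param K_range integer vector of K values
#' @param criterion `"KIC"`, `"AIC"` or `"BIC"`
#' @param seed RNG seed
#' @param n_restarts per-K restarts
#' @param ... passed to [em_cluster()]
#' @return list with `K_star`, `table` (K, logL, nu, criterion, converged)
#'   and the fitted model at `K_star`.
#' @export
select_k <- function(gm, K_range, criterion = c("KIC", "AIC", "BIC"),
                     seed = NULL, n_restarts = 10L, ...) {
  criterion <- match.arg(criterion)
  if (!is.null(seed)) set.seed(as.integer(seed))
  fits <- lapply(K_range, function(K)
    em_cluster(gm, K, n_restarts = n_restarts, ...))
  crit <- vapply(fits, function(f) f[[criterion]], 0)
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  tab <- data.frame(K = K_range,
                    logL = vapply(fits, function(f) f$logL, 0),
                    nu = vapply(fits, function(f) f$nu, 0),
                    criterion = crit, converged = conv)
  usable <- which(conv)
  if (!length(usable)) usable <- seq_along(fits)
  best <- usable[which.min(crit[usable])]   # which.min takes first = smaller K on ties
  list(K_star = K_range[best], table = tab, model = fits[[best]],
       criterion = criterion)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b cluster label vectors of equal length
#' @return adjusted Rand index between -1 and 1
#' @export
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  stot <- choose(sum(tab), 2)
  exp_ <- si * sj / stot
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
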