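# Multivariate ordinations of genotype matrices: discriminant analysis of
# principal components (DAPC) and factorial correspondence analysis (FCA).

# dosage matrix with per-column mean imputation of missing entries
dosage_imputed <- function(gm) {
  ix <- gm_index(gm)
  d <- ix$dosage
  for (j in seq_along(ix$blocks)) {
    cols <- (ix$offsets[j] + 1):ix$offsets[j + 1]
    miss <- !ix$typed[, j]
    if (any(miss)) {
      mu <- colMeans(d[!miss, cols, drop = FALSE])
      d[miss, cols] <- rep(mu, each = sum(miss))
    }
  }
  d
}

#' Discriminant analysis of principal components
#'
#' Centres the individual-by-allele dosage matrix (mean-imputed), reduces it
#' by PCA, and runs linear discriminant analysis on the retained components.
#' When `n_pc` is not given it is chosen by stratified 90/10 cross-validation
#' over a grid, maximising mean held-out assignment success.
#'
#' @param gm genotype_matrix
#' @param groups factor over individuals (default populations)
#' @param n_pc number of principal components to retain (NULL = cross-validate)
#' @param n_rep cross-validation repetitions per grid point (default 10)
#' @param seed RNG seed
#' @return object of class `dapc_result` with discriminant coordinates
#'   (`ind_coord`), group assignment, eigenvalues, retained `n_pc`, and the
#'   cross-validation record.
#' @export
dapc <- function(gm, groups = gm$pop, n_pc = NULL, n_rep = 10L, seed = NULL) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (!is.null(seed)) set.seed(as.integer(seed))
  X <- dosage_imputed(gm)
  n <- nrow(X)
  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  max_pc <- min(n - nlevels(groups) - 1L, sum(pca$sdev > 1e-8))
  cv <- NULL
  if (is.null(n_pc)) {
    grid <- unique(pmax(1L, round(seq(1L, max_pc, length.out = min(8L, max_pc)))))
    succ <- matrix(NA_real_, length(grid), n_rep)
    for (r in seq_len(n_rep)) {
      test <- unlist(lapply(split(seq_len(n), groups), function(ii)
        if (length(ii) >= 2L) sample(ii, max(1L, round(0.1 * length(ii)))) else integer()))
      train <- setdiff(seq_len(n), test)
      if (!length(test) || nlevels(droplevels(groups[train])) < nlevels(groups)) next
      for (gi in seq_along(grid)) {
        npc <- min(grid[gi], length(train) - nlevels(groups) - 1L)
        fit <- MASS::lda(pca$x[train, seq_len(npc), drop = FALSE],
                         grouping = groups[train])
        pr <- predict(fit, pca$x[test, seq_len(npc), drop = FALSE])$class
        succ[gi, r] <- mean(pr == groups[test])
      }
    }
    mean_succ <- rowMeans(succ, na.rm = TRUE)
    n_pc <- grid[which.max(mean_succ)]
    cv <- data.frame(n_pc = grid, success = mean_succ)
  }
  if (n_pc >= n - nlevels(groups)) stop("n_pc too large for the group design")
  fit <- MASS::lda(pca$x[, seq_len(n_pc), drop = FALSE], grouping = groups)
  pr <- predict(fit)
  structure(list(ind_coord = pr$x, assignment = pr$class, groups = groups,
                 eigenvalues = fit$svd^2, n_pc = n_pc, cv = cv,
                 pca_sdev = pca$sdev,
                 reassignment_success = mean(pr$class == groups)),
            class = "dapc_result")
}

#' Factorial correspondence analysis of genotypes
#'
#' Correspondence analysis (SVD of standardised residuals) of the
#' individual-by-allele 0/1/2 table, with population barycentres as the
#' means of member coordinates and per-axis explained-variance fractions.
#' All-constant columns are dropped with a warning.
#'
#' @param gm genotype_matrix
#' @param n_axes number of axes to keep (default 3)
#' @return object of class `fca_result` with `ind_coord`, `barycentres`,
#'   `eigenvalues`, `explained` (fraction of total inertia per axis).
#' @export
fca <- function(gm, n_axes = 3L) {
  if (nlevels(gm$pop) < 3L) stop("need >= 3 populations")
  ix <- gm_index(gm)
  X <- ix$dosage
  keep <- apply(X, 2L, function(col) var(col) > 0)
  if (!all(keep)) {
    warning(sum(!keep), " constant allele columns dropped")
    X <- X[, keep, drop = FALSE]
  }
  P <- X / sum(X)
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  pos <- sv$d > 1e-10
  eig <- sv$d[pos]^2
  n_axes <- min(n_axes, sum(pos))
  coord <- sweep(sv$u[, seq_len(n_axes), drop = FALSE], 1L, sqrt(r), "/") %*%
    diag(sv$d[seq_len(n_axes)], n_axes)
  rownames(coord) <- rownames(gm$alleles)
  colnames(coord) <- paste0("Axis", seq_len(n_axes))
  bary <- apply(coord, 2L, function(cl) tapply(cl, gm$pop, mean))
  structure(list(ind_coord = coord, barycentres = bary,
                 eigenvalues = eig,
                 explained = eig / sum(eig)),
            class = "fca_result")
}
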