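# LD-based effective population size (Burrows composite r^2, Waples-style
# sampling correction, NeEstimator-type point estimate and parametric CI).

#' Effective population size from linkage disequilibrium
#'
#' For every locus pair, the Burrows composite disequilibrium is computed for
#' each allele pair (after applying the allele-exclusion rule), converted to
#' a squared correlation `r^2 = Delta^2 / (p(1-p) q(1-q))`, and averaged over
#' all comparisons. The sampling expectation `1/S + 3.19/S^2` (harmonic mean
#' sample size `S >= 30`; `1/S + 0.69/S^2` below) is subtracted to give the
#' drift component `r2_drift`, from which
#' `Ne(monogamy) = (2/3 + sqrt(4/9 - 7.2 r2)) / (2 r2)` and
#' `Ne(random)   = (1/3 + sqrt(1/9 - 2.76 r2)) / (2 r2)`.
#' Non-positive `r2_drift` yields `Ne = Inf`. The parametric CI treats
#' `n_comparisons * r2_mean / r2_true` as chi-squared with `n_comparisons`
#' degrees of freedom.
#'
#' @param gm genotype_matrix
#' @param population population label
#' @param crit allele-exclusion rule: `"singletons"` (drop alleles observed
#'   exactly once in the population, the conservative default) or a numeric
#'   minimum allele frequency; `"none"` keeps everything.
#' @param mating `"monogamy"` (lifetime monogamy) or `"random"`.
#' @return list of class `ne_estimate`
#' @export
ne_ld <- function(gm, population, crit = "singletons", mating = c("monogamy", "random")) {
  mating <- match.arg(mating)
  sel <- gm$pop == population
  L <- n_loci(gm)
  r2s <- c(); Ss <- c()
  keep_allele <- function(cnt) {
    if (identical(crit, "singletons")) cnt > 1L
    else if (identical(crit, "none")) cnt > 0L
    else cnt / sum(cnt) >= as.numeric(crit) & cnt > 0L
  }
  polymorphic <- 0L
  locdat <- vector("list", L)
  for (j in seq_len(L)) {
    a <- alleles_at(gm, j)[sel, , drop = FALSE]
    locdat[[j]] <- a
    ok <- !is.na(a[, 1])
    cnt <- table(c(a[ok, ]))
    if (sum(keep_allele(cnt)) >= 2L) polymorphic <- polymorphic + 1L
  }
  if (polymorphic < 2L) stop("need >= 2 polymorphic loci after exclusions")
  for (j1 in seq_len(L - 1L)) for (j2 in (j1 + 1L):L) {
    A <- locdat[[j1]]; B <- locdat[[j2]]
    ok <- !is.na(A[, 1]) & !is.na(B[, 1])
    if (sum(ok) < 2L) next
    A <- A[ok, , drop = FALSE]; B <- B[ok, , drop = FALSE]
    n <- nrow(A)
    sizesA <- sort(unique(c(A))); sizesB <- sort(unique(c(B)))
    cA <- tabulate(match(c(A), sizesA), length(sizesA))
    cB <- tabulate(match(c(B), sizesB), length(sizesB))
    kA <- which(keep_allele(setNames(cA, sizesA)))
    kB <- which(keep_allele(setNames(cB, sizesB)))
    if (length(kA) < 2L || length(kB) < 2L) next
    Ai <- matrix(match(A, sizesA), ncol = 2L)
    Bi <- matrix(match(B, sizesB), ncol = 2L)
    bg <- burrows_gametes(Ai, Bi, length(sizesA), length(sizesB))
    # composite covariance per allele pair, small-sample factor n/(n-1)
    p <- bg$x[kA]; q <- bg$y[kB]
    usep <- p > 0 & p < 1; useq <- q > 0 & q < 1
    if (!any(usep) || !any(useq)) next
    kA2 <- kA[usep]; kB2 <- kB[useq]; p <- p[usep]; q <- q[useq]
    XY <- crossprod(bg$X[, kA2, drop = FALSE], bg$Y[, kB2, drop = FALSE])
    delta <- (XY / (2 * n) - 2 * outer(p, q)) * n / (n - 1)
    r2m <- delta^2 / outer(p * (1 - p), q * (1 - q))
    r2s <- c(r2s, as.numeric(r2m))
    Ss <- c(Ss, rep(n, length(r2m)))
  }
  if (!length(r2s)) stop("no usable allele-pair comparisons")
  S <- 1 / mean(1 / Ss)              # harmonic mean sample size
  r2_mean <- mean(r2s)
  expect <- function(S) if (S >= 30) 1 / S + 3.19 / S^2 else 1 / S + 0.69 / S^2
  r2_drift <- r2_mean - expect(S)
  ne_point <- function(r2) {
    if (r2 <= 0) return(Inf)
    if (mating == "monogamy") {
      disc <- max(0, 4 / 9 - 7.2 * r2)  # clamp: very large r2 => tiny Ne
      (2 / 3 + sqrt(disc)) / (2 * r2)
    } else {
      disc <- max(0, 1 / 9 - 2.76 * r2)
      (1 / 3 + sqrt(disc)) / (2 * r2)
    }
  }
  df <- length(r2s)
  r2_lo <- r2_mean * df / qchisq(0.975, df)
  r2_hi <- r2_mean * df / qchisq(0.025, df)
  ci <- sort(c(ne_point(r2_lo - expect(S)), ne_point(r2_hi - expect(S))), na.last = TRUE)
  structure(list(population = population, r2_mean = r2_mean,
                 r2_drift = r2_drift, S = S,
                 Ne_point = ne_point(r2_drift),
                 CI = ci, n_comparisons = df,
                 crit = crit, mating = mating,
                 low_confidence = S < 10),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Ne(LD, %s) for %s: %.1f  [%.1f, %.1f]  (r2=%.5f, S=%.1f, %d comparisons)\n",
              x$mating, x$population, x$Ne_point, x$CI[1], x$CI[2],
              x$r2_mean, x$S, x$n_comparisons))
  invisible(x)
}
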