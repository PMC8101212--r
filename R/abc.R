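# Approximate Bayesian Computation: reference tables over demographic
# scenarios, rejection + LDA / multinomial-logistic model choice, and
# local-linear (Beaumont) parameter posteriors.

#' Build an ABC reference table
#'
#' For each scenario and each of `n_sims` rows: draw all parameters from
#' their priors, simulate a dataset, and record the summary-statistic
#' vector. Standardisation constants (pooled mean and SD per statistic) are
#' stored with the table.
#'
#' @param scenarios list of [scenario()] objects (the competing models)
#' @param model [mutation_model()]
#' @param n_sims simulations per scenario
#' @param n_loci loci per simulated dataset (default 15)
#' @param seed master seed (deterministically split per row)
#' @param progress print a dot every 1000 rows
#' @return object of class `reference_table` with `stats` (matrix),
#'   `model_id` (factor), `params` (matrix of drawn values), and
#'   `standardisation`
#' @export
build_reference_table <- function(scenarios, model, n_sims, n_loci = 15L,
                                  seed = 1L, progress = FALSE) {
  loci <- loci_frame(sim_locus_panel(n_loci, model$n_states))
  rows <- list(); mids <- character(0); pars <- list()
  set.seed(as.integer(seed))
  r <- 0L
  for (s in seq_along(scenarios)) {
    scn <- scenarios[[s]]
    for (b in seq_len(n_sims)) {
      r <- r + 1L
      ok <- FALSE; tries <- 0L
      while (!ok && tries < 5L) {
        tries <- tries + 1L
        res <- tryCatch({
          draw <- sample_priors(scn, model, n_loci = n_loci)
          gm <- simulate_dataset(scn, draw, loci = loci, n_states = model$n_states)
          st <- summary_statistics(gm, groups = names(scn$samples))
          list(draw = draw, st = st)
        }, error = function(e) NULL)
        ok <- !is.null(res) && all(is.finite(res$st))
      }
      if (!ok) stop("simulation kept failing for scenario ", scn$name)
      rows[[r]] <- res$st
      mids[r] <- scn$name
      pars[[r]] <- c(res$draw$values,
                     mu_mean = res$draw$mu_mean, P = res$draw$P,
                     mu_sni = res$draw$mu_sni)
      if (progress && r %% 1000L == 0L) cat(".")
    }
  }
  if (progress) cat("\n")
  stats <- do.call(rbind, rows)
  # parameter sets differ across scenarios: align on the union of names
  pnames <- unique(unlist(lapply(pars, names)))
  params <- matrix(NA_real_, length(pars), length(pnames),
                   dimnames = list(NULL, pnames))
  for (i in seq_along(pars)) params[i, names(pars[[i]])] <- pars[[i]]
  mu <- colMeans(stats); sdv <- apply(stats, 2L, sd)
  structure(list(stats = stats, model_id = factor(mids, levels = vapply(scenarios, `[[`, "", "name")),
                 params = params,
                 standardisation = list(mean = mu, sd = sdv),
                 n_per_model = n_sims),
            class = "reference_table")
}

# logit transform of statistics range-mapped to (0,1) by pooled min/max
# (epsilon-padded so observed values at the boundary stay finite)
logit_map <- function(x, lo, hi) {
  eps <- 0.001 * (hi - lo + 1e-12)
  z <- (x - (lo - eps)) / ((hi + eps) - (lo - eps))
  z <- pmin(pmax(z, 1e-9), 1 - 1e-9)
  log(z / (1 - z))
}

# Weighted multinomial (softmax) logistic regression fitted by BFGS with
# analytic gradient; returns class probabilities at x0 with delta-method SEs.
wmultinom_predict <- function(X, y, w, x0) {
  K <- nlevels(y); p <- ncol(X)
  Xd <- cbind(1, X)
  Y <- matrix(0, nrow(Xd), K); Y[cbind(seq_len(nrow(Xd)), as.integer(y))] <- 1
  npar <- (K - 1) * (p + 1)
  probs_of <- function(beta, Xd) {
    B <- matrix(beta, p + 1, K - 1)
    eta <- cbind(0, Xd %*% B)
    exp(eta - row_logsumexp(eta))
  }
  nll <- function(beta) {
    pr <- probs_of(beta, Xd)
    -sum(w * log(pmax(rowSums(Y * pr), 1e-300)))
  }
  grad <- function(beta) {
    pr <- probs_of(beta, Xd)
    G <- t(Xd) %*% ((pr - Y)[, -1, drop = FALSE] * w)
    as.numeric(G)
  }
  fit <- optim(rep(0, npar), nll, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  H <- optimHess(fit$par, nll, grad)
  Vb <- tryCatch(solve(H + diag(1e-8, npar)), error = function(e) diag(1e6, npar))
  x0d <- matrix(c(1, x0), nrow = 1)
  pr0 <- as.numeric(probs_of(fit$par, x0d))
  # delta method: d pr0_k / d beta
  se <- numeric(K)
  for (k in seq_len(K)) {
    g <- numeric(npar)
    for (j in seq_len(K - 1)) {
      dk <- as.numeric(k == j + 1)
      g[((j - 1) * (p + 1) + 1):(j * (p + 1))] <- pr0[k] * (dk - pr0[j + 1]) * as.numeric(x0d)
    }
    se[k] <- sqrt(max(0, t(g) %*% Vb %*% g))
  }
  list(prob = pr0, se = se, converged = fit$convergence == 0)
}

#' ABC model choice by rejection + LDA + weighted multinomial logistic
#'
#' Standardised Euclidean distances between simulated and observed summary
#' statistics select the closest `retain` fraction; the retained statistics
#' are logit-transformed (range-mapped to (0,1) by pooled min/max), reduced
#' by linear discriminant analysis on the model label, and fed with
#' Epanechnikov weights `w = 1 - (d/d_max)^2` into a weighted multinomial
#' logistic regression evaluated at the observed point. The best model is
#' flagged significant when its 95% CI does not overlap the second-best
#' model's. A rejection-only posterior (model frequencies among retained
#' rows) is reported alongside.
#'
#' @param ref [build_reference_table()] result
#' @param observed named statistic vector (same design as the table)
#' @param retain retained fraction (default 0.01)
#' @return object of class `model_posterior`
#' @export
abc_model_choice <- function(ref, observed, retain = 0.01) {
  if (nlevels(ref$model_id) < 2L) stop("need >= 2 models")
  st <- ref$stats
  observed <- observed[colnames(st)]
  mu <- ref$standardisation$mean; sdv <- pmax(ref$standardisation$sd, 1e-12)
  Z <- sweep(sweep(st, 2L, mu), 2L, sdv, "/")
  z0 <- (observed - mu) / sdv
  d <- sqrt(rowSums(sweep(Z, 2L, z0)^2))
  n_keep <- max(2L, ceiling(retain * nrow(st)))
  keep <- order(d)[seq_len(n_keep)]
  dmax <- max(d[keep])
  w <- 1 - (d[keep] / (dmax * (1 + 1e-9)))^2
  y <- droplevels(ref$model_id[keep])
  lo <- apply(st, 2L, min); hi <- apply(st, 2L, max)
  Xl <- sapply(seq_len(ncol(st)), function(j) logit_map(st[keep, j], lo[j], hi[j]))
  x0l <- vapply(seq_len(ncol(st)), function(j) logit_map(observed[j], lo[j], hi[j]), 0)
  vv <- apply(Xl, 2L, var)
  use <- vv > 1e-12
  Xl <- Xl[, use, drop = FALSE]; x0l <- x0l[use]
  lda_ok <- nlevels(y) >= 2L && all(table(y) >= 2L)
  X <- NULL; x0 <- NULL
  if (lda_ok) {
    fit <- tryCatch(MASS::lda(Xl, grouping = y), error = function(e) NULL)
    if (!is.null(fit)) {
      X <- Xl %*% fit$scaling
      x0 <- as.numeric(matrix(x0l, 1) %*% fit$scaling)
    }
  }
  if (is.null(X)) { X <- Xl; x0 <- x0l }   # degenerate LDA fallback
  # guard: models absent from the retained set get probability ~0
  pred <- wmultinom_predict(X, y, w, x0)
  models <- levels(ref$model_id)
  prob <- setNames(rep(0, length(models)), models)
  se <- setNames(rep(0, length(models)), models)
  prob[levels(y)] <- pred$prob / sum(pred$prob)
  se[levels(y)] <- pred$se
  ci <- rbind(lo = pmax(0, prob - 1.96 * se), hi = pmin(1, prob + 1.96 * se))
  rej <- table(factor(ref$model_id[keep], levels = models)) / n_keep
  ord <- order(prob, decreasing = TRUE)
  signif_best <- length(models) >= 2L &&
    ci["lo", ord[1]] > ci["hi", ord[2]]
  structure(list(posterior = prob, ci = ci,
                 rejection_posterior = as.numeric(rej),
                 best = models[ord[1]], significant = signif_best,
                 retained = n_keep, converged = pred$converged),
            class = "model_posterior")
}

#' @export
print.model_posterior <- function(x, ...) {
  cat("ABC model posteriors (", x$retained, " retained ):\n")
  for (m in names(x$posterior))
    cat(sprintf("  %-12s P = %.3f  [%.3f, %.3f]\n", m, x$posterior[m],
                x$ci["lo", m], x$ci["hi", m]))
  cat("best:", x$best, if (x$significant) "(significant)" else "", "\n")
  invisible(x)
}

#' ABC local-linear parameter posterior (Beaumont regression adjustment)
#'
#' Retains the closest fraction of one model's simulations, logit-maps each
#' parameter to its prior bounds, regresses it on the standardised
#' statistics with Epanechnikov weights, adjusts the retained draws to the
#' observed point (`theta* = theta - B (s - s_obs)`), back-transforms, and
#' returns weighted posterior quantiles. Adjusted draws cannot leave the
#' prior support thanks to the logit map.
#'
#' @param ref reference table
#' @param model_name scenario to condition on
#' @param observed observed statistic vector
#' @param bounds named list of `c(lo, hi)` prior bounds per parameter column
#'   (defaults to the observed min/max of the draws, padded)
#' @param retain retained fraction (default 0.01, relative to that model's rows)
#' @return object of class `parameter_posterior` with adjusted draws,
#'   weights and quantiles (2.5/25/50/75/97.5%)
#' @export
abc_parameter_posterior <- function(ref, model_name, observed, bounds = NULL,
                                    retain = 0.01) {
  sel <- ref$model_id == model_name
  if (!any(sel)) stop("unknown model: ", model_name)
  st <- ref$stats[sel, , drop = FALSE]
  par <- ref$params[sel, , drop = FALSE]
  par <- par[, colSums(!is.finite(par)) == 0L, drop = FALSE]
  observed <- observed[colnames(st)]
  mu <- colMeans(st); sdv <- pmax(apply(st, 2L, sd), 1e-12)
  Z <- sweep(sweep(st, 2L, mu), 2L, sdv, "/")
  z0 <- (observed - mu) / sdv
  d <- sqrt(rowSums(sweep(Z, 2L, z0)^2))
  n_keep <- max(10L, ceiling(retain * nrow(st)))
  keep <- order(d)[seq_len(n_keep)]
  dmax <- max(d[keep])
  w <- 1 - (d[keep] / (dmax * (1 + 1e-9)))^2
  S <- Z[keep, , drop = FALSE]
  S <- S[, apply(S, 2L, var) > 1e-12, drop = FALSE]
  z0s <- z0[colnames(S)]
  quants <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  out_q <- list(); adj <- list()
  for (pn in colnames(par)) {
    th <- par[keep, pn]
    b <- bounds[[pn]] %||% (range(par[, pn]) + c(-1, 1) * 1e-9)
    tl <- logit_map(th, b[1], b[2])
    X <- cbind(1, S)
    WX <- X * w
    beta <- tryCatch(solve(crossprod(X, WX), crossprod(WX, tl)),
                     error = function(e)
                       solve(crossprod(X, WX) + diag(1e-6, ncol(X)),
                             crossprod(WX, tl)))
    resid <- as.numeric(tl - X %*% beta)
    tl_adj <- as.numeric(c(1, z0s) %*% beta) + resid
    # inverse of logit_map
    eps <- 0.001 * (b[2] - b[1] + 1e-12)
    zz <- 1 / (1 + exp(-tl_adj))
    th_adj <- (b[1] - eps) + zz * ((b[2] + eps) - (b[1] - eps))
    th_adj <- pmin(pmax(th_adj, b[1]), b[2])
    adj[[pn]] <- th_adj
    out_q[[pn]] <- weighted_quantile(th_adj, w, quants)
  }
  qmat <- do.call(rbind, out_q)
  colnames(qmat) <- paste0("q", quants * 100)
  structure(list(model = model_name, quantiles = qmat,
                 draws = do.call(cbind, adj), weights = w,
                 retained = n_keep),
            class = "parameter_posterior")
}
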