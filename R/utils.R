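# Internal helpers shared across modules.

# Deterministic sub-seed derived from a master seed and a stage label.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
spawn_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483587 + 1)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

# Symmetric-capable Dirichlet sampler via gammas.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# log of C(n, k) tolerant of k > n (returns -Inf).
lchoose_safe <- function(n, k) {
  out <- suppressWarnings(lchoose(n, k))
  out[k > n] <- -Inf
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Great-circle distance in km between points given as decimal degrees.
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  6371.0088 * 2 * asin(pmin(1, sqrt(a)))
}

# Weighted quantiles (type 4-ish linear interpolation on the weighted ECDF).
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  sapply(probs, function(p) {
    i <- which(cw >= p)[1]
    if (is.na(i)) x[length(x)] else x[i]
  })
}
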