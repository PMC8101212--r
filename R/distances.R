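# Population distances, neighbour-joining, and Mantel isolation-by-distance.

#' Cavalli-Sforza and Edwards chord distance matrix
#'
#' `D_CH = (2/(pi L)) * sum_l sqrt(2 (1 - sum_a sqrt(p_al q_al)))` over the
#' `L` loci typed in both populations of a pair.
#'
#' @param freqs a [allele_frequencies()] table
#' @return symmetric matrix of chord distances (class `dist_matrix` list with
#'   `values` and `kind`).
#' @export
chord_distance_matrix <- function(freqs) {
  G <- length(freqs$groups); Lall <- length(freqs$loci)
  d <- matrix(0, G, G, dimnames = list(freqs$groups, freqs$groups))
  fr <- lapply(seq_len(Lall), function(j) {
    m <- freqs$counts[[j]]
    sweep(m, 2L, pmax(colSums(m), 1L), "/")
  })
  typed <- freqs$gene_count > 0
  for (i in seq_len(G - 1L)) for (k in (i + 1L):G) {
    shared <- which(typed[i, ] & typed[k, ])
    if (!length(shared)) { d[i, k] <- d[k, i] <- NA_real_; next }
    s <- 0
    for (j in shared) {
      cosang <- sum(sqrt(fr[[j]][, i] * fr[[j]][, k]))
      s <- s + sqrt(2 * max(0, 1 - cosang))
    }
    d[i, k] <- d[k, i] <- 2 / (pi * length(shared)) * s
  }
  structure(list(values = d, kind = "chord"), class = "dist_matrix")
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q-criterion. Negative
#' branch lengths are clamped to zero (raw values kept in the returned
#' object). The result carries a Newick serialisation; on additive input the
#' tree metric reproduces the distances exactly.
#'
#' @param dist symmetric distance matrix (plain matrix or `dist_matrix`)
#' @return list of class `nj_tree` with `newick`, `edges`
#'   (parent, child, length, raw_length) and `labels`.
#' @export
neighbor_joining <- function(dist) {
  D <- if (inherits(dist, "dist_matrix")) dist$values else as.matrix(dist)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  labels <- rownames(D) %||% paste0("t", seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 labels")
  # node bookkeeping: leaves 1..n, internal nodes get successive ids
  active <- seq_len(n)
  node_of <- seq_len(n)
  next_id <- n + 1L
  edges <- NULL
  newick <- as.list(labels)
  names(newick) <- as.character(seq_len(n))
  Dm <- D
  repeat {
    m <- length(active)
    if (m == 2L) break
    rs <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(rs, rs, `+`)
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    dij <- Dm[i, j]
    li <- dij / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- dij - li
    u <- next_id; next_id <- next_id + 1L
    edges <- rbind(edges,
                   c(u, node_of[i], max(0, li), li),
                   c(u, node_of[j], max(0, lj), lj))
    newu <- sprintf("(%s:%.10g,%s:%.10g)",
                    newick[[as.character(node_of[i])]], max(0, li),
                    newick[[as.character(node_of[j])]], max(0, lj))
    newick[[as.character(u)]] <- newu
    dnew <- (Dm[i, -c(i, j), drop = FALSE] + Dm[j, -c(i, j), drop = FALSE] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], as.numeric(dnew)),
                c(as.numeric(dnew), 0))
    node_of <- c(node_of[keep], u)
    active <- seq_len(m - 1L)
  }
  # final join: splice the remaining node into the root's child list so the
  # result is the standard unrooted (trifurcating-root) representation
  lfin <- Dm[1, 2]
  edges <- rbind(edges, c(node_of[2], node_of[1], max(0, lfin), lfin))
  root_nwk <- newick[[as.character(node_of[2])]]
  inner <- substr(root_nwk, 2, nchar(root_nwk) - 1)
  nwk <- sprintf("(%s,%s:%.10g);", inner,
                 newick[[as.character(node_of[1])]], max(0, lfin))
  colnames(edges) <- c("parent", "child", "length", "raw_length")
  structure(list(newick = nwk, edges = edges, labels = labels),
            class = "nj_tree")
}

#' @export
print.nj_tree <- function(x, ...) {
  cat("neighbour-joining tree over", length(x$labels), "labels\n")
  cat(substr(x$newick, 1, 200), if (nchar(x$newick) > 200) "...", "\n")
  invisible(x)
}

#' Great-circle geographic distance matrix
#'
#' Haversine distances in km between population coordinates, with a 1 km
#' floor applied before the log transform used for isolation by distance
#' (so coincident sites do not produce `-Inf`).
#'
#' @param coords data.frame with columns population, lat, lon
#' @param floor_km minimum distance (default 1)
#' @return symmetric matrix of km
#' @export
geo_distance_matrix <- function(coords, floor_km = 1) {
  G <- nrow(coords)
  d <- matrix(0, G, G, dimnames = list(coords$population, coords$population))
  for (i in seq_len(G - 1L)) for (k in (i + 1L):G) {
    km <- haversine_km(coords$lat[i], coords$lon[i], coords$lat[k], coords$lon[k])
    d[i, k] <- d[k, i] <- max(km, floor_km)
  }
  d
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation between the off-diagonal vectors of linearised genetic
#' differentiation `FST/(1-FST)` and log geographic distance, with a
#' one-sided permutation p-value obtained by jointly permuting the rows and
#' columns of one matrix.
#'
#' @param gen symmetric genetic distance matrix (already linearised), or a
#'   `pairwise_fst` object (linearised internally)
#' @param geo symmetric geographic distance matrix in km (log taken here),
#'   or an already-transformed matrix when `log_geo = FALSE`
#' @param n_perm permutations (default 9999)
#' @param seed RNG seed
#' @param log_geo take the natural log of `geo` first (default TRUE)
#' @return list of class `mantel_result` with `r`, `p_value`, `n_perm`
#' @export
mantel_ibd <- function(gen, geo, n_perm = 9999L, seed = NULL, log_geo = TRUE) {
  if (inherits(gen, "pairwise_fst")) gen <- linearised_fst(gen)
  if (log_geo) geo <- log(geo)
  G <- nrow(gen)
  if (G < 4L) stop("need >= 4 populations")
  low <- lower.tri(gen)
  r_obs <- cor(gen[low], geo[low])
  hits <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pp <- sample(G)
      if (cor(gen[pp, pp][low], geo[low]) >= r_obs - 1e-12) hits <- hits + 1L
    }
  })
  structure(list(r = r_obs, p_value = (hits + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "mantel_result")
}
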