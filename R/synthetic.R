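# Labelled synthetic microsatellite worlds with known truth, for testing
# every stage of the pipeline without external data. Two generator families:
# fast Dirichlet-drift worlds (statistics tests) and the coalescent-backed
# simulator (ABC tests); both emit genotype_matrix objects.

default_synth_loci <- function(n_loci = 15L, n_alleles = 12L) {
  lapply(seq_len(n_loci), function(j) {
    motif <- if (j %% 2L == 1L) 2L else 3L
    locus_def(sprintf("S%02d", j), motif, c(98, 100 + motif * 60 + 2))
  })
}

# allele size lattice for a synthetic locus
synth_sizes <- function(lf, j, n_alleles) {
  100 + lf$motif_length[j] * seq_len(n_alleles)
}

draw_hwe_genotypes <- function(n, sizes, p) {
  a1 <- sample(sizes, n, replace = TRUE, prob = p)
  a2 <- sample(sizes, n, replace = TRUE, prob = p)
  cbind(pmin(a1, a2), pmax(a1, a2))
}

#' Island-model world with a target FST
#'
#' Ancestral allele frequencies are symmetric-Dirichlet; deme frequencies
#' are Dirichlet around the ancestor with concentration
#' `p (1 - F) / F`, which gives `E[FST] ~ F`; genotypes are drawn under
#' Hardy-Weinberg within demes.
#'
#' @param k_demes number of demes
#' @param n_per_deme diploid individuals per deme (scalar or vector)
#' @param n_loci loci (default 15)
#' @param target_fst F in (0, 0.9)
#' @param n_alleles ancestral alleles per locus (default 12)
#' @param seed RNG seed
#' @return list with `gm` (genotype_matrix) and `truth` (generator record)
#' @export
make_island_world <- function(k_demes, n_per_deme, n_loci = 15L,
                              target_fst = 0.24, n_alleles = 12L, seed = 1L) {
  stopifnot(target_fst > 0, target_fst < 0.9)
  if (n_alleles <= 2L && target_fst > 0.5)
    warning("high target FST with <= 2 alleles may be infeasible")
  set.seed(as.integer(seed))
  if (length(n_per_deme) == 1L) n_per_deme <- rep(n_per_deme, k_demes)
  loci <- default_synth_loci(n_loci)
  lf <- loci_frame(loci)
  conc <- (1 - target_fst) / target_fst
  n <- sum(n_per_deme)
  alle <- matrix(NA_real_, n, 2L * n_loci)
  pops <- rep(sprintf("deme%02d", seq_len(k_demes)), n_per_deme)
  anc <- deme_freqs <- vector("list", n_loci)
  for (j in seq_len(n_loci)) {
    sizes <- synth_sizes(lf, j, n_alleles)
    p0 <- as.numeric(rdirichlet(1, rep(1, n_alleles)))
    fr <- rdirichlet(k_demes, p0 * conc)
    anc[[j]] <- setNames(p0, sizes); deme_freqs[[j]] <- fr
    row0 <- 0L
    for (d in seq_len(k_demes)) {
      g <- draw_hwe_genotypes(n_per_deme[d], sizes, fr[d, ])
      alle[(row0 + 1):(row0 + n_per_deme[d]), c(2L * j - 1L, 2L * j)] <- g
      row0 <- row0 + n_per_deme[d]
    }
  }
  gm <- genotype_matrix(alle, lf, factor(pops), validate = FALSE)
  list(gm = gm,
       truth = list(generator = "island_world", k_demes = k_demes,
                    n_per_deme = n_per_deme, n_loci = n_loci,
                    target_fst = target_fst, n_alleles = n_alleles,
                    seed = seed, ancestral = anc, deme_freqs = deme_freqs))
}

#' Panel of parentals, F1 hybrids and first-generation backcrosses
#'
#' Two parental frequency sets at the requested differentiation; F1
#' individuals take one allele from each parental pool per locus; a
#' backcross takes one parental gamete and one F1 gamete.
#'
#' @param parent_fst differentiation between the parental pools (> 0)
#' @param n_pure pure individuals per parental pool
#' @param n_f1 F1 hybrids
#' @param n_bc backcrosses per direction (BC_A and BC_B each)
#' @param n_loci loci (default 15)
#' @param n_alleles ancestral alleles per locus (default 12)
#' @param seed RNG seed
#' @return list with `gm` and `truth` (labels per individual)
#' @export
make_hybrid_panel <- function(parent_fst, n_pure = 30L, n_f1 = 20L, n_bc = 20L,
                              n_loci = 15L, n_alleles = 12L, seed = 1L) {
  stopifnot(parent_fst > 0)
  set.seed(as.integer(seed))
  loci <- default_synth_loci(n_loci)
  lf <- loci_frame(loci)
  conc <- (1 - parent_fst) / parent_fst
  labels <- c(rep("pure_A", n_pure), rep("pure_B", n_pure),
              rep("F1", n_f1), rep("BC_A", n_bc), rep("BC_B", n_bc))
  n <- length(labels)
  alle <- matrix(NA_real_, n, 2L * n_loci)
  fa <- fb <- vector("list", n_loci)
  for (j in seq_len(n_loci)) {
    sizes <- synth_sizes(lf, j, n_alleles)
    p0 <- as.numeric(rdirichlet(1, rep(1, n_alleles)))
    fr <- rdirichlet(2, p0 * conc)
    fa[[j]] <- fr[1, ]; fb[[j]] <- fr[2, ]
    gam <- function(f) sample(sizes, 1, prob = f)
    g_f1 <- function() c(gam(fr[1, ]), gam(fr[2, ]))
    for (i in seq_len(n)) {
      g <- switch(labels[i],
        pure_A = c(gam(fr[1, ]), gam(fr[1, ])),
        pure_B = c(gam(fr[2, ]), gam(fr[2, ])),
        F1 = g_f1(),
        BC_A = c(gam(fr[1, ]), g_f1()[sample(2, 1)]),
        BC_B = c(gam(fr[2, ]), g_f1()[sample(2, 1)]))
      alle[i, c(2L * j - 1L, 2L * j)] <- sort(g)
    }
  }
  gm <- genotype_matrix(alle, lf, factor(labels, levels = unique(labels)),
                        validate = FALSE)
  list(gm = gm,
       truth = list(generator = "hybrid_panel", labels = labels,
                    parent_fst = parent_fst, freq_A = fa, freq_B = fb,
                    seed = seed))
}

# Forward Wright-Fisher drift of a gamete pool: haplotypes over L loci with
# free recombination; returns the final 2N x L gamete matrix. Builds both
# drift (allelic-richness loss) and cross-locus LD.
# recomb: probability of switching parental haplotype between adjacent loci
# (0.5 = free recombination; lower values emulate physical linkage and build
# persistent multi-locus LD blocks)
forward_drift_pool_from <- function(pool, n_dip, generations, recomb = 0.5) {
  L <- ncol(pool)
  ng <- 2L * n_dip
  if (nrow(pool) != ng)
    pool <- pool[sample(nrow(pool), ng, replace = nrow(pool) < ng), , drop = FALSE]
  for (g in seq_len(generations)) {
    # each offspring gamete: pick a parent (pair of rows); haplotype choice
    # follows a Markov chain along loci with switch probability `recomb`
    parents <- sample(n_dip, ng, replace = TRUE)
    r1 <- 2L * parents - 1L; r2 <- 2L * parents
    pick <- matrix(FALSE, ng, L)
    pick[, 1] <- runif(ng) < 0.5
    if (L > 1L) for (j in 2:L)
      pick[, j] <- xor(pick[, j - 1L], runif(ng) < recomb)
    newpool <- pool[r1, , drop = FALSE]
    newpool[pick] <- pool[r2, , drop = FALSE][pick]
    pool <- newpool
  }
  pool
}

forward_drift_pool <- function(init_freqs, sizes_list, n_dip, generations,
                               recomb = 0.5) {
  L <- length(init_freqs)
  pool <- sapply(seq_len(L), function(j)
    sample(sizes_list[[j]], 2L * n_dip, replace = TRUE, prob = init_freqs[[j]]))
  pool <- matrix(pool, nrow = 2L * n_dip)
  if (generations == 0L) return(pool)
  forward_drift_pool_from(pool, n_dip, generations, recomb)
}

#' Domesticated bottleneck strains derived from a source population
#'
#' Forward Wright-Fisher drift (free recombination) of a single founding
#' gamete pool for `generations`, after which `n_strains` strains split and
#' drift independently for a short `strain_generations`. This mirrors the
#' domestication story of farmed insect strains: a common captive origin with
#' routine exchanges between farms keeps strains genetically similar (low
#' between-strain LD variance) while the small census size inflates
#' cross-locus LD within every strain -- hence reduced allelic richness,
#' inflated within-strain LD, and a lower `D_ST/D_IS` ratio among strains
#' than among independently evolving wild demes.
#'
#' @param source_freqs per-locus allele frequency vectors of the source
#' @param sizes_list per-locus allele size vectors
#' @param loci list of [locus_def()] matching `sizes_list`
#' @param bottleneck_n diploid strain size during drift (>= 2)
#' @param generations generations of shared drift (0 = strains identical to
#'   source up to sampling)
#' @param n_strains number of strains
#' @param strain_generations independent drift per strain after the split
#'   (default 10)
#' @param recomb adjacent-locus recombination probability (default 0.2,
#'   emulating the partial physical linkage behind the long-range LD of
#'   domesticated strains; 0.5 = free recombination)
#' @param n_sample diploids sampled per strain
#' @param seed RNG seed
#' @return list with `gm` and `truth`
#' @export
make_domesticated_bottleneck <- function(source_freqs, sizes_list, loci,
                                         bottleneck_n = 50L, generations = 100L,
                                         n_strains = 4L, strain_generations = 10L,
                                         recomb = 0.2, n_sample = 20L, seed = 1L) {
  stopifnot(bottleneck_n >= 2L)
  set.seed(as.integer(seed))
  lf <- loci_frame(loci)
  L <- nrow(lf)
  shared <- forward_drift_pool(source_freqs, sizes_list, bottleneck_n,
                               generations, recomb)
  alle <- NULL; pops <- c()
  for (s in seq_len(n_strains)) {
    pool <- shared
    if (strain_generations > 0L)
      pool <- forward_drift_pool_from(pool, bottleneck_n, strain_generations, recomb)
    rows <- sample(nrow(pool), 2L * n_sample, replace = nrow(pool) < 2L * n_sample)
    g <- matrix(NA_real_, n_sample, 2L * L)
    for (j in seq_len(L)) {
      a <- pool[rows[seq(1, 2L * n_sample, 2)], j]
      b <- pool[rows[seq(2, 2L * n_sample, 2)], j]
      g[, 2L * j - 1L] <- pmin(a, b); g[, 2L * j] <- pmax(a, b)
    }
    alle <- rbind(alle, g)
    pops <- c(pops, rep(sprintf("strain%02d", s), n_sample))
  }
  gm <- genotype_matrix(alle, lf, factor(pops), validate = FALSE)
  list(gm = gm,
       truth = list(generator = "domesticated_bottleneck",
                    bottleneck_n = bottleneck_n, generations = generations,
                    n_strains = n_strains, seed = seed))
}

#' Configuration of the study-scale synthetic world
#'
#' Defaults mirror a global microsatellite survey sampling frame:
#' 150 populations of 5-50 diploids (mean ~19), 15 di/tri-nucleotide loci,
#' 16 genetic clusters of which 4 are bottlenecked "domesticated" captive
#' clusters sharing one origin, and an overall differentiation target of
#' FST ~ 0.24 split into between-cluster and between-population-within-
#' cluster layers.
#'
#' @param n_populations total populations (default 150)
#' @param n_loci loci (default 15)
#' @param n_clusters genetic clusters (default 16)
#' @param cluster_sizes populations per cluster (defaults to a realistic
#'   skewed allocation summing to `n_populations`)
#' @param fst_between_clusters,fst_within_cluster layered differentiation;
#'   the defaults (0.16, 0.04) are calibrated so that the realised overall
#'   Weir-Cockerham FST of the world, including the extra drift of the
#'   bottlenecked captive clusters, lands near the design target of 0.24
#' @param n_captive_clusters bottlenecked captive clusters (default 4)
#' @param n_alleles ancestral alleles per locus (default 14)
#' @param captive_pop_generations per-population drift generations on top of
#'   each captive cluster's shared strain pool (default 5)
#' @param captive_recomb adjacent-locus recombination probability inside
#'   captive strain pools (default 0.2: partial linkage builds the
#'   domestication LD signature; set 0.5 for free recombination when a
#'   linkage-equilibrium world is wanted)
#' @param ancestral_alpha symmetric Dirichlet shape of the ancestral allele
#'   frequency spectrum (default 0.45: skewed, as real microsatellite
#'   spectra are, which keeps rarefied richness near the emulated ~3 while
#'   allowing many low-frequency alleles)
#' @return list of class `synthetic_world_config`
#' @export
synthetic_world_config <- function(n_populations = 150L, n_loci = 15L,
                                   n_clusters = 16L, cluster_sizes = NULL,
                                   fst_between_clusters = 0.16,
                                   fst_within_cluster = 0.04,
                                   n_captive_clusters = 4L,
                                   n_alleles = 14L,
                                   captive_pop_generations = 5L,
                                   captive_recomb = 0.2,
                                   ancestral_alpha = 0.45) {
  if (is.null(cluster_sizes)) {
    base <- rep(n_populations %/% n_clusters, n_clusters)
    extra <- n_populations - sum(base)
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    # skew: first (captive) clusters larger, like real-world farmed strains
    cluster_sizes <- base
  }
  stopifnot(sum(cluster_sizes) == n_populations,
            length(cluster_sizes) == n_clusters)
  structure(list(n_populations = n_populations, n_loci = n_loci,
                 n_clusters = n_clusters, cluster_sizes = cluster_sizes,
                 fst_between_clusters = fst_between_clusters,
                 fst_within_cluster = fst_within_cluster,
                 n_captive_clusters = n_captive_clusters,
                 n_alleles = n_alleles,
                 captive_pop_generations = captive_pop_generations,
                 captive_recomb = captive_recomb,
                 ancestral_alpha = ancestral_alpha),
            class = "synthetic_world_config")
}

#' Study-scale synthetic world
#'
#' Hierarchical Dirichlet world: cluster frequency profiles drift from a
#' common ancestor (`fst_between_clusters`), population profiles drift from
#' their cluster (`fst_within_cluster`). The first `n_captive_clusters`
#' clusters are "domesticated": their frequency profiles derive from a
#' single shared captive origin with stronger drift and their populations
#' are sampled from bottlenecked gamete pools (building cross-locus LD and
#' reduced richness). Population sizes are 5-50 diploids with mean ~19.
#' Provenance and subcontinent labels are attached as metadata, and
#' population coordinates are generated so that wild clusters exhibit
#' isolation by distance.
#'
#' @param config [synthetic_world_config()]
#' @param seed RNG seed
#' @return list with `gm` and `truth` (cluster of every population, the
#'   frequency layers and all generating parameters)
#' @export
make_global_fixture <- function(config = synthetic_world_config(), seed = 1L) {
  set.seed(as.integer(seed))
  cfg <- config
  loci <- default_synth_loci(cfg$n_loci)
  lf <- loci_frame(loci)
  conc_ct <- (1 - cfg$fst_between_clusters) / cfg$fst_between_clusters
  conc_sc <- (1 - cfg$fst_within_cluster) / cfg$fst_within_cluster
  sizes_list <- lapply(seq_len(cfg$n_loci), function(j)
    synth_sizes(lf, j, cfg$n_alleles))
  anc <- lapply(seq_len(cfg$n_loci), function(j)
    as.numeric(rdirichlet(1, rep(cfg$ancestral_alpha %||% 0.45, cfg$n_alleles))))
  # cluster layer
  cl_freq <- vector("list", cfg$n_clusters)
  captive_origin <- lapply(anc, function(p0) as.numeric(rdirichlet(1, p0 * conc_ct)))
  for (k in seq_len(cfg$n_clusters)) {
    if (k <= cfg$n_captive_clusters) {
      # domesticated clusters: shared captive origin, extra drift
      cl_freq[[k]] <- lapply(captive_origin, function(p)
        as.numeric(rdirichlet(1, pmax(p, 1e-6) * 8)))
    } else {
      cl_freq[[k]] <- lapply(anc, function(p0)
        as.numeric(rdirichlet(1, p0 * conc_ct)))
    }
  }
  # populations
  n_pop_sizes <- pmin(50L, pmax(5L, 5L + rnbinom(cfg$n_populations, mu = 14, size = 6)))
  cluster_of <- rep(seq_len(cfg$n_clusters), cfg$cluster_sizes)
  subcont <- c("South America", "Central America", "North America", "Africa",
               "Asia", "Australia", "Europe")
  cl_centre <- cbind(lat = runif(cfg$n_clusters, -35, 55),
                     lon = runif(cfg$n_clusters, -150, 150))
  # captive clusters: one shared strain pool per cluster (farms exchange
  # stock), light per-population drift on top
  captive_pools <- lapply(seq_len(min(cfg$n_captive_clusters, cfg$n_clusters)),
                          function(k) forward_drift_pool(cl_freq[[k]], sizes_list,
                                                         n_dip = 60L,
                                                         generations = 25L,
                                                         recomb = cfg$captive_recomb %||% 0.2))
  alle <- NULL; pops <- c(); meta_rows <- list()
  for (p in seq_len(cfg$n_populations)) {
    k <- cluster_of[p]
    np <- n_pop_sizes[p]
    pname <- sprintf("pop%03d", p)
    captive <- k <= cfg$n_captive_clusters
    if (captive) {
      pool <- forward_drift_pool_from(captive_pools[[k]], n_dip = 60L,
                                      generations = cfg$captive_pop_generations %||% 5L,
                                      recomb = cfg$captive_recomb %||% 0.2)
      # sample gametes without replacement: drawing the same gamete twice
      # would fabricate sib/selfing structure no survey would contain
      rows <- sample(nrow(pool), 2L * np, replace = 2L * np > nrow(pool))
      g <- matrix(NA_real_, np, 2L * cfg$n_loci)
      for (j in seq_len(cfg$n_loci)) {
        a <- pool[rows[seq(1, 2L * np, 2)], j]; b <- pool[rows[seq(2, 2L * np, 2)], j]
        g[, 2L * j - 1L] <- pmin(a, b); g[, 2L * j] <- pmax(a, b)
      }
    } else {
      g <- matrix(NA_real_, np, 2L * cfg$n_loci)
      for (j in seq_len(cfg$n_loci)) {
        fp <- as.numeric(rdirichlet(1, pmax(cl_freq[[k]][[j]], 1e-9) * conc_sc))
        g[, c(2L * j - 1L, 2L * j)] <- draw_hwe_genotypes(np, sizes_list[[j]], fp)
      }
    }
    alle <- rbind(alle, g)
    pops <- c(pops, rep(pname, np))
    meta_rows[[p]] <- data.frame(
      population = pname,
      provenance = if (captive) "captive" else "wild",
      subcontinent = subcont[1 + (k - 1) %% length(subcont)],
      lat = min(89, max(-89, cl_centre[k, 1] + rnorm(1, 0, 4))),
      lon = min(179, max(-179, cl_centre[k, 2] + rnorm(1, 0, 4))),
      stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta_rows)
  gm <- genotype_matrix(alle, lf, factor(pops), metadata = meta, validate = FALSE)
  list(gm = gm,
       truth = list(generator = "global_fixture", config = cfg, seed = seed,
                    cluster_of_population = setNames(cluster_of, meta$population),
                    pop_sizes = n_pop_sizes))
}
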