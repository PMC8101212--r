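# R-level interface to the coalescent / GSM mutation engine.

#' Simulate a genealogy under a demographic scenario
#'
#' Continuous-time multi-population coalescent: within a population of
#' diploid size N, each pair of lineages coalesces at rate `1/(2N)` per
#' generation (total rate `k(k-1)/(4N)`); events move lineages between
#' populations pastwards. All samples are taken at time 0.
#'
#' @param scn a [scenario()]
#' @param draw optional [sample_priors()] draw resolving free parameters
#' @param seed RNG seed
#' @return list of class `genealogy`: `parent` (1-based, 0 for the root,
#'   which is the last node), `time` (generations), `leaf_pop`, `n_leaves`.
#' @export
simulate_genealogy <- function(scn, draw = NULL, seed = NULL) {
  rs <- resolve_scenario(scn, draw)
  if (sum(rs$samples) < 1L) stop("no samples declared")
  with_seed(seed, {
    g <- cpp_sim_genealogy(rs$samples, rs$N, rs$events)
    g$pop_names <- rs$pop_names
    class(g) <- "genealogy"
    g
  })
}

#' Generalised stepwise mutation on a genealogy
#'
#' Drops Poisson-distributed mutations on each branch. Step magnitudes are
#' geometric, `P(k) = (1 - P) P^(k-1)`, direction equiprobable; states are
#' reflected at the boundaries of the `n_states` contiguous repeat states.
#' Single-nucleotide indels occur at rate `mu_sni` and shift the allele
#' off the repeat lattice by +/-1 bp (offset capped at +/-2 bp), so allele
#' identity is (repeat count, offset). Fragment sizes in bp are
#' `size_min + repeat * motif_length + offset`, with the root placed at the
#' central repeat state.
#'
#' @param genealogy a [simulate_genealogy()] result
#' @param rate per-locus mutation rate per generation
#' @param P geometric step parameter in (0, 1); `P = 0` gives the strict
#'   stepwise model
#' @param mu_sni single-nucleotide indel rate
#' @param motif_length repeat motif length in bp
#' @param n_states number of repeat states (default 40)
#' @param size_min fragment size of repeat state 0 (default 100)
#' @param seed RNG seed
#' @return list with `sizes` (bp per sampled copy), `repeats`, `offsets`
#' @export
mutate_gsm <- function(genealogy, rate, P, mu_sni = 0, motif_length = 2L,
                       n_states = 40L, size_min = 100, seed = NULL) {
  with_seed(seed, {
    m <- cpp_mutate_gsm(genealogy$parent, genealogy$time, genealogy$n_leaves,
                        rate, P, mu_sni, n_states, n_states %/% 2L)
    list(sizes = size_min + m$repeats * motif_length + m$offsets,
         repeats = m$repeats, offsets = m$offsets,
         n_mutations = m$n_mutations, n_sni = m$n_sni)
  })
}

#' Default locus panel for simulations
#'
#' Di- and trinucleotide loci (alternating) whose size ranges span the
#' simulator's repeat lattice plus the +/-2 bp indel offsets.
#'
#' @param n_loci number of loci (default 15)
#' @param n_states repeat states per locus (default 40)
#' @param size_min fragment size of state 0 (default 100)
#' @return list of [locus_def()]
#' @export
sim_locus_panel <- function(n_loci = 15L, n_states = 40L, size_min = 100) {
  lapply(seq_len(n_loci), function(j) {
    motif <- if (j %% 2L == 1L) 2L else 3L
    locus_def(sprintf("L%02d", j), motif,
              c(size_min - 2, size_min + motif * (n_states - 1) + 2))
  })
}

#' Simulate a full microsatellite dataset under a scenario
#'
#' One genealogy and GSM mutation pass per locus; gene copies within each
#' population are paired into diploid individuals (exchangeable under random
#' mating).
#'
#' @param scn scenario
#' @param draw [sample_priors()] draw (or NULL for fully numeric scenarios,
#'   in which case mutation parameters must be supplied)
#' @param loci list of [locus_def()] (default [sim_locus_panel()] sized to
#'   the draw)
#' @param n_states repeat states (default 40)
#' @param seed RNG seed
#' @return genotype_matrix with populations named as in the scenario
#' @export
simulate_dataset <- function(scn, draw, loci = NULL, n_states = 40L, seed = NULL) {
  L <- length(draw$locus_rates)
  if (is.null(loci)) loci <- sim_locus_panel(L, n_states)
  lf <- loci_frame(loci)
  if (nrow(lf) != L) stop("loci and draw disagree on the locus count")
  rs <- resolve_scenario(scn, draw)
  with_seed(seed, {
    n_copies <- sum(rs$samples)
    n_ind <- n_copies %/% 2L
    pops <- rep(rs$pop_names, rs$samples %/% 2L)
    sim <- cpp_sim_dataset(rs$samples, rs$N, rs$events, draw$locus_rates,
                           draw$P, draw$mu_sni, n_states)
    sizes <- sweep(sim$repeats, 2L, lf$motif_length, "*") + sim$offsets
    sizes <- sweep(sizes, 2L, lf$size_min + 2, "+")
    odd <- seq(1L, n_copies, by = 2L)
    a <- sizes[odd, , drop = FALSE]; b <- sizes[odd + 1L, , drop = FALSE]
    alle <- matrix(NA_real_, n_ind, 2L * L)
    alle[, seq(1L, 2L * L, 2L)] <- pmin(a, b)
    alle[, seq(2L, 2L * L, 2L)] <- pmax(a, b)
    rownames(alle) <- paste0("ind_", seq_len(n_ind))
    new_genotype_matrix(alle, lf, factor(pops, levels = rs$pop_names))
  })
}
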