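# Shared fixture builders; everything is generated in code, no data files.

# two-column allele matrix -> genotype_matrix with uniform loci
tiny_gm <- function(allele_mat, pops, motif = 2L, range = c(90, 260),
                    meta = NULL) {
  L <- ncol(allele_mat) / 2L
  loci <- lapply(seq_len(L), function(j)
    locus_def(sprintf("T%02d", j), motif, range))
  genotype_matrix(allele_mat, loci, pops, metadata = meta)
}

# one-locus genotype matrix from explicit genotype pairs
one_locus_gm <- function(pairs, pops = rep("p1", nrow(pairs))) {
  tiny_gm(pairs, pops)
}

# random HWE population at one locus
random_pairs <- function(n, sizes = seq(100, 120, 2), prob = NULL) {
  a <- sample(sizes, n, TRUE, prob = prob)
  b <- sample(sizes, n, TRUE, prob = prob)
  cbind(pmin(a, b), pmax(a, b))
}

expect_symmetric <- function(m, tol = 1e-10) {
  expect_lt(max(abs(m - t(m))), tol)
}
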