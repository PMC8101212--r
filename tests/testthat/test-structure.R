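test_that("pairwise FST agrees with wc_fstats on each pair", {
  w <- make_island_world(3, 15, n_loci = 6, target_fst = 0.2, seed = 2)
  pf <- pairwise_fst_matrix(w$gm)
  expect_symmetric(pf$fst)
  expect_equal(unname(diag(pf$fst)), rep(0, 3))
  lv <- levels(w$gm$pop)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    sub <- w$gm[w$gm$pop %in% lv[pair]]
    expect_equal(pf$fst[pair[1], pair[2]],
                 unname(wc_fstats(sub)$overall["fst"]), tolerance = 1e-12)
  }
  # identical populations: raw estimate near zero (may be negative)
  set.seed(5)
  am <- do.call(cbind, replicate(6, random_pairs(80), simplify = FALSE))
  gm <- tiny_gm(am, rep(c("x", "y"), 40))
  pf2 <- pairwise_fst_matrix(gm, n_perm = 99, seed = 4)
  expect_lt(abs(pf2$fst[1, 2]), 0.03)
  expect_gt(pf2$p[1, 2], 0.05)
  expect_equal(linearised_fst(pf2)[1, 2],
               max(0, pf2$fst[1, 2]) / (1 - max(0, pf2$fst[1, 2])))
})

test_that("chord distance: identity, two-allele closed form, symmetry", {
  a <- rbind(matrix(rep(c(100, 100), 2), 2, byrow = TRUE),
             matrix(rep(c(102, 102), 2), 2, byrow = TRUE))
  gm <- one_locus_gm(a, c("A", "A", "B", "B"))
  d <- chord_distance_matrix(allele_frequencies(gm))
  expect_equal(d$values["A", "B"], 2 / pi * sqrt(2), tolerance = 1e-12)
  # identical frequency vectors -> 0
  gm2 <- one_locus_gm(rbind(c(100, 102), c(100, 102)), c("A", "B"))
  d2 <- chord_distance_matrix(allele_frequencies(gm2))
  expect_equal(d2$values["A", "B"], 0)
  expect_symmetric(d$values)
})

test_that("neighbour joining: closed forms and exact additive recovery", {
  # 3 taxa: closed-form branch lengths
  D <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  lens <- sort(tr$edges[, "length"])
  expect_equal(sort(c((5 + 9 - 8) / 2, (5 + 8 - 9) / 2, (9 + 8 - 5) / 2)),
               lens, tolerance = 1e-9)
  # additive 5-taxon distances from a random tree -> exact recovery
  skip_if_not_installed("ape")
  set.seed(8)
  for (i in 1:3) {
    tr0 <- ape::rtree(5 + i)
    D0 <- stats::cophenetic(tr0)
    nj <- neighbor_joining(D0)
    back <- stats::cophenetic(ape::read.tree(text = nj$newick))
    expect_lt(max(abs(D0 - back[rownames(D0), colnames(D0)])), 1e-8)
  }
  # matches ape's NJ topology on a noisy matrix
  Dn <- as.matrix(stats::dist(matrix(stats::rnorm(24), 8)))
  t_mine <- ape::read.tree(text = neighbor_joining(Dn)$newick)
  t_ape <- ape::nj(stats::as.dist(Dn))
  expect_equal(ape::dist.topo(ape::unroot(t_mine), ape::unroot(t_ape))[1], 0)
  # asymmetric input rejected
  Dbad <- Dn; Dbad[1, 2] <- Dbad[1, 2] + 1
  expect_error(neighbor_joining(Dbad), "symmetric")
})

test_that("AMOVA: panmictic limit, island-model theory, percentages sum to 100", {
  set.seed(12)
  # one panmictic population split arbitrarily -> within-individuals ~100%
  am <- cbind(random_pairs(80), random_pairs(80), random_pairs(80))
  gm <- tiny_gm(am, rep(c("a", "b", "c", "d"), 20))
  a0 <- amova(gm, "population", n_perm = 0)
  expect_gt(a0$percent["within_inds"], 90)
  expect_equal(sum(a0$percent), 100, tolerance = 1e-9)
  # island model: between-population percentage tracks FST
  w <- make_island_world(10, 20, n_loci = 10, target_fst = 0.15, seed = 13)
  a1 <- amova(w$gm, "population", n_perm = 0)
  fst <- unname(wc_fstats(w$gm)$overall["fst"])
  expect_equal(unname(a1$percent["between_pops"]) / 100, fst, tolerance = 0.02)
  # two-level hierarchy with real group structure
  wf <- make_global_fixture(synthetic_world_config(n_populations = 16,
                                                   n_clusters = 4,
                                                   n_captive_clusters = 1),
                            seed = 14)
  a2 <- amova(wf$gm, c("subcontinent", "population"), n_perm = 19, seed = 5)
  expect_equal(length(a2$components), 4L)
  expect_equal(sum(a2$percent), 100, tolerance = 1e-9)
  expect_true(all(is.finite(a2$phi)))
  # permutation p-values present for testable levels
  expect_true(all(!is.na(a2$p_values[c(1, 2, 3)])))
})

test_that("Mantel test: perfect correlation, enumeration oracle, invariance", {
  set.seed(15)
  coords <- data.frame(population = letters[1:6],
                       lat = runif(6, -40, 60), lon = runif(6, -150, 150))
  geo <- geo_distance_matrix(coords)
  gen <- log(geo)  # genetic distance == log geographic -> r = 1
  m <- mantel_ibd(gen, geo, n_perm = 499, seed = 1)
  expect_equal(m$r, 1, tolerance = 1e-12)
  # minimal p up to re-drawn identity permutations (which tie at r = 1)
  expect_lte(m$p_value, 0.02)
  # 4 populations: permutation p matches full enumeration of 24 relabellings
  g4 <- as.matrix(stats::dist(matrix(rnorm(8), 4)))
  h4 <- as.matrix(stats::dist(matrix(rnorm(8), 4)))
  low <- lower.tri(g4)
  r_obs <- cor(g4[low], h4[low])
  perms <- rbind(1:4)
  allp <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  allp <- allp[apply(allp, 1, function(x) length(unique(x)) == 4), ]
  r_all <- apply(allp, 1, function(pp) cor(g4[pp, pp][low], h4[low]))
  p_exact <- mean(r_all >= r_obs - 1e-12)
  m4 <- mantel_ibd(g4, h4, n_perm = 9999, seed = 2, log_geo = FALSE)
  expect_equal(m4$p_value, p_exact, tolerance = 0.02)
  # agreement with vegan on r
  skip_if_not_installed("vegan")
  vm <- vegan::mantel(g4, h4, permutations = 99)
  expect_equal(m4$r, unname(vm$statistic), tolerance = 1e-10)
  # coincident coordinates floored at 1 km before log
  coords2 <- coords; coords2[2, c("lat", "lon")] <- coords2[1, c("lat", "lon")]
  expect_equal(geo_distance_matrix(coords2)[1, 2], 1)
})

test_that("Mantel type-I error is near nominal on uncorrelated matrices", {
  set.seed(16)
  pv <- replicate(400, {
    g <- as.matrix(stats::dist(matrix(rnorm(12), 6)))
    h <- as.matrix(stats::dist(matrix(rnorm(12), 6)))
    mantel_ibd(g, h, n_perm = 199, log_geo = FALSE)$p_value
  })
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.03)
})
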