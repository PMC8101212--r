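test_that("EM clustering: fixed-difference limit and EM guarantees", {
  # two populations fixed for different alleles: crisp memberships and a
  # log-likelihood equal to the sum of per-genotype log frequencies
  a <- rbind(matrix(rep(c(100, 100), 10), 10, byrow = TRUE),
             matrix(rep(c(104, 104), 10), 10, byrow = TRUE))
  gm <- one_locus_gm(a, rep(c("A", "B"), each = 10))
  cm <- em_cluster(gm, 2, n_restarts = 3, seed = 1)
  expect_true(all(apply(cm$z, 1, max) > 0.999))
  expect_equal(adjusted_rand(cm$assignment, rep(1:2, each = 10)), 1)
  # logL: per-genotype log frequency is ~0 (homozygote at cluster freq ~1),
  # leaving only the mixing-proportion term: n * log(1/2)
  expect_equal(cm$logL, 20 * log(0.5), tolerance = 0.01)
  # logL trace is non-decreasing
  expect_true(all(diff(cm$trace) > -1e-6))
  # posteriors sum to one
  expect_equal(unname(rowSums(cm$z)), rep(1, 20), tolerance = 1e-9)
  # K = 1 works and has nu = sum(a_l - 1)
  c1 <- em_cluster(gm, 1, seed = 1)
  expect_equal(c1$nu, 1)  # one locus, two alleles
})

test_that("EM clustering recovers simulated island-model demes", {
  w <- make_island_world(3, 30, n_loci = 15, target_fst = 0.15, seed = 5)
  cm <- em_cluster(w$gm, 3, n_restarts = 5, seed = 1)
  tab <- table(cm$assignment, w$gm$pop)
  expect_gte(sum(apply(tab, 2, max)) / 90, 0.95)
})

test_that("select_k: trivial K*=1, recovery of K=4, penalty structure", {
  set.seed(6)
  # single panmictic population -> K* = 1
  am <- cbind(random_pairs(50), random_pairs(50), random_pairs(50),
              random_pairs(50), random_pairs(50))
  gm <- tiny_gm(am, rep("p", 50))
  sk1 <- select_k(gm, 1:3, seed = 2, n_restarts = 3)
  expect_equal(sk1$K_star, 1L)
  # simulated 4-cluster data: K* = 4 in >= 90% of seeded runs
  hits <- vapply(1:10, function(s) {
    w <- make_island_world(4, 25, n_loci = 15, target_fst = 0.2, seed = s)
    select_k(w$gm, 2:6, seed = s, n_restarts = 3)$K_star == 4L
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  # KIC penalty strictly increases with K at fixed logL
  w <- make_island_world(3, 20, n_loci = 10, target_fst = 0.2, seed = 3)
  fits <- lapply(1:4, function(K) em_cluster(w$gm, K, n_restarts = 2, seed = 1))
  pen <- vapply(fits, function(f) f$KIC + 2 * f$logL, 0)  # 3(nu+1)
  expect_true(all(diff(pen) > 0))
})

test_that("hybrid classification: parental identity and labelled-truth accuracy", {
  set.seed(7)
  hp <- make_hybrid_panel(0.3, n_pure = 60, n_f1 = 40, n_bc = 40,
                          n_alleles = 24, seed = 8)
  pa <- which(hp$truth$labels == "pure_A")
  pb <- which(hp$truth$labels == "pure_B")
  # a parental individual queried against its own pool -> pure posterior ~ 1
  hc_self <- hybrid_classify(hp$gm, pa[-1], pb, query = pa[1])
  expect_gt(hc_self$posterior[1, "pure_A"], 0.9)
  # posteriors sum to 1
  hc <- hybrid_classify(hp$gm, pa, pb)
  expect_equal(unname(rowSums(hc$posterior)), rep(1, nrow(hc$posterior)),
               tolerance = 1e-9)
  # accuracy on labelled truth
  truth <- hp$truth$labels[-c(pa, pb)]
  expect_gte(mean(as.character(hc$assignment) == truth), 0.85)
  # disjointness and size guards
  expect_error(hybrid_classify(hp$gm, pa, c(pb, pa[1])), "disjoint")
  expect_error(hybrid_classify(hp$gm, pa[1:3], pb), ">= 5")
})

test_that("DAPC separates groups and cross-validates n_pc", {
  # two fixed-difference groups (plus two variable loci so LDA has
  # within-group variance): one axis, perfect reassignment
  set.seed(77)
  a <- rbind(matrix(rep(c(100, 100), 12), 12, byrow = TRUE),
             matrix(rep(c(104, 104), 12), 12, byrow = TRUE))
  gm <- tiny_gm(cbind(a, random_pairs(24), random_pairs(24)),
                rep(c("A", "B"), each = 12))
  d <- dapc(gm, n_pc = 3, seed = 1)
  expect_equal(ncol(d$ind_coord), 1L)
  expect_equal(d$reassignment_success, 1)
  # cross-validated n_pc lands within 2% of the best grid point
  w <- make_island_world(3, 25, n_loci = 12, target_fst = 0.15, seed = 9)
  dv <- dapc(w$gm, seed = 2, n_rep = 5)
  best <- max(dv$cv$success, na.rm = TRUE)
  chosen <- dv$cv$success[dv$cv$n_pc == dv$n_pc]
  expect_gte(chosen, best - 0.02)
  # eigenvalues non-increasing
  expect_true(all(diff(dv$eigenvalues) <= 1e-9))
  expect_error(dapc(gm, n_pc = 50), "n_pc")
})

test_that("FCA: mirror symmetry, barycentres, CA oracle", {
  # mirror-image frequency profiles -> barycentres symmetric on axis 1
  set.seed(10)
  a <- rbind(matrix(rep(c(100, 100), 10), 10, byrow = TRUE),
             matrix(rep(c(104, 104), 10), 10, byrow = TRUE),
             matrix(rep(c(100, 104), 10), 10, byrow = TRUE))
  gm <- one_locus_gm(a, rep(c("A", "B", "C"), each = 10))
  f <- fca(gm, n_axes = 2)
  expect_equal(f$barycentres["A", 1], -f$barycentres["B", 1], tolerance = 1e-9)
  expect_lt(abs(f$barycentres["C", 1]), 1e-9)
  # barycentre = mean of member coordinates
  expect_equal(unname(f$barycentres["A", ]),
               unname(colMeans(f$ind_coord[gm$pop == "A", , drop = FALSE])))
  # oracle: correspondence analysis via vegan::cca on the dosage table
  skip_if_not_installed("vegan")
  w <- make_island_world(4, 10, n_loci = 5, target_fst = 0.25, seed = 11)
  fw <- fca(w$gm, n_axes = 3)
  X <- msatpop:::gm_index(w$gm)$dosage
  X <- X[, apply(X, 2, var) > 0]
  cc <- vegan::cca(X)
  ev <- cc$CA$eig / sum(cc$CA$eig)
  expect_equal(unname(fw$explained[1:3]), unname(ev[1:3]), tolerance = 1e-8)
  # individual coordinates match up to axis sign
  sc <- vegan::scores(cc, display = "sites", choices = 1:2, scaling = 1)
  for (ax in 1:2) {
    r <- abs(cor(fw$ind_coord[, ax], sc[, ax]))
    expect_gt(r, 0.999)
  }
})
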