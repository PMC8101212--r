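one_pop_scn <- function(N = 500, n = 10)
  scenario("one", data.frame(name = "A", N = N), samples = c(A = n))

test_that("prior sampling respects declared supports", {
  mm <- mutation_model()
  scn <- scenario("m", data.frame(name = "A", N = "N0"), samples = c(A = 5),
                  priors = list(N0 = c(100, 100)))   # degenerate prior
  d <- sample_priors(scn, mm, n_loci = 4, seed = 1)
  expect_equal(unname(d$values["N0"]), 100)
  set.seed(2)
  ds <- replicate(4000, {
    dd <- sample_priors(scn, mm, n_loci = 1)
    c(dd$mu_mean, dd$P, dd$mu_sni)
  })
  expect_true(all(ds[1, ] >= 1e-5 & ds[1, ] <= 1e-3))
  expect_true(all(ds[2, ] >= 0.1 & ds[2, ] <= 0.99))
  expect_true(all(ds[3, ] >= 1e-8 & ds[3, ] <= 1e-5))
  expect_equal(mean(ds[1, ]), (1e-5 + 1e-3) / 2, tolerance = 0.03)
  # undeclared parameter -> configuration error
  expect_error(scenario("bad", data.frame(name = "A", N = "Nx"),
                        samples = c(A = 5)), "prior")
  # per-locus rates reproducible under seed
  d1 <- sample_priors(scn, mm, n_loci = 6, seed = 9)
  d2 <- sample_priors(scn, mm, n_loci = 6, seed = 9)
  expect_identical(d1$locus_rates, d2$locus_rates)
})

test_that("scenario validation catches stranded lineages and bad events", {
  expect_error(scenario("s", data.frame(name = c("A", "B"), N = c(100, 100)),
                        samples = c(A = 2, B = 2)), "stranded")
  expect_error(scenario("s", data.frame(name = c("A", "B"), N = c(100, 100)),
                        samples = c(A = 2, B = 2),
                        events = list(ev_merge(50, "B", "A"),
                                      ev_merge(10, "A", "B"))), "time-ordered")
})

test_that("genealogies match coalescent expectations", {
  # one diploid (2 gene copies) in a population of size N: E[TMRCA] = 2N
  set.seed(3)
  tm <- replicate(4000, max(simulate_genealogy(one_pop_scn(400, 1))$time))
  expect_equal(mean(tm), 800, tolerance = 0.06)
  # sample of one gene copy... smallest valid: one diploid -> 2 copies
  g <- simulate_genealogy(one_pop_scn(100, 1), seed = 5)
  expect_equal(g$n_leaves, 2L)
  expect_equal(length(g$parent), 3L)
  expect_equal(g$parent[3], 0L)  # root has no parent
  # two populations merged at t = 0 behave like one population
  # 1 diploid in each of two pops merged at t = 0 behaves like one pop with
  # 2 diploids (4 gene copies): E[TMRCA] = 4N(1 - 1/4)
  scn2 <- scenario("two", data.frame(name = c("A", "B"), N = c(400, 400)),
                   samples = c(A = 1, B = 1),
                   events = list(ev_merge(0, "B", "A")))
  set.seed(6)
  tm2 <- replicate(4000, max(simulate_genealogy(scn2)$time))
  set.seed(7)
  tm2b <- replicate(4000, max(simulate_genealogy(one_pop_scn(400, 2))$time))
  expect_equal(mean(tm2), mean(tm2b), tolerance = 0.08)
  expect_equal(mean(tm2), 4 * 400 * (1 - 1 / 4), tolerance = 0.08)
})

test_that("GSM mutation model: limits, step law, lattice congruence", {
  g <- simulate_genealogy(one_pop_scn(1000, 10), seed = 7)
  # zero rates: all copies share the root allele
  m0 <- mutate_gsm(g, rate = 0, P = 0.5, mu_sni = 0, seed = 1)
  expect_equal(length(unique(m0$sizes)), 1L)
  # with mu_sni = 0, all alleles congruent to the root modulo motif length
  m1 <- mutate_gsm(g, rate = 0.01, P = 0.6, mu_sni = 0, motif_length = 3,
                   n_states = 40, seed = 2)
  expect_true(all(diff(sort(unique(m1$sizes))) %% 3 == 0))
  # geometric step magnitudes: mean 1/(1-P)
  set.seed(8)
  st <- msatpop:::cpp_gsm_steps(200000, 0.5)
  expect_equal(mean(st), 2, tolerance = 0.02)
  st2 <- msatpop:::cpp_gsm_steps(100000, 0.2)
  expect_equal(mean(st2), 1.25, tolerance = 0.02)
  # SNI offsets stay within +/-2 bp
  m2 <- mutate_gsm(g, rate = 0.01, P = 0.5, mu_sni = 0.01, seed = 3)
  expect_true(all(abs(m2$offsets) <= 2))
})

test_that("strict stepwise limit reproduces the closed-form homozygosity", {
  # P -> 0, theta = 4 N mu = 1: expected homozygosity 1/sqrt(1 + 2 theta)
  scn <- one_pop_scn(1000, 25)
  mu <- 1 / 4000
  set.seed(9)
  hom <- replicate(2500, {
    g <- simulate_genealogy(scn)
    m <- mutate_gsm(g, rate = mu, P = 1e-9, mu_sni = 0, n_states = 60)
    p <- tabulate(match(m$sizes, unique(m$sizes))) / length(m$sizes)
    sum(p^2)
  })
  # finite-sample inflation of sum(p^2) for n copies: E ~ F + (1-F)/n
  n_copies <- 50
  expected <- 1 / sqrt(3) + (1 - 1 / sqrt(3)) / n_copies
  expect_equal(mean(hom), expected, tolerance = 0.025)
})

test_that("simulated datasets are deterministic and well-formed", {
  mm <- mutation_model()
  scn <- scenario("two", data.frame(name = c("A", "B"), N = c(800, 800)),
                  samples = c(A = 10, B = 10),
                  events = list(ev_merge(1500, "B", "A")))
  d <- sample_priors(scn, mm, n_loci = 8, seed = 11)
  gm1 <- simulate_dataset(scn, d, seed = 12)
  gm2 <- simulate_dataset(scn, d, seed = 12)
  expect_identical(gm1$alleles, gm2$alleles)
  expect_equal(n_distinct <- nlevels(gm1$pop), 2L)
  expect_equal(nrow(gm1$alleles), 20L)
  expect_equal(n_loci <- nrow(gm1$loci), 8L)
  # allele sizes within declared locus ranges
  for (j in 1:8) {
    aa <- msatpop:::alleles_at(gm1, j)
    expect_true(all(aa >= gm1$loci$size_min[j] & aa <= gm1$loci$size_max[j]))
  }
  # larger N stochastically increases diversity
  set.seed(13)
  he_of <- function(N) {
    scnN <- scenario("one", data.frame(name = "A", N = N), samples = c(A = 20))
    mean(replicate(60, {
      dd <- sample_priors(scnN, mutation_model(mu_mean = c(5e-4, 5e-4)), n_loci = 5)
      d5 <- diversity_table(simulate_dataset(scnN, dd))
      mean(d5$he, na.rm = TRUE)
    }))
  }
  expect_gt(he_of(5000), he_of(200))
})
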