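# msatpop

Population genetics for diploid microsatellite surveys, end to end: from a
genotype table (individuals × loci, two fragment sizes per call) to
diversity statistics, F-statistics, Hardy–Weinberg and linkage tests,
population distances and trees, AMOVA, isolation by distance,
maximum-likelihood clustering with information-criterion model selection,
hybrid/backcross detection, LD-based effective population size, and
coalescent-simulation-based Approximate Bayesian Computation for comparing
demographic histories.

The package is built for the kind of global survey in which thousands of
individuals from ~150 wild and captive populations are genotyped at ~15
di/trinucleotide markers — think invasive-species biogeography or the
population structure of a farmed insect — and every analysis is exercised
by synthetic data generators with known truth, so the whole pipeline is
testable without any external dataset.

## The models in brief

* **F-statistics** are Weir–Cockerham (1984) variance components combined
  by ratio-of-sums over alleles and loci; `F_IT = F_ST + (1−F_ST) F_IS`
  holds exactly by construction.
* **H_E** uses Nei's unbiased correction; **allelic richness** is the
  hypergeometric rarefaction `A_R = Σ_a [1 − C(N−N_a, g)/C(N, g)]`.
* **HWE** is a Monte-Carlo exact test on genotype-array probabilities
  conditional on allele counts; **LD** within populations is an EM
  likelihood-ratio test on unphased two-locus genotypes with permutation
  significance; **Ohta's D-statistics** decompose squared LD into within-
  and between-population components from Burrows composite gamete
  frequencies, with `D²_IT = D'²_IS + D'²_ST` exact.
* **Ne** follows the LD method: mean Burrows `r²` across allele pairs,
  sampling expectation `1/S + 3.19/S²` subtracted, lifetime-monogamy or
  random-mating quadratic applied.
* **Clustering** is an EM mixture of Hardy–Weinberg genotype likelihoods
  (snapclust-style), selected by KIC `= −2 logL + 3(ν+1)` with
  `ν = (K−1) + K Σ_l (a_l − 1)`; **hybrid classes** (pure/F1/backcross)
  use HWE likelihoods at mixed parental frequencies.
* **The simulator** is a multi-population continuous-time coalescent
  (merges, admixtures, size changes) with a generalised stepwise mutation
  model: geometric step sizes with parameter `P`, reflecting boundaries on
  40 repeat states, and ±1 bp single-nucleotide indels; priors
  `μ ~ U(1e-5, 1e-3)`, `P ~ U(0.1, 0.99)`, `μ_SNI ~ U(1e-8, 1e-5)`.
* **ABC model choice** retains the closest 1% of simulations, reduces
  logit-transformed statistics by LDA, and fits an Epanechnikov-weighted
  multinomial logistic regression at the observed point; parameter
  posteriors use Beaumont's local-linear adjustment on logit-mapped
  parameters.

See `vignettes/msatpop-methods.Rmd` for assumptions, defaults and design
choices.

## Worked example

```r
library(msatpop)

# a labelled synthetic world: 16 clusters, 150 populations, 15 loci,
# overall FST targeted at 0.24, four bottlenecked "captive" clusters
w  <- make_global_fixture(seed = 1)
gm <- w$gm

dataset_summary(gm)
#> 2936 individuals (2936 unique MLGs) | 150 populations | 15 loci
#> mean population size 19.6 (range 6-43); missing rate 0.000

wc_fstats(gm)
#> Weir-Cockerham overall: FST = 0.2356  FIS = 0.0012  FIT = 0.2366

mean(rarefied_allelic_richness(gm, g = 10)$mean_ar)
#> [1] 3.318227

ne_ld(gm, "pop002")   # LD effective size of one (captive) population
#> Ne(LD, monogamy) for pop002: 35.6  [26.3, 49.9]  (r2=0.05055, S=33.0, 776 comparisons)
```

Every number above is produced by the code shown (seed 1). The summary says
all individuals carry unique multilocus genotypes — the expected regime for
15 polymorphic microsatellites; the overall FST sits at the world's design
target of 0.24; richness rarefied to five diploids lands in the survey-like
~3 range; and the captive population returns a bounded Ne in the tens, as
bottlenecked farmed strains do.

For the full pipeline (diversity tables, HWE/LD scans, chord-distance NJ
tree, pairwise FST, AMOVA, IBD, clustering, Ne — all written as CSV/JSON/
Newick artefacts with a manifest):

```r
cfg <- run_config("out_dir", seed = 1)   # study-standard permutation counts
bundle <- run_full_report(gm, cfg)
```

A thin command-line front-end with `simulate` and `report` subcommands is
in `inst/scripts/msatpop-cli.R`.

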