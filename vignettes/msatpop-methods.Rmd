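---
title: "Models and methods behind msatpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind msatpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`msatpop` implements a complete population-genetics workflow for diploid
microsatellite data — the kind of global survey in which a few thousand
individuals from ~150 wild and captive populations are genotyped at ~15
di/trinucleotide markers — together with a coalescent simulator and
Approximate Bayesian Computation (ABC) machinery for comparing demographic
histories. This vignette explains the models, the defaults, and the design
choices that were genuinely open, in the order a user meets them.

## Data model

A `genotype_matrix` stores, per individual and locus, an unordered pair of
allele fragment sizes in bp (the representation produced by fragment-length
scoring against an internal size standard), `NA` for a missing call.
Alleles are canonicalised in ascending order and genotypes are treated as
unphased everywhere: any statistic that needs two-locus information uses
phase-free (composite or EM) estimators. Individuals with missing calls at
some loci are retained; every statistic works from per-locus gene counts.
A locus definition fixes the repeat-motif length, the admissible size range
(validation rejects out-of-range alleles), and the missing-data sentinel.
Population metadata (wild/captive provenance, subcontinent, optional
coordinates) ride along with the matrix.

## Diversity and F-statistics

Expected heterozygosity uses Nei's unbiased correction
$H_E = \frac{n_g}{n_g-1}\,(1-\sum_a p_a^2)$ with $n_g$ the cell's gene
count. Rarefied allelic richness is the hypergeometric expectation
$A_R = \sum_a \left[1 - \binom{N-N_a}{g}\big/\binom{N}{g}\right]$, by
default at $g = 10$ gene copies (five diploids, the smallest sample size of
the emulated survey); $A_R$ is non-decreasing in $g$ and equals the allele
count at the full sample. F-statistics are Weir & Cockerham (1984) variance
components $a, b, c$ computed per allele, combined by ratio-of-sums across
alleles and loci — the convention of `hierfstat` and most modern software —
never by averaging per-locus ratios. The identity
$F_{IT} = F_{ST} + (1-F_{ST})F_{IS}$ holds exactly when all three are
formed from the same component sums, and the test suite asserts it.

Hardy–Weinberg testing is a Monte-Carlo exact test: the observed gene
copies of a cell are repeatedly shuffled into random diploid pairings and
the conditional probability of each shuffled genotype array (given allele
counts) is compared with the observed one; `p = (#{P(shuffle) <= P(obs)} +
1)/(n_perm + 1)`, so p is never zero and the observed array counts once on
both sides. Monomorphic cells return p = 1 by convention. Significance
summaries apply a Bonferroni correction *within* each population across its
locus tests, not across the whole dataset — matching how such surveys
usually adjust ("too conservative otherwise"), and deliberately not
adjusting at the dataset level.

Null alleles follow Brookfield: estimator 1 is
$\hat r_1 = (H_E - H_O)/(1 + H_E)$; estimator 2 treats observed
non-amplifying individuals (both alleles missing) as putative null
homozygotes, $\hat r_2 = (H_E - H_O + 2b)/(1 + H_E + 2b)$ with $b$ the
blank fraction. With zero recorded blanks the two coincide — the situation
in datasets with no null homozygotes, which is why estimator 1's closed
form governs the reproducible outputs. Raw (possibly negative) and
zero-truncated values are both reported; significance comes from a
bootstrap over individuals (95% CI excluding zero).

## Linkage disequilibrium, Ohta components, effective size

Three different LD questions get three different estimators, mirroring the
division of labour among the classic tools:

* **Within-population LD test** (Arlequin-style): EM estimates of two-locus
  haplotype frequencies from unphased genotypes; the statistic is the
  likelihood ratio $2(\ln L_{\text{full}} - \ln L_{\text{equilibrium}})$,
  with significance from permuting one locus's genotypes across individuals
  (1000 permutations by default). The permutation scheme preserves both
  single-locus genotype arrays, so the test is exact at its resolution; the
  suite verifies nominal type-I error within ±2% over 500 null replicates.
* **Ohta's variance decomposition** (GENETIX-style): composite Burrows
  gamete frequencies $g_{ijk}$ per population feed the five components
  $D^2_{IS}, D^2_{ST}, D'^2_{IS}, D'^2_{ST}, D^2_{IT}$, using unweighted
  averages across populations so the identity
  $D^2_{IT} = D'^2_{IS} + D'^2_{ST}$ holds to machine precision. The
  reported between/within ratio is $D'^2_{ST}/D^2_{IS}$ — Ohta's own
  drift-vs-selection diagnostic. We also emit the fully unprimed ratio, but
  it is not the default: in simulations the unprimed $D^2_{ST}$ is
  dominated by allele-frequency differentiation and *rises* for
  low-diversity bottlenecked strains, whereas the primed-between/unprimed-
  within pair reproduces the expected domestication signature (shared-origin
  strains with strong within-strain LD sit clearly below independent wild
  demes).
* **Effective population size** (NeEstimator-style): Burrows
  $\hat\Delta$ per allele pair converted to
  $r^2 = \hat\Delta^2/(p(1-p)q(1-q))$, averaged over all comparisons; the
  sampling expectation $1/S + 3.19/S^2$ (harmonic-mean $S \ge 30$;
  $1/S + 0.69/S^2$ below) is subtracted and the lifetime-monogamy
  quadratic $N_e = (2/3 + \sqrt{4/9 - 7.2\,r^2_\Delta})/(2 r^2_\Delta)$
  (or its random-mating analogue) applied. Non-positive drift components
  give $N_e = \infty$; the parametric CI treats
  $n\,\bar r^2 / r^2$ as $\chi^2_n$. The default allele-exclusion rule
  drops within-population singletons (the conservative choice of the
  emulated study); the recovery simulations use the standard 5%
  minor-allele screen instead, because at $S = 50$ the remaining rare
  alleles bias $r^2$ downward and inflate $N_e$ by ~18% — an estimator
  property worth knowing when interpreting either setting.

## Structure: distances, trees, AMOVA, IBD, ordinations

Cavalli-Sforza & Edwards chord distances use
$D_{CH} = \frac{2}{\pi L}\sum_l \sqrt{2(1-\sum_a \sqrt{p_{al} q_{al}})}$
over loci typed in both populations. Neighbour-joining is Saitou–Nei with
the Studier–Keppler criterion; negative branch lengths are clamped to zero
for display while raw values are kept, and on additive input the tree
metric is exact (asserted against an independent implementation).

AMOVA decomposes 0/1 allele-mismatch distances between gene copies through
an exact unbalanced nested ANOVA: within-cluster sums of squares come from
allele counts via $\mathrm{SSD}(u) = [\binom{m}{2} - \sum_a
\binom{m_a}{2}]/m$, expected-mean-square coefficients from the general
nested-design formula $c_{l,j} = \sum_u \sum_v m_{u\cap v}^2/m_u$, and the
component system is solved per dataset with loci pooled. Negative
components are reported, never zeroed. With a one-level hierarchy the
between-population percentage equals Weir–Cockerham $F_{ST}\times 100$
exactly in our tests. Permutation schemes per level: copies among
individuals within populations; individuals among populations (within
groups); populations among groups — 99 permutations by default.

Isolation by distance is a Mantel test (9999 permutations) between
$F_{ST}/(1-F_{ST})$ (pairwise values truncated at zero first) and
log great-circle km; geographic distances get a 1 km floor so coincident
sites survive the log. DAPC centres the mean-imputed 0/1/2 allele dosage
matrix, reduces by PCA, and chooses the retained components by stratified
90/10 cross-validation before LDA. FCA is classic correspondence analysis
(SVD of standardised residuals) of the same dosage table, with population
barycentres as member means.

## Mixture clustering and hybrid classes

`em_cluster()` fits the snapclust-style model: each cluster has its own
allele frequencies and genotypes follow HWE within clusters; EM alternates
membership posteriors with posterior-weighted frequency updates. The first
start is k-means on leading PCs of the dosage matrix, the rest are random;
empty clusters trigger reseeding. The parameter count is
$\nu = (K-1) + K\sum_l (a_l - 1)$ and model selection uses Cavanaugh's
KIC $= -2\ln L + 3(\nu+1)$ (AIC/BIC also available), ties broken toward
smaller K, non-converged fits excluded from the argmin.

Hybrid classification models five ancestry classes
($\alpha \in \{1, 0.75, 0.5, 0.25, 0\}$) with expected frequencies
$f_c = \alpha f_A + (1-\alpha) f_B$ and HWE genotype likelihoods at $f_c$
— the same first-generation approximation the snapclust hybrid machinery
uses; it is deliberately misspecified for backcrosses (whose genotypes are
not a random union of gametes at $f_c$), which is the main accuracy
limiter. Parental frequencies come from declared reference individuals
with a 0.5 pseudo-count; joint re-estimation is available but off by
default because mostly-hybrid query sets erode the pools. With
marker-panel-like richness (~24 alleles/locus) and parental references of
~100 individuals, classification exceeds 90% at parental $F_{ST} = 0.3$;
with a 12-allele panel the information ceiling is ~86%, almost entirely
F1-vs-backcross confusion.

## Coalescent simulator and ABC

The simulator is a continuous-time multi-population coalescent (pairwise
rate $k(k-1)/(4N)$ per generation) with time-ordered events: merges,
two-source admixtures (each lineage picks a source by the admixture rate),
and size changes. It approximates the generation-based engines of ABC
packages; differences are $O(1/N)$. Mutation is a generalised stepwise
model: Poisson mutations per branch, geometric step magnitudes
$P(k) = (1-P)P^{k-1}$ with equiprobable sign, reflection at the bounds of
40 contiguous repeat states (a standard engine default, configurable), and
single-nucleotide indels at rate $\mu_{SNI}$ that shift alleles off the
repeat lattice by ±1 bp (offset capped at ±2), so allele identity is
(repeat count, offset). Priors follow the emulated analysis: per-locus
mean rate $\mu \sim U(10^{-5}, 10^{-3})$ with Gamma(shape 2) per-locus
heterogeneity, $P \sim U(0.1, 0.99)$, $\mu_{SNI} \sim U(10^{-8},
10^{-5})$. The engine is written in C++ on R's RNG: a 15-locus two-deme
dataset simulates in ~4 ms and a fixed seed reproduces everything,
including the per-locus rate draws. The strict-stepwise limit
($P \to 0$) matches the closed-form homozygosity
$F = 1/\sqrt{1+2\theta}$ in the suite, with the finite-sample correction
$F + (1-F)/n$ for the $n$ sampled copies.

ABC summary statistics are the classic microsatellite panel: per group,
mean allele number, mean unbiased diversity, mean allele-size variance;
per pair, the pooled versions plus shared-allele distance, the mean
classification index in both directions (log-likelihood of one group's
genotypes under the other's add-one-smoothed frequencies), Weir–Cockerham
$F_{ST}$, and Goldstein's $(\delta\mu)^2$. Model choice retains the 1%
closest simulations (standardised Euclidean distance), logit-transforms
the retained statistics via pooled min/max range-mapping, reduces by LDA
on the model label, and fits a weighted multinomial logistic regression
(Epanechnikov weights, analytic-gradient BFGS — implemented here because
no multinomial fitter is guaranteed in the environment) evaluated at the
observed point; 95% CIs come from the delta method on the fit's Hessian
and the "significant best model" flag requires non-overlap of the top two
CIs. A rejection-only posterior is reported alongside as a cross-check.
Parameter posteriors use Beaumont's local-linear adjustment on
logit-mapped parameters, which confines adjusted draws to the prior
support by construction. The reference-table default in examples is
10,000 simulations per model — a desk-scale stand-in for the canonical
million, marked as such wherever it appears.

## The synthetic worlds, and what a green test does not establish

Two generator families emit the same `genotype_matrix`:

* **Dirichlet-drift worlds** for the statistics and clustering tests.
  `make_island_world()` draws deme frequencies from
  $\mathrm{Dir}(p_0 (1-F)/F)$ around a flat-Dirichlet ancestor, giving
  $E[F_{ST}] \approx F$; `make_global_fixture()` layers this into 16
  clusters over 150 populations of 5–50 diploids (mean ≈ 19), with the
  first four clusters "domesticated": derived from one shared captive
  origin, with one drifting strain gamete pool per cluster (farms exchange
  stock) sampled without replacement into populations, and partial linkage
  (adjacent-locus recombination 0.2) that produces the expected reduced
  richness, within-strain LD and low $D'^2_{ST}/D^2_{IS}$. The two layer
  intensities (0.16 between clusters, 0.04 within, over a skewed
  Dirichlet(0.45) ancestral spectrum) were calibrated once so
  the realised overall $F_{ST}$ of the full world sits at the design
  target 0.24; they are not free dials. On this layered world KIC's argmin
  recovers the design K to within one grid step (±2 around 16) with
  population-level adjusted Rand ≥ 0.83: the Dirichlet cluster layer can
  leave two clusters close enough to merge or a population deviant enough
  to split, so exact-K recovery is only asserted on cleanly separated
  worlds.
* **Coalescent-backed worlds** for the ABC tests, with known generating
  scenarios and parameters.

These worlds state their assumptions openly: HWE within populations (no
inbreeding, so $F_{IS} \approx 0$ by construction), no genotyping error,
no allelic dropout or stutter, missingness only if injected, and island
rather than stepping-stone migration. A green suite therefore establishes
estimator correctness on data satisfying the model assumptions — not
robustness to the artefacts of real fragment scoring, which the emulated
study handled upstream of the statistics.

## Numerical choices

Permutation p-values always use the +1 correction. EM (clustering,
haplotypes, hybrids) stops on log-likelihood increments below $10^{-6}$
(clustering) or $10^{-7}$ (haplotypes); cluster frequencies carry a
$10^{-9}$ floor so support never vanishes mid-run. The likelihood-ratio
statistic is clamped at zero against EM convergence noise. KIC ties break
toward smaller K. Distance matrices must be symmetric to $10^{-8}$.
Chi-square CIs for $N_e$ use the comparison count as degrees of freedom —
optimistic when loci are physically linked, as the emulated study's seven
high-LD pairs illustrate.

## Known limitations

No recombination within loci, no selection, no temporal sampling in the
simulator; no Chakraborty or EM null-allele estimators; no Bayesian MCMC
clustering; the GenePop writer targets round-trip fidelity (population
labels and >999 bp offsets ride in the title line) rather than archival
conventions; AMOVA supports one or two grouping levels above populations,
which covers the emulated study's designs.
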