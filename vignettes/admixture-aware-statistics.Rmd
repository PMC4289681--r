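---
title: "Admixture-aware population-genetic statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture-aware population-genetic statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixstats)
```

Recently admixed populations break the assumptions behind most standard
population-genetic estimators: allele frequencies are mixtures, linkage
disequilibrium (LD) is created and destroyed by gene flow, and departures
from Hardy–Weinberg genotype proportions reflect population structure as
much as inbreeding. This package collects a set of estimators that make the
admixture explicit — taking per-individual ancestry proportions as known
inputs (as produced by model-based clustering software such as ADMIXTURE)
— together with a synthetic-cohort generator that reproduces the exact
generative assumptions of each estimator. The motivating setting is a
two-ancestry cohort (an indigenous component plus a European donor
component), but everything generalizes to K ancestries where stated.

## The admixture-proportion mixture and corrected allele frequencies

Ancestry proportions $\alpha_i \in [0,1]$ in a recently admixed cohort
typically show atoms at exactly 0 (unadmixed individuals) and 1 (recent
migrants) plus a continuous interior. `fit_admixture_distribution()` fits
the mixture

$$\alpha \sim p_0\,\delta_0 + (1 - p_0 - p_1)\,\mathrm{Beta}(a, b) + p_1\,\delta_1.$$

The atoms are assigned empirically with a boundary threshold
`eps = 1e-3` — ancestry software emits near-zero values rather than exact
zeros, so a hard equality test would miss the atom; the threshold is small
enough that genuinely admixed individuals (who carry percent-scale
proportions) are never captured. The beta shapes are maximum-likelihood
estimates on the interior points (via `MASS::fitdistr` from a
moment-matching start). A fitted model is sanity-checked by comparing its
implied mean against the empirical mean of the proportions; on simulated
cohorts of 2,000 the two agree to better than 0.01.

`discretize_distribution()` summarizes the fitted distribution as $B = 10$
equal-width bins with probability-weighted representative values
$\alpha_b$. Ten equal-width bins are a convention chosen for ease of
calculation; the representative value of a bin is the probability-weighted
mean of its content (computed in closed form from incomplete beta
integrals), with the boundary atoms folded into the first and last bin.
Equal-mass binning would serve equally well; the choice is isolated in
this one function.

Under the mixture model the observed cohort frequency decomposes as
$f_G = \bar\alpha f_D + (1-\bar\alpha) f'_G$, where $f_D$ is the donor
(European) reference frequency and $f'_G$ the frequency in the unadmixed
component. `corrected_allele_frequency()` inverts this through the bins as
a ratio of sums,

$$f'_G \;=\; \frac{\sum_b \Pr(\alpha_b)\,(f_G - \alpha_b f_D)}
                 {\sum_b \Pr(\alpha_b)\,(1 - \alpha_b)},$$

a grouping chosen deliberately: averaging the per-bin inversions
$(f_G - \alpha_b f_D)/(1-\alpha_b)$ instead is *not* unbiased — writing
$f_G = \bar\alpha f_D + (1-\bar\alpha) f_I$ and taking the expectation over
bins leaves a residual $(f_D - f_I)\,E[(\bar\alpha-\alpha)/(1-\alpha)]$,
which for a cohort that is half unadmixed with Beta(2,2) admixture in the
rest and $f_D = 0.1$, $f_I = 0.4$ amounts to a bias of $+0.15$. The
ratio-of-sums form is exactly unbiased when the decomposition holds, and
the recovery tests confirm a mean absolute error below 0.02 at $n = 2{,}000$
individuals. Bins with $\alpha_b = 1$ describe individuals carrying no
information about $f'_G$ and are excluded (their weight cancels in the
ratio). Noisy inputs can push the raw value outside $[0,1]$; it is clamped
and flagged per site.

## Ancestry-specific haplotype frequencies and LD by EM

For a pair of tightly linked SNPs, the four haplotypes AB, Ab, aB, ab have
unknown frequencies $p_{jk}$ in each ancestral population $k$. Unphased
genotypes of admixed individuals are modeled by summing over (i) the
haplotype pairs consistent with each two-SNP genotype and (ii) the latent
ancestry of each of the two haplotypes, assumed independent given the
admixture proportions and constant across the two loci of a haplotype:

$$L(p) = \prod_i \sum_{h \in h(G_i)} \sum_{k_1} \sum_{k_2}
         p_{h_1 k_1}\, p_{h_2 k_2}\, \alpha_{i k_1}\, \alpha_{i k_2}.$$

`estimate_pair_haplotype_frequencies()` maximizes this by EM. The M-step
is the standard ratio of expected counts,
$p^{*}_{jk} = E[\#\{\text{haplotypes } j \text{ of ancestry } k\}] /
E[\#\{\text{haplotypes of ancestry } k\}]$, which keeps every ancestry
column on the simplex and provably increases the likelihood; monotonicity
is property-tested on hundreds of random datasets. (A per-individual
normalization with a $1/(2n)$ factor would leave the columns summing to
$1/2$ and cannot be a valid update for this likelihood.) Haplotype pairs
are enumerated as ordered pairs — double heterozygotes contribute both
phase configurations — so reported log-likelihoods are comparable only
between implementations using the same enumeration; the test-suite oracle
does.

Numerical choices: convergence is declared when no parameter moves by more
than `tol = 1e-6`; five uniform-random restarts guard against local
optima, with ties broken by likelihood and then by start order
(deterministic under a fixed seed); ancestries whose total admixture
weight among retained individuals is at most 0.5 — less than half an
expected haplotype of data — are flagged unresolved rather than reported
as noise. Individuals missing either genotype are dropped for that pair.

Per-ancestry LD follows from the fitted columns:
$D = p_{AB} - p_A p_B$ and $r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$, undefined
(flagged `NA`) when a locus is monomorphic within an ancestry.
`ld_decay_curve()` assembles distance-binned naive (dosage-correlation)
and per-ancestry curves. When a high-LD ancestry mixes with a low-LD one,
the naive curve falls strictly between the two ancestral curves — gene
flow into a population with perfect LD always dilutes it — and the EM
curves recover the bracket on simulated cohorts.

## Admixture-aware inbreeding

For one individual with ancestry proportions $\alpha$ and per-ancestry
site frequencies $f_{sk}$, the relevant allele frequency is
$f^*_s = \sum_k \alpha_k f_{sk}$, and the genotype likelihood under
inbreeding coefficient $F$ is the identity-by-descent mixture
$\Pr(g_s \mid F)$: $(1-f^*)^2(1-F) + (1-f^*)F$, $2f^*(1-f^*)(1-F)$,
$f^{*2}(1-F) + f^*F$ for $g_s = 0, 1, 2$. `estimate_inbreeding()`
maximizes the composite log-likelihood over sites on $F \in [0,1]$ — a
101-point grid followed by golden-section refinement between the best
point's neighbours, verified against a 10,001-point brute-force grid.
$F$ is constrained to $[0,1]$ because the mixture interpretation (and
non-negativity of the probabilities) requires it. Near-monomorphic sites
($f^*$ within `f_eps = 0.005` of a boundary) are dropped to keep logs
finite. Sites are treated as independent; LD between sites makes the
composite likelihood overconfident but leaves the point estimate
essentially unbiased, which is what the recovery tests measure. Using
pooled cohort frequencies instead of $f^*$ inflates $\hat F$ on admixed
data (the Wahlund effect masquerading as inbreeding); the test suite
reproduces this contrast qualitatively.

## D statistics, the weighted block jackknife, and FST

For populations arranged as (((H1, H2), H3), H4) with H4 the outgroup,

$$D = \frac{\sum_i (f_{iH3}-f_{iH4})(f_{iH1}-f_{iH2})}
           {\sum_i (f_{iH3}+f_{iH4}-2f_{iH3}f_{iH4})
                   (f_{iH1}+f_{iH2}-2f_{iH1}f_{iH2})}.$$

Only sites with a non-missing frequency in all four populations enter;
zero-denominator sites (all four populations monomorphic) are dropped from
both sums and from the site count. The frequency form is free of allele
polarization, and swapping H1/H2 or H3/H4 flips the sign exactly — both
properties are tested.

Standard errors come from a delete-$m$ jackknife for unequal $m$ over
contiguous 5 Mb windows anchored at each chromosome's first site (the
anchoring is a convention; empty windows are skipped). With block sizes
$m_j$, $n = \sum_j m_j$ and $h_j = n/m_j$, the pseudo-values are
$\tau_j = h_j\hat\theta - (h_j-1)\hat\theta_{(-j)}$ and the variance is
$\frac{1}{g}\sum_j (\tau_j - \hat\theta_J)^2/(h_j - 1)$ with
$\hat\theta_J = g\hat\theta - \sum_j (1 - m_j/n)\hat\theta_{(-j)}$. The
formula variant is pinned by tests: with equal blocks it agrees with an
independent unweighted delete-$m$ implementation to $10^{-12}$, and with
one site per block it is the classic delete-1 jackknife. Under a
symmetric four-population null the empirical rate of $|Z| \ge 3$ stays
within its nominal bound.

Between-population differentiation uses the Weir–Cockerham (1984)
variance-components estimator for two populations,
$F_{ST} = \sum_s a_s / \sum_s (a_s + b_s + c_s)$, computed from sample
sizes, allele frequencies and observed heterozygosity; sites monomorphic
in the pooled sample are excluded, and an entirely monomorphic input is
flagged undefined rather than returned as 0/0.

## The ancestry-tract Markov model

Along a haplotype of an admixed genome, ancestry is approximated by a
two-state Markov chain over base pairs with transition rates
$\lambda_1 = (1-m)r(t-1)$ (admixed $\to$ unadmixed) and
$\lambda_2 = m r (t-1)$ (unadmixed $\to$ admixed), where $m$ is the
admixture proportion, $r$ the per-bp recombination rate and $t > 1$ the
admixture time in generations. A site initiates an admixed run of at least
$k$ sites with probability $R = \pi_2 \lambda_2 (1-\lambda_1)^{k-1}$,
$\pi_2 = 1-m$, and for small $R$ the probability of no such run in a
genome of $S$ sites is $e^{-RS}$. Thresholds in cM convert to sites by
$k = (L/100)/r$ — at $r = 1.3\times10^{-8}$, 39 cM is $3\times10^7$
sites — and the power is evaluated in log space to avoid underflow at
genome scale. At $m = 0.05$, $t = 25$, $S = 2.7$ Gb this gives 0.9945 for
"no tract of 39 cM or longer", i.e. about 0.005 for seeing at least one;
such a tract in an admixed individual is therefore strong evidence of much
more recent gene flow.

One subtlety: the no-tract probability is *not* monotone in $t$.
$R \propto (t-1) e^{-(1-m)rk(t-1)}$ rises with $t$ only while
$(t-1) < 1/((1-m)rk)$; past that point older admixture means shorter
tracts and the no-long-tract probability increases again. At the 39 cM
threshold the turning point is near $t \approx 3.7$. The property tests
therefore assert monotonicity in $S$, in the threshold length, and in $m$
(for $m \le 0.5$) everywhere, but in $t$ only on the regime where the
model implies it.

`bin_tract_lengths()` summarizes tract sets in 5 cM bins, and
`match_by_ancestry()` matches individuals across two cohorts by ancestry
proportion before tract distributions are compared, so that differences in
population-level admixture do not masquerade as differences in tract
lengths. Matching is exact minimum-cost assignment: for a one-dimensional
cost the optimum preserves sorted order, so a small dynamic program over
the two sorted lists finds it; tests confirm equality with an exhaustive
assignment search. The package works throughout with a uniform
recombination rate per bp — cM lengths are `bp * r * 100` — rather than an
empirical genetic map, which keeps the analytic model and the simulator
exactly aligned; tract lengths from a real map should be converted to cM
upstream and supplied via the `length_cM` column.

## What the synthetic cohorts do and do not emulate

`draw_admixture_proportions()`, `simulate_ancestral_frequencies()`,
`simulate_admixed_genotypes()`, `simulate_admixed_genotype_pairs()` and
`simulate_ancestry_tracts()` generate data from exactly the models the
estimators assume: mixture-distributed ancestry proportions; allele
frequencies drifting on a fixed 4-leaf tree (((H1,H2),H3),H4) by
Balding–Nichols draws, whose closed-form moments make null expectations
checkable; genotypes with ancestry and allele drawn per site, inbreeding
applied site-independently; two-SNP haplotypes with one ancestry per
haplotype; and geometric-length ancestry tracts from the two-state chain.
Every generator is bit-reproducible under a fixed seed.

These choices are estimator-matched, not biological realism: there is no
coalescent history, no genetic map, no contiguous runs of homozygosity, no
phasing or genotyping error, and no LD between the sites used by the
inbreeding and D-statistic machinery. Passing recovery tests therefore
demonstrates correctness of the estimators under their own assumptions —
they do not certify robustness to the ways real data violate those
assumptions (model-misspecified ancestry proportions above all).

Problem sizes used in the test suite were chosen so that each recovery
check has clear statistical resolution at comfortable runtime: cohorts of
1,000–2,000 individuals for frequency-level recoveries, 10,000 sites per
individual for inbreeding, 10,000 SNPs by 200 replicates for D-statistic
calibration, and 1,000 simulated haplotype genomes of 270 Mb for the
tract-model cross-check (the analytic probability depends on $S$ only
through $RS$, so a scaled genome tests the same approximation at higher
event rates).

## Known limitations

* Ancestry proportions are taken as known; their estimation error
  propagates unmodeled into every downstream estimator.
* The EM works pairwise on SNP pairs; it does not phase more than two
  loci, and composite log-likelihoods across pairs are not independent.
* The inbreeding likelihood is composite across linked sites; standard
  errors derived from its curvature would be anticonservative, so none are
  reported.
* The tract model assumes a single admixture pulse and uniform
  recombination; continuous migration or map heterogeneity stretch tract
  lengths in ways the closed form does not capture.
* `filter_individuals()` and `filter_sites()` use pairwise deletion for
  missing genotypes throughout, which is standard for array data but can
  bias r² slightly when missingness is informative.
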