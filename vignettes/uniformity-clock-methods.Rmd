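---
title: "Dating obligate selfing from genotype uniformity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating obligate selfing from genotype uniformity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfingclock)
```

## The problem

Some plant lineages abandon outcrossing entirely: completely
cleistogamous orchids produce only closed, obligately self-pollinating
flowers. Microsatellite (SSR) markers mutate fast, so even a selfing
population should accumulate visible allele variation within tens to
hundreds of generations. When every sampled individual of such a species
shows the *same* multilocus SSR genotype, that uniformity carries
temporal information: the population cannot have been propagating for
long. This package turns that observation into a clock, and surrounds it
with the population-genetic machinery needed to analyse such a study
end to end: SSR summary statistics and distance trees, SNP filtering and
polarisation, heterozygous-SNV "genomic selfing syndrome" metrics, and a
phylogenetic regression of those metrics on mating system.

## The genotype-uniformity clock

Model a population of `Ne` independent obligately selfing lines scored
at `l` SSR loci. At a diploid locus a new allele arises with probability
`2*mu_copy` per generation (two transmitted copies), but under selfed
propagation a new heterozygous allele is eventually *fixed* (reaches
homozygosity) with probability 1/2 and otherwise lost — selfing resolves
an `Aa` genotype to `AA`, `Aa`, `aa` with probabilities 1/4, 1/2, 1/4,
and the symmetric random walk ends at either absorbing state equally
often. The rate of eventually-fixed new alleles per locus per generation
is therefore `2*mu_copy * 1/2 = mu_copy`; we call this the
*fixation-effective* rate `mu` ([`mutation_model()`]).

The probability that one line fixes no new allele at any locus over `t`
generations is

    P_t = (1 - mu)^(l * t)

and the probability that all `Ne` lines still show only the ancestral
multilocus genotype is

    P_i = P_t^Ne.

`generations_to_threshold()` returns the smallest integer `t*` with
`P_i(t*) < alpha`. Observed uniformity therefore bounds the population's
age: persisting beyond `t*` generations would be improbable at level
`alpha`.

```{r clock}
clock_table(mutation_model(), ne = c(50, 100, 500))
```

With the defaults — `mu = 4.96e-5`, the lowest dinucleotide-repeat rate
measured in *Arabidopsis thaliana* mutation-accumulation lines and hence
a conservative (age-overestimating) choice; `l = 6` dinucleotide loci;
`alpha = 0.05` — uniformity becomes improbable by generation 21 for
`Ne = 500`, 101 for `Ne = 100` and 202 for `Ne = 50`. At 5–10 years per
generation (`generation_time_range()`), even the smallest scenario dates
the transition to obligate selfing within roughly the last two thousand
years.

Numerical choices:

* `P_t` and `P_i` are evaluated in log space (`log1p(-mu)`), so very
  large `l * t * Ne` cannot underflow on the way to the threshold.
* The threshold is strict: `P_i(t) = alpha` exactly does **not** count
  as "below". The closed form
  `floor(log(alpha) / (l * Ne * log1p(-mu))) + 1` is used and then
  verified against the log-space curve to absorb floating-point edge
  effects; tests confirm equality with exhaustive search.
* `mu = 0` has no finite answer and returns `Inf` with a warning.

## The forward simulator as an independent oracle

`simulate_uniformity()` estimates the same curve by Monte Carlo, in two
modes.

**Effective mode** draws, for each replicate, the first generation at
which any of the `Ne * l` line–locus Bernoulli(`mu`) streams produces an
eventually-fixed allele. The first success over independent streams has
an exact geometric distribution with per-generation hazard
`1 - (1 - mu)^(Ne*l)`, so the draw is made directly from that
distribution — a vectorisation, not an approximation.

**Explicit mode** (compiled code) simulates every line as a diploid
selfer at the per-copy level: two gametes drawn from the one parent,
each transmitted copy mutating with per-copy probability `mu` under a
stepwise model (repeat count ±1, equal probability; an infinite-alleles
option makes every mutation novel). Under the default `fixed_only`
criterion a line deviates once a new allele reaches homozygosity, and
the deviation is *dated to the generation its segregating non-ancestral
content arose*. This dating convention matters: the analytic `P_t`
counts the arising of mutations destined for fixation, while fixation
itself lags by the mean selfing resolution time (about two generations);
dating at fixation would bias the simulated curve upward by a few
percent in the mid-range, enough to be detectable at 20 000 replicates.
The simulation therefore continues past `t_max` until every lineage
that could still back-date the first deviation has resolved. The
alternative `observed_genotype` criterion counts any non-ancestral
genotype (heterozygotes included) at first observation and decays
faster, as tests verify.

Back-mutation: under the stepwise model a second mutation can restore
the ancestral repeat size. At the rates considered (`mu ~ 5e-5`) the
probability that this affects a uniformity curve is of order `mu`
relative to the signal and is ignored by the analytic model; the
infinite-alleles flag removes the effect entirely for users who want
the closest match to the analytic assumptions.

Monte-Carlo standard errors are per-generation binomial SEs over
replicates. Tests require agreement between effective mode, explicit
mode and the analytic curve within 3 SE at 20 000 replicates, and
recover the 1/2 fixation probability itself within 3 binomial SE at
100 000 replicate lineages.

`simulate_ssr_population()` generalises the machinery to a Wright–Fisher
population of constant size with mixed mating (selfing probability `s`,
otherwise random outcrossing), per-locus mutation rates, and
instantaneous founder events; it is the engine behind the synthetic SSR
generator. Classical checks hold: heterozygosity halves per generation
at `s = 1`, and `F_IS ≈ 0` at `s = 0`.

## SSR summary statistics and trees

`locus_diversity()` reports the allele count `A`, observed
heterozygosity `H_O` (fraction of heterozygous individuals) and expected
heterozygosity `H_E = 1 - sum(p^2)`. The plain gene-diversity form is
the default because reference implementations differ in whether they
report the `2N/(2N-1)` small-sample correction; the corrected form sits
behind `unbiased = TRUE`. `allelic_richness()` uses the rarefaction
estimator

    R_S = sum_i [ 1 - C(N - N_i, g) / C(N, g) ]

evaluated through `lchoose()` for stability; tests verify it against
brute-force enumeration of all subsamples up to `N = 8` copies, and its
default `g` is the largest value admissible for every group–locus
combination (capped at twice the smallest group size).
`inbreeding_coefficient()` is `(H_E - H_O)/H_E` per locus, with
monomorphic loci excluded from the mean — the simple moment form, not
the Weir–Cockerham variance-components estimator. Missing genotypes are
excluded locus-wise (pairwise deletion); `complete_cases_ssr()` provides
the stricter all-loci-amplified filter as an option.

`nei_da()` implements the D_A distance
`1 - mean over loci of sum(sqrt(x_i * y_i))`, with loci unscored in one
group dropped (with a warning) and the locus count adjusted.
`da_matrix(by = "sample")` supports genotype-level distances (each
individual its own frequency vector), since published trees of
multilocus genotypes can be built either way. Neighbour-joining goes
through the standard Saitou–Nei agglomeration; negative branch lengths,
which least squares can produce on non-additive matrices, are clamped
to zero with the deficit moved to the sibling edge so path lengths
through the parent are preserved. On additive matrices the
reconstruction is exact, which the tests exploit as an oracle (100/100
random additive trees recovered with path-length error < 1e-9).
`bootstrap_support()` resamples loci with replacement and reports
bipartition frequencies on the reference topology.

## SNP filtering, polarisation and Delta-K

`filter_snps()` applies the marker-quality rules in a fixed, documented
order — the order matters because the rules interact, and reconciled
per-rule removal counts are only interpretable once the order is pinned:

1. remove SNPs with observed heterozygosity `>= 0.6` (collapsed
   paralogues masquerading as heterozygotes); the boundary value 0.6 is
   removed;
2. remove SNPs whose minor allele is carried by fewer than 3 samples
   dataset-wide (a sample counts once whether heterozygous or
   homozygous); exactly 3 carriers is retained; invariant SNPs have
   zero carriers and drop out here;
3. remove SNPs genotyped in less than a proportion `R` of samples
   (0.1 and 0.7 being the conventional working points);
4. optionally thin to the first SNP per locus group (smallest
   within-locus position) to avoid linked sites.

The filter is idempotent and its report reconciles exactly with the
matrix dimensions; both are tested on a packaged toy fixture that pins
the boundary behaviours.

`polarize_and_histogram()` calls the allele predominant (majority of
copies) in the chasmogamous group ancestral; 50/50 ties resolve to the
reference allele and are counted in the output rather than silently
folded in. `count_fixed_differences()` requires opposite monomorphism
with at least one genotyped sample per group and is symmetric.
`nucleotide_diversity()` uses the unbiased per-site form
`n/(n-1) * 2p(1-p)`, which equals the average pairwise difference among
sampled copies (tested by enumeration). `evanno_delta_k()` is the
absolute second difference of mean log-likelihood over `K` scaled by the
between-run standard deviation; a zero standard deviation leaves that
`K` undefined rather than infinite.

## Heterozygous-SNV selfing-syndrome metrics

`syndrome_metrics()` summarises a sample's heterozygous SNVs over its
transcript set: SNVs per kb, nonsynonymous fraction, deleterious
fraction, deleterious per kb, and the fraction of transcripts carrying a
nonsynonymous SNV. Deleteriousness uses the strict absolute-value rule
`|score| > 2.5`: at a heterozygous site the derived and ancestral
alleles cannot be distinguished, so a strongly positive score is treated
like a strongly negative one. The boundary (`|score| = 2.5` exactly) is
counted neutral under the strict reading; `strict = FALSE` flips it, and
nonsynonymous SNVs without a score are reported as unclassified and
excluded from the deleterious-fraction denominator only. Sister-pair
comparisons default to the equal-variance Student t-test (Welch behind a
flag); the degenerate zero-variance, equal-means case reports
`t = 0, p = 1`.

## Phylogenetic generalized least squares

`brownian_covariance()` builds the Brownian-motion covariance (shared
root-to-MRCA path lengths) from the tree as given — non-ultrametric
trees are accepted, since trait-evolution variance follows total branch
length, not calendar time. `pgls_fit()` solves the GLS normal equations
through the Cholesky factor of `C` (whitening followed by QR), never an
explicit inverse, and declares the design singular below a reciprocal
condition number of 1e-12. Standard errors use the residual variance
with `n - p` degrees of freedom. On a star tree the fit reduces exactly
to OLS; scaling `C` leaves estimates and t-statistics invariant; and on
ultrametric trees the fit matches `nlme::gls` with a Brownian
correlation structure — all tested. `fit_all_metrics()` regresses each
species-mean metric on the selfing indicator independently and applies
no multiple-testing correction, mirroring per-metric reporting in the
literature; the output carries a note saying so.

## The synthetic data generator

`scenario_config()` fixes the study conditions the generators emulate:

* **SSR** (`make_sister_pair_ssr()`): a chasmogamous population of 250
  with selfing/geitonogamy rate 0.95 evolves for 200 generations from
  three-allele standing variation; a cleistogamous lineage of effective
  size 50 is founded from a single individual 15 generations before
  sampling and selfs completely. The 18-locus panel mutates at
  4.96e-5 per copy per generation at its 6 dinucleotide loci and 1e-5
  at the 12 longer-motif loci — longer repeat motifs mutate several-fold
  more slowly, and a single panel-wide dinucleotide rate would make
  18-locus uniformity improbable in a way real mixed-motif panels are
  not. Sampled sizes (54 and 31) echo typical field sampling. With
  these conditions the analytic clock puts the probability of full
  genotype uniformity at sampling near 0.73, so uniformity is the
  typical but not guaranteed outcome; the tests therefore compare the
  uniformity *frequency* across seeds against that analytic bound
  instead of asserting uniformity of every run.
* **SNPs** (`make_sister_pair_snps()`): 125 locus groups × 3 SNPs with
  ancestral frequencies uniform on (0.1, 0.9) drift for 35 generations
  in both descendants — binomial Wright–Fisher steps over `2*Ne` copies
  for the mixed mater and `Ne` haploid-equivalent copies for the
  selfer, whose lines are effectively haploid. Genotypes are drawn with
  inbreeding `F = s/(2-s)` (mixed mater) and `F = 1` (selfer), then
  masked at 5% missingness. Fixed differences grow with divergence
  time, as tested.
* **Variant tables** (`make_variant_tables()`): Poisson SNV counts per
  transcript (log-normal lengths around 1.4 kb), Bernoulli effect
  classes, and class-conditional uniform scores — neutral in (−2.5, 0],
  deleterious in (−8, −2.5); arbitrary but threshold-respecting — so
  realised deleterious fractions match configuration in expectation.
  The selfing profile (0.1 SNV/kb, nonsynonymous 0.45, deleterious
  0.25) against the outcrossing profile (1.0 SNV/kb, 0.35, 0.10)
  encodes the qualitative selfing syndrome: less heterozygosity,
  proportionally more nonsynonymous and deleterious variation.
* **PGLS data** (`make_pgls_dataset()`): a random 16-tip tree, half the
  tips designated selfers, trait = baseline + effect × selfing +
  Brownian noise (sd 0.5 per unit branch length).

Every generator is a pure function of its configuration: the seed fully
determines the output, and tests assert byte-identical reproduction.

What the generators do **not** emulate: real marker ascertainment,
null alleles and stutter, linkage within MIG-seq loci beyond shared
locus labels, population structure within species, selection, or
realistic mutational spectra. Passing tests therefore show that the
statistics and the clock behave correctly under the stated model, not
that the model captures every feature of field data.

## Problem sizes and limitations

The test suite runs the clock analytically (instant), the Monte-Carlo
oracle comparisons at 20 000 replicates, fixation probability at
100 000 lineages, NJ additivity on 100 random trees of up to 8 taxa,
rarefaction by enumeration up to 8 gene copies, and PGLS calibration on
200 Brownian replicates of a 16-tip tree; the full suite completes in
well under a minute. These sizes were chosen so each stochastic check
has at least 3-SE resolution against its oracle.

Known limitations: the clock assumes independent selfing lines with one
surviving offspring each (no drift between lines, no line extinction);
`F_IS` is the moment estimator, not Weir–Cockerham; Structure's MCMC
itself and ABC demographic inference are out of scope (only the
Delta-K utility on supplied log-likelihoods is provided); and the
deleteriousness scores are taken as given — the package does not score
variants.
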