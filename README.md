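# selfingclock

Dating the origin of obligate selfing from multilocus genotype
uniformity, with the population-genomic toolkit around it.

## The problem

Completely cleistogamous plants — those producing only closed,
obligately self-pollinating flowers — are cut off from outcrossing
entirely. Microsatellite (SSR) loci mutate quickly, so even a purely
selfing population should accumulate allele variation within tens to
hundreds of generations. When field sampling of such a species finds
**one identical multilocus genotype everywhere**, that uniformity is a
clock: it bounds how long the lineage can have been propagating.

For a population of `Ne` independent selfing lines scored at `l` SSR
loci with fixation-effective mutation rate `μ` per locus per generation
(a new allele arises at `2μ` per diploid locus but fixes under selfing
with probability ½), the probability that no new allele has been fixed
anywhere after `t` generations is

    P_t = (1 − μ)^(l·t),        P_i = P_t^Ne .

The smallest `t*` with `P_i(t*) < α` converts observed uniformity into
an upper age bound. The package computes this clock analytically,
verifies it with a forward-time Monte-Carlo simulator (both a fast
effective-rate mode and a full explicit-diploid mode with stepwise
mutation), and provides the accompanying analyses of a sister-pair
study of mixed-mating and obligately selfing species:

* SSR summary statistics: allele counts, observed/expected
  heterozygosity, rarefaction allelic richness, F_IS, private alleles,
  Nei's D_A distance, neighbour-joining trees with locus bootstrap;
* SNP-matrix filtering (heterozygosity, minor-allele, missingness and
  one-SNP-per-locus rules with reconciled reports), allele polarisation
  on the outcrossing relative, fixed-difference counts, nucleotide
  diversity, and the Evanno ΔK statistic;
* per-sample heterozygous-SNV "genomic selfing syndrome" metrics
  (SNVs/kb, nonsynonymous and deleterious fractions at the
  |score| > 2.5 cutoff) with sister-pair t-tests;
* phylogenetic generalized least squares under Brownian motion relating
  those metrics to mating system;
* a synthetic-data generator reproducing the statistical structure of
  all of the above, so the full pipeline is testable without any
  downloads.

## Worked example

```r
library(selfingclock)

m <- mutation_model()          # mu = 4.96e-5, l = 6 dinucleotide loci
clock_table(m, ne = c(50, 100, 500))
#>    ne t_star years_min years_max
#> 1  50    202      1010      2020
#> 2 100    101       505      1010
#> 3 500     21       105       210
```

Reading: with an effective population of 50 selfing lines, retaining a
single multilocus genotype for more than 202 generations has
probability below 0.05 — at 5–10 years per generation, uniformity
observed today places the transition to obligate selfing within roughly
the past 1 010–2 020 years. Larger populations tighten the bound (21
generations at `Ne = 500`).

The explicit diploid simulator confirms the analytic curve:

```r
cv <- simulate_uniformity(sim_config(ne = 50, t_max = 202,
                                     n_reps = 20000, mode = "explicit",
                                     seed = 42))
round(cv[c(21, 101, 202), ], 4)
#>     generation estimate     se analytic
#> 21          21   0.7295 0.0031   0.7316
#> 101        101   0.2217 0.0029   0.2225
#> 202        202   0.0494 0.0015   0.0495
```

And the synthetic sister pair shows the field pattern the clock is built
for — a recently founded selfer that is genotype-uniform while its
mixed-mating relative retains variation:

```r
tab <- make_sister_pair_ssr(scenario_config(seed = 1))
attr(locus_diversity(tab, by = "species"), "means")
#>    group        A         Ho       He
#> 1  chasm 2.222222 0.03292181 0.393871
#> 2 cleist 1.000000 0.00000000 0.000000
```

Every sampled cleistogamous individual carries the same multilocus
genotype (one distinct genotype across both of its populations), while
the chasmogamous species keeps 2.2 alleles per locus.

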