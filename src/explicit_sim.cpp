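#include <Rcpp.h>
using namespace Rcpp;

// Explicit diploid forward simulation of obligately selfing lines.
//
// Each line is one diploid selfer carrying n_loci microsatellite loci
// (alleles stored as repeat-count offsets from the ancestral size 0).
// Every generation each line leaves exactly one surviving selfed
// offspring: two gametes are drawn independently from the parent, and
// each transmitted allele copy mutates with per-copy probability mu
// (stepwise +/-1 with equal probability, or a novel allele under the
// infinite-alleles option). A replicate records the first generation at
// which any line deviates from the ancestral multilocus genotype:
//
//  - fixed_only: a line deviates once a new allele reaches homozygosity,
//    and the deviation is dated to the generation the segregating
//    non-ancestral content first arose. The analytic clock counts the
//    arising of mutations destined for fixation, so dating at the
//    arising generation (rather than the fixation generation, which
//    lags by the mean selfing resolution time of ~2 generations) makes
//    the simulated curve estimate the same quantity. Simulation
//    continues past t_max until every still-segregating lineage that
//    could back-date the first deviation has resolved.
//  - observed: any non-ancestral genotype counts, heterozygotes
//    included, at the generation it is first observed.
//
// Returns the first-deviation generation per replicate (t_max + 1 when
// the replicate is uniform through t_max).
//
// Homozygous-locus fast path: when a parent is homozygous the offspring
// genotype is unchanged unless a transmitted copy mutates, so a single
// uniform deviate decides "no mutation in either copy" (probability
// (1-mu)^2); the rare complement is resolved by exact conditional
// probabilities. The process distribution is untouched.

static inline int mutate_step(int allele, bool infinite_alleles, int *novel) {
  if (infinite_alleles) return ++(*novel);
  return allele + (unif_rand() < 0.5 ? 1 : -1);
}

// [[Rcpp::export]]
IntegerVector explicit_first_deviation(int n_reps, int ne, int n_loci,
                                       double mu, int t_max,
                                       bool fixed_only,
                                       bool infinite_alleles) {
  IntegerVector first(n_reps);
  const double p_no_mut2 = (1.0 - mu) * (1.0 - mu);
  const double p_both_given_any =
    (mu > 0.0) ? (mu * mu) / (1.0 - p_no_mut2) : 0.0;
  const int none = t_max + 1;
  const int hard_stop = t_max + 10000;  // safety; settling is ~2 gens
  std::vector<int> a1(ne * n_loci), a2(ne * n_loci), origin(ne * n_loci);

  for (int r = 0; r < n_reps; ++r) {
    std::fill(a1.begin(), a1.end(), 0);
    std::fill(a2.begin(), a2.end(), 0);
    std::fill(origin.begin(), origin.end(), 0);
    int novel = 0;
    int dev = none;
    for (int t = 1; t <= hard_stop; ++t) {
      // decide whether this generation can still change the result:
      // once dev is set, only lineages that arose before it matter, and
      // past t_max only lineages that arose within the window matter
      bool need;
      if (!fixed_only) {
        need = (dev == none) && t <= t_max;
      } else if (dev == none && t <= t_max) {
        need = true;
      } else {
        const int cutoff = (dev == none) ? none : dev;  // strict below
        need = false;
        for (size_t k = 0; k < a1.size() && !need; ++k)
          need = (a1[k] != a2[k]) && origin[k] <= t_max &&
                 origin[k] < cutoff;
      }
      if (!need) break;
      for (int i = 0; i < ne; ++i) {
        for (int j = 0; j < n_loci; ++j) {
          const int idx = i * n_loci + j;
          int p1 = a1[idx], p2 = a2[idx];
          int c1, c2;
          if (p1 == p2) {
            if (unif_rand() < p_no_mut2) continue;  // genotype unchanged
            c1 = p1; c2 = p2;
            if (unif_rand() < p_both_given_any) {
              c1 = mutate_step(c1, infinite_alleles, &novel);
              c2 = mutate_step(c2, infinite_alleles, &novel);
            } else if (unif_rand() < 0.5) {
              c1 = mutate_step(c1, infinite_alleles, &novel);
            } else {
              c2 = mutate_step(c2, infinite_alleles, &novel);
            }
          } else {
            c1 = (unif_rand() < 0.5) ? p1 : p2;
            c2 = (unif_rand() < 0.5) ? p1 : p2;
            if (unif_rand() < mu) c1 = mutate_step(c1, infinite_alleles, &novel);
            if (unif_rand() < mu) c2 = mutate_step(c2, infinite_alleles, &novel);
          }
          a1[idx] = c1; a2[idx] = c2;
          if (!fixed_only) {
            if ((c1 != 0 || c2 != 0) && t <= t_max && t < dev) {
              dev = t;
              i = ne; break;   // first observation settles the replicate
            }
            continue;
          }
          if (c1 == 0 && c2 == 0) {
            origin[idx] = 0;                 // back to ancestral: lineage gone
          } else {
            if (origin[idx] == 0) origin[idx] = t;
            if (c1 == c2 && origin[idx] < dev) dev = origin[idx];
          }
        }
      }
    }
    first[r] = (dev <= t_max) ? dev : none;
  }
  return first;
}
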