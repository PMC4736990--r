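# rguc

Selection of **r**elevant **g**enetic **u**nits for **c**onservation from
dominant (presence/absence) multilocus marker data such as AFLP.

Conservation programs rarely can protect every population of a threatened
species. Given a binary individuals × markers matrix with population labels,
a population → region partition and optional qualitative field attributes,
`rguc` answers three questions in one reproducible pipeline:

1. **How many** populations must be protected? From the among-population
   differentiation (AMOVA Φ/F statistics on squared-distance variation),
   the sampling equation `P = 1 − F_ST^n` gives the smallest `n` with
   `1 − F_ST^n ≥ P` (default target `P = 0.999`).
2. **Where?** Rare bands (overall frequency < 10%, present in < 20% of
   populations) carry the irreplaceable variation. Their loss
   probabilities `L = (1 − p)^2N` define the capture statistic
   `R = m(−log L_e)/m(−log L_o)` (the proportion of rare bands captured by
   sampling one population) and a preferred sampling area per band; the
   per-region counts are apportioned into the `n` slots by the
   largest-remainder method.
3. **Which populations?** Within each region, populations are ranked by
   min-max-normalized Nei gene diversity, frequency down-weighted marker
   rarity (DW) and rare-band counts, with configurable bonuses for
   favourable conservation attributes, plus a coverage pass that flags
   extra populations needed to retain every endemic haplotype.

It also estimates **haplotype-sampling completeness** from `n` sequences
with `k` observed haplotypes via the Stirling probability distribution
`P(k | n, θ) = θ!/(θ−k)! · S(n,k)/θ^n` with a uniform prior on θ, and
ships a seeded **Balding–Nichols F-model generator** of synthetic marker
matrices whose `F` parameter is exactly the quantity AMOVA estimates —
so the whole pipeline is testable end to end without any field data.

## Worked example

A synthetic survey mirroring a 17-population, 3-region, ~360-individual
design with differentiation `F = 0.29`, a dozen injected rare bands, and a
haplotype sample of 61 sequences from a 7-haplotype pool:

```r
library(rguc)

sim <- simulate_marker_matrix(sim_spec(
  n_populations = 17, n_individuals = 21, n_markers = 1100,
  F = 0.29, n_regions = 3, seed = 42,
  rare_injections = data.frame(p = rep(c(0.06, 0.08, 0.05), each = 4),
                               n_carriers = rep(c(1L, 2L, 3L), 4))))

fit <- rguc(sim$matrix, sim$regions,
            haplotypes = simulate_haplotype_sample(rep(1/7, 7), 61, seed = 1),
            config = rguc_config(n_permutations = 199, n_bootstrap = 199,
                                 rng_seed = 1))
print(fit)
print(fit$amova)
```

```
RGUC selection analysis
  17 populations in 3 region(s); F_ST = 0.289
  populations required (P = 0.999): 6
  rare bands: 23; capture R = 0.504
  allocation: R1=0, R2=3, R3=3
  selected: P7, P8, P9, P17, P16, P13
  haplotype completeness: posterior mean theta = 7.002, P(complete) = 0.998
One-level AMOVA (357 individuals, 1112 markers)
             source  df       SS        MS   sigma2 percent
  Among populations  16 21358.44 1334.9027  56.9027   28.91
 Within populations 340 47581.81  139.9465 139.9465   71.09
Fixation indices: F_ST = 0.2891
Permutation p: F_ST = 0.005  (199 permutations)
F_ST 95% CI (marker bootstrap): 0.283-0.294
```

Reading the output: the fitted `F_ST = 0.289` recovers the generator's
`F = 0.29` (the F-model makes that a meaningful check, not a coincidence);
at that differentiation, six populations suffice for 99.9% of the
among-population diversity. `R = 0.504` means sampling a single population
would capture about half of the rare bands — the injected bands sit in 1–3
populations each, so one population is far from enough. The allocation
splits the six slots by where the rare bands are most capturable (regions
R2 and R3 here; by chance none of this draw's 23 rare bands favoured R1),
and the selection lists the top-ranked populations per region.
`write_report(fit, "report/")` writes a full-precision JSON report plus
TSV tables; `summary(fit)` prints per-population profiles and both AMOVA
tables; `plot(fit)` shows the two loss regressions whose slope ratio is R.

Real data enter through `read_marker_matrix()` (TSV/CSV, either
orientation), `read_region_partition()`, `read_population_attributes()`
and `collapse_haplotypes()` (aligned FASTA with multi-base gap runs coded
as single-step events).

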