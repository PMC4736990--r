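---
title: "Methods: prioritizing populations for conservation from dominant markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prioritizing populations for conservation from dominant markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rguc)
```

## The problem

A threatened species with many scattered populations cannot all be protected.
The question this package answers is: **how many** populations must be
conserved to retain a target share of the species' genetic diversity, **how
should that effort be split** across geographic regions, and **which**
populations within each region should be chosen first. The inputs are the
kind of data a conservation-genetics survey typically produces: a dominant
(presence/absence) multilocus marker matrix such as AFLP, a population-to-region
partition, qualitative field attributes per population, and optionally a
small sample of organellar haplotypes.

## The analysis, step by step

### Diversity and rarity descriptors

For dominant markers only the band phenotype is observed, so all descriptors
work on band frequencies $f$:

* **Nei's gene diversity** per population is the mean over the dataset's
  polymorphic markers of $1 - f^2 - (1-f)^2$. We deliberately use the
  phenotypic (band-frequency) estimator: no Hardy–Weinberg square-root
  transform to allele frequencies and no $n/(n-1)$ small-sample factor.
  Dominant data do not identify heterozygotes, every transform adds
  assumptions, and the phenotypic estimator is the simplest defensible
  choice. Both alternatives are switchable (`nei_correction`), and because
  conventions differ between programs we treat absolute diversity values as
  convention-sensitive: comparisons *between* populations computed the same
  way are what the prioritization uses.
* **Frequency down-weighted marker values (DW)** score rarity: for every
  band the population's carrier count is divided by the dataset-wide carrier
  count, the ratios are summed, and the sum is divided by the population's
  sample size (`dw_normalize = FALSE` keeps the raw sum). A population
  whose bands are globally scarce scores high. The normalization is again a
  convention; the within-analysis ranking is what matters downstream.
* **Rare bands** are markers with overall frequency (over all individuals)
  strictly below 10% that occur in strictly fewer than 20% of the
  populations (both thresholds configurable). Note the arithmetic
  consequence: with $K$ populations a band may occupy at most
  $\lceil 0.2K \rceil - 1$ of them, so datasets with five or fewer
  populations can only have rare bands private to a single population.
  For each rare band, $p$ is the *unweighted mean* of its frequencies in
  the carrier populations — deliberately distinct from the overall
  frequency used by the filter, because $p$ feeds the loss model below,
  which conditions on the populations that actually carry the band.

### AMOVA and the number of populations needed

The analysis of molecular variance runs on the pairwise squared Euclidean
distance between band profiles, which for 0/1 data is simply the count of
differing markers. Sums of squares are obtained from the distance matrix
(total from all pairs, within-population from within-population pairs),
variance components follow from the expected mean squares with unequal
sample sizes, and $F_{ST}$ is the among-population share of the total.
With a region partition the three-stratum decomposition yields
$F_{CT}$, $F_{SC}$ and $F_{ST}$. Design choices:

* Permutation tests reassign individuals to populations (sizes preserved);
  hierarchically, individuals are additionally permuted within regions for
  $F_{SC}$ and whole populations among regions for $F_{CT}$. The p-value is
  $(b+1)/(B+1)$ with $B = 1023$ permutations by default.
* The 95% confidence interval for $F_{ST}$ is a percentile bootstrap over
  *marker columns* (1000 replicates). Resampling markers treats loci, not
  individuals, as the replication unit, which matches how multilocus
  dominant panels are usually assessed; it is a documented choice, not the
  only defensible one.
* Negative variance components (common in weakly structured data) are
  reported as-is with a warning; `truncate_negative_variance = TRUE` clamps
  them at zero. Truncation changes percentages, so silence here would be
  worse than noise.
* When regional groups coincide with populations the
  among-populations-within-groups stratum has zero degrees of freedom and
  its component is identically zero, not `NaN`.

The minimum number of populations to protect solves $P = 1 - F_{ST}^{\,n}$:
$n = \lceil \ln(1-P)/\ln F_{ST} \rceil$, default $P = 0.999$. The ceiling
(never rounding) is used because a conservation target is a lower bound.
The real-valued $n$ is reported alongside as a diagnostic so users can see
how close the integer decision was.

### Rare-band loss probabilities and the capture statistic R

The probability that a sampling scheme misses a rare band of frequency $p$
present in $N$ populations is $L = (1-p)^{2N}$. Two values are computed per
band: the **observed** loss $L_o$ with the band's actual carrier count, and
the **expected** loss $L_e = (1-p)^2$, i.e. the $N = 1$ reference in which
only one population is sampled. This definition of $L_e$ is forced by the
interpretation of the final statistic as *the proportion of rare bands
captured by sampling a single population*: regressing $-\log L_o$ and
$-\log L_e$ on $p$ (ordinary least squares with intercept;
`regression_through_origin` switches both fits) and taking the slope ratio
$R = m_e/m_o$ yields $R = 1$ exactly when every band is private to one
population, and $R < 1$ — more redundancy across populations — otherwise.
$R$ is invariant to the logarithm base, which the tests assert.

### Preferred sampling areas and apportionment

Each rare band is assigned to the region where a single randomly drawn
population is most likely to capture it:
$P_g = \tfrac{1}{K_g}\sum_{j \in g}\left[1 - (1-p_j)^{2n_j}\right]$,
with $p_j$ the band's frequency and $n_j$ the sample size in population
$j$. Dividing by the region's population count $K_g$ matters: a band in one
of two populations of a small region beats the same band in one of four
populations of a large region. A simpler carrier-fraction score is
available (`psa_method = "carrier_fraction"`). Ties are broken by the
higher regional mean frequency, then by region label order, so the
assignment is a deterministic total function.

Normalizing the per-region counts gives the proportions by which the
$n$ required populations are split, using Hamilton's largest-remainder
apportionment (floor of each quota, leftover slots to the largest
remainders, remainder ties by label order). The apportionment uses
unrounded proportions by default; `use_rounded_proportions` reproduces
published two-decimal splits exactly when needed.

### Within-region prioritization

Within each region populations are ranked by the mean of the three
min-max-normalized genetic descriptors ($h_{Nei}$, DW, $N_r$), plus
configurable bonus weights for stable vulnerability, legal protection,
large occupation area and high population size. The weights default to
**zero**: the published practice here is expert judgment, and the package's
job is to make that judgment explicit and reproducible rather than to bake
in an arbitrary weighting. After the top-ranked set fills the region's
allocation, a greedy coverage pass flags additional "also recommended"
populations until every endemic haplotype of the region is represented —
mirroring the common situation where a genetically unremarkable population
is the sole carrier of a restricted haplotype.

### Haplotype-sampling completeness

Aligned sequences are collapsed to haplotypes after indel coding: every
maximal gap run longer than one base is treated as a single mutational
event (one presence/absence character; the covered columns are masked for
sequences carrying the run), while single-base gaps remain a fifth
character state in place. Under the model of $\theta$ *equally frequent*
haplotypes, the probability of observing $k$ distinct haplotypes among $n$
sequences is
$$P(k \mid n, \theta) = \frac{\theta!}{(\theta-k)!}\, \frac{S(n,k)}{\theta^n},$$
with $S(n,k)$ the Stirling number of the second kind, computed exactly in
log space by the recurrence $S(n,k) = k\,S(n-1,k) + S(n-1,k-1)$ with
log-sum-exp (stable far beyond $n = 100$). A uniform prior on
$\theta \in \{k, \dots, \theta_{\max}\}$ ($\theta_{\max} = 100$ by default)
gives a posterior whose mass at $\theta = k$ is the probability that
sampling is complete. The result warns if the posterior still has
appreciable mass at the cap. Equal frequencies are the model's assumption,
not a belief: when observed counts are highly skewed the result carries a
caveat note, and the completeness probability should be read as optimistic.

```{r}
dixon_completeness(haplotype_sample(n = 61, k = 7))
```

## The synthetic-data generator

`simulate_marker_matrix()` draws, per marker, an ancestral band frequency
$\pi \sim U(0.05, 0.95)$ and per population a frequency from the
Balding–Nichols distribution
$\mathrm{Beta}\!\left(\pi\tfrac{1-F}{F},\, (1-\pi)\tfrac{1-F}{F}\right)$,
then Bernoulli individuals; $F = 0$ is handled as the exact no-variance
limit. This parameterization was chosen because its $F$ **is** the quantity
AMOVA's $F_{ST}$ estimates, which turns parameter recovery into a real
check: at the default study shape (17 populations × 21 individuals × ~1100
markers, $F = 0.29$) the estimated $F_{ST}$ lands within a few thousandths
of $F$. Rare bands with known truth are injected by overwriting chosen
populations' frequencies; the truth record keeps both the target and the
realized carriers, because a Bernoulli draw at $p \approx 0.06$ over ~20
individuals misses a target population roughly a quarter of the time — the
recovery tests compare against realized carriers for exactly that reason.

What the generator does **not** emulate: linkage between markers, scoring
error and band-homology artefacts of real AFLP data, uneven sampling
effort, isolation-by-distance (populations are exchangeable within the
F-model), and coalescent structure in haplotypes (these are multinomial
draws from a fixed pool, not evolved sequences). Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to those real-data complications.

## Numerical and testing choices

* Test and example simulations are scaled to run in seconds: oracle
  comparisons use 6–18 individuals, calibration checks use 25–30 replicate
  datasets at 49–99 permutations, and one study-shaped run
  (17 × 21 × 1000 markers) verifies parameter recovery.
* Permutation and bootstrap seeds come from the configuration (`rng_seed`),
  so a fitted analysis re-run with the same configuration writes a
  byte-identical JSON report.
* Reports serialize numbers at full precision (no rounding before output);
  rounding to the configured decimals happens only in printed summaries.
* All hard input errors name the offending cell, population or level;
  validation never imputes.

## Known limitations

* Absolute $h_{Nei}$ and DW values depend on estimator conventions (see
  above); compare them only within one analysis.
* The equal-frequency assumption of the completeness model is rarely true;
  the posterior mean is robust to mild skew but the completeness
  probability is optimistic under strong skew.
* The composite prioritization score is a transparent default, not an
  optimality claim; sensitivity to the bonus weights should be explored
  per dataset.
* AMOVA p-values use label permutations, which assume exchangeability of
  individuals under the null; strong family structure within populations
  would violate it.
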