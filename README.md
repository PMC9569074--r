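# foundertrace

Population-genetic reconstruction of the introduction history of isolated
populations founded by a handful of individuals.

When a population is established by a single translocation and then persists
in isolation, its present-day genetics record the founding event: mtDNA
haplotype counts bound the number of founding females, nuclear diversity
bounds the founder group size, and linkage disequilibrium measures the
effective size the population has been drifting at. `foundertrace`
implements that inference chain end to end for the classic data of such
studies — aligned mtDNA sequences and diploid microsatellite genotypes —
motivated by introduced amphibian populations (an ~90-year-old, single-
introduction toad population and its native source), but applicable to any
comparable system.

## What it computes

**Diversity and differentiation.** Haplotype diversity
*h* = *n*(1 − Σ*p*²)/(*n* − 1) and per-site nucleotide diversity *π* with
Nei's standard deviations; allele counts, private alleles, and rarefied
allelic and private allelic richness (expected alleles in *g* gene copies);
observed and unbiased expected heterozygosity; Weir–Cockerham *F*~IS~;
conditional exact Hardy–Weinberg tests (full enumeration or Monte-Carlo)
with Bonferroni correction; pairwise Φ~ST~ (AMOVA on inter-haplotype
nucleotide differences) and *R*~ST~ (AMOVA on squared allele-size
differences, variance components summed over loci) with permutation tests;
isolation by distance via Spearman's rho between individual-level Nei
genetic distances and Vincenty geodesic distances.

**Effective population size.** The single-sample LD method: Burrows'
composite disequilibrium Δ̂ from unphased genotypes,
*r*² = Δ̂²/(*p*~A~(1−*p*~A~)*p*~B~(1−*p*~B~)) over MAF-screened allele
pairs, the small-sample expectation E[*r*²] = 1/*S* + 3.19/*S*² subtracted,
and *N̂*~e~ = (1/3 + √(1/9 − 2.76 *r*²′))/(2 *r*²′) under random mating,
with delete-one-locus jackknife confidence intervals.

**Founding simulations.** A female-founder retention model (how many
founding females are compatible with the observed haplotype count, with the
analytic oracle E[*H*] = Σ(1 − (1 − *p*~h~)^*k*)) and an individual-based,
age-structured forward simulator of the founding bottleneck: overlapping
generations, fixed lifespan, dioecious random mating with female-limited
annual recruitment, and a deterministic logistic size schedule
*N*\*~y+1~ = round(*N*\*~y~ + (λ−1)*N*\*~y~(1 − *N*\*~y~/*K*)). The
compiled core makes 1000-iteration scenario grids cheap.

**Grid-matching inference.** `fit_founder_history()` simulates a founder
size × growth rate grid, accepts growth rates whose census trajectory
passes through the observed census window, accepts founder sizes whose
terminal allele number brackets the observed value, and summarises
*N*~e~/*N*~c~. A synthetic-data generator produces source populations with
prescribed haplotype spectra, allele counts and heterozygosities so the
whole chain is testable without any external data.

## Worked example

```r
library(foundertrace)
set.seed(1)

# a source population like the native one: 38 haplotypes (h ~ 0.967),
# 11 microsatellite loci, ~17.3 alleles/locus, H_E ~ 0.795
src <- make_source_model(synthetic_preset("yantai-like"))
d   <- sample_dataset(src, 89, population = "Yantai")
diversity_summary(d$haplotypes, d$genotypes)
#>    N n_hap    h  h_sd    pi pi_sd N_A N_PA    N_a    A_R   H_O   H_E  F_IS
#> 1 89    30 0.96 0.007 0.008 0.004 188  188 17.091 17.091 0.781 0.782     0

# census size from one mark-recapture session
lincoln_petersen(81, 51, 21)
#> Lincoln-Petersen: N = 81 x 51 / 21 = 197
ne_nc_ratio(c(20, 57), c(1500, 4000))
#> Ne/Nc ratio: 0.005-0.04

# how many founding females retain 2 haplotypes?
draw_females(src, k = 3, reps = 100)
#> k = 3 females: retained haplotypes median 3 [IQR 3-3, range 1-3] (100 reps)
infer_female_range(src, observed = 2)
#> [1] 2

# founder size and growth rate by grid matching (200 iterations/scenario)
cfg <- demographic_config(sex_ratio = c(1, 3), capacity = 5000,
                          years = 100, iterations = 200)
fit <- fit_founder_history(src, observed_na = 6.0,
                           nc_range = c(1500, 4000),
                           config = cfg, ne_range = c(20, 57))
fit
#> Founder-history grid match
#>   observed N_a = 6.00, census window 1500-4000 (year 90)
#>   accepted lambda: 1.04, 1.06, 1.08
#>   accepted founder size: 40, 60
#>   Ne/Nc: 0.005-0.04
```

Reading: a census window of 1500–4000 animals ~90 years after introduction
is compatible with annual growth rates of 4–8%; an observed mean of 6.0
alleles per locus (against a source at 17.3) is compatible with a founder
group of 40–60 animals; and two mtDNA haplotypes need only about two
founding females. `summary(fit)` tabulates every simulated grid cell and
`plot(fit)` draws the allele-number trajectories against the observed
level.

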