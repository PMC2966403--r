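# phylogeocat

Comparative mtDNA phylogeography and climate-envelope niche modelling in R.

The package implements the analysis stack used to contrast the population
histories of co-distributed species from short mitochondrial fragments —
the motivating case being two small Indian felids (jungle cat, *Felis
chaus*, and leopard cat, *Prionailurus bengalensis*) whose contrasting
genetic structure turns out to track a climatic limit rather than any
physical barrier. It covers:

- **Haplotypes and polymorphism** — FASTA I/O, gene concatenation,
  collapsing identical sequences into haplotypes (strict or
  complete-deletion missing-data policy), segregating sites with
  transition/transversion classification.
- **Diversity and neutrality** — gene diversity `h = n/(n-1)(1 - Σp_i²)`,
  nucleotide diversity π, mean pairwise differences θπ (Tajima's total
  variance), Watterson's `θs = S/a₁`; Tajima's D and Fu's Fs with p-values
  from seeded constant-size coalescent simulations conditioned on
  θ̂ = θπ.
- **Mismatch distributions** — the sudden-expansion model
  `F(d; τ, θ₀, θ₁)` (geometric equilibrium propagated through an
  instantaneous expansion), least-squares fitting with a parametric
  bootstrap (SSD and Harpending's raggedness p-values, percentile CIs),
  and expansion dating `t = τ/(2µ)` with a per-bp substitution-rate
  calibration.
- **Population structure** — haplotypic AMOVA on pairwise differences
  (Φ_ST, reported as F_ST in much of the literature) with permutation
  tests, pairwise population Φ_ST matrices, great-circle distance matrices
  (haversine, R = 6371 km), and Mantel tests of isolation by distance
  (exact enumeration for small label sets).
- **Networks and trees** — median-joining haplotype networks (Bandelt et
  al. 1999; quasi-median vectors, ε-relaxed minimum-spanning network,
  degree-≤2 pruning), Jukes-Cantor distances, neighbour-joining trees with
  site-resampling bootstrap, reciprocal-monophyly checks.
- **BIOCLIM niche model** — ESRI ASCII-grid raster I/O, Pearson
  correlation variable filtering (|r| > 0.7), percentile envelopes
  (2.5% tails), tent-percentile-min suitability scoring, seeded
  pseudo-absence sampling, replicated 75/25 train/test AUC evaluation,
  and per-variable threshold reports.
- **Synthetic data** — coalescent alignments under constant-size,
  sudden-expansion and two-island demographies (finite- or infinite-sites
  mutation) and gradient-plus-noise climate rasters with
  threshold-governed presence sampling, so the whole pipeline is testable
  offline.

## Worked example

```r
library(phylogeocat)

# simulate a population that expanded tau = 4 mutational units ago
model <- demography_model("sudden_expansion", theta0 = 1, theta1 = 100,
                          tau = 4, n = 50)
aln <- simulate_alignment(model, L = 601, seed = 7)

diversity_summary(aln)$theta_pi
#> [1] 5.110204
tajimas_d(aln, n_sims = 1000, seed = 1)$D
#> [1] -2.343818
fit <- fit_sudden_expansion(mismatch_histogram(aln), n_boot = 100, seed = 1)
coef(fit)["tau"]
#>      tau
#> 5.519607
expansion_time(coef(fit)[["tau"]], L = 601,
               rate_per_bp_per_year = 1.3e-8)$t_truncated
#> [1] 353232
```

The strongly negative Tajima's D and a fitted τ of the simulated order
are the classic expansion signature (single realizations scatter around
the truth; the recovery property is asserted over 50 replicates in the
tests). With the 1.3%/bp/Myr mtDNA calibration and a one-year generation
time, τ converts to an expansion age in years — the same arithmetic that
maps τ = 2.605–4.240 on 601 bp to the mid-Pleistocene window
166,709–271,342 years.

The full per-species pipeline is driven by a config list or YAML file:

```r
run_phylogeography(config, out_dir)   # diversity/neutrality/AMOVA/mismatch/
                                      # network/tree/Mantel report bundle
run_niche(config, out_dir)            # correlation filter, envelope model,
                                      # suitability grid, replicate AUC
```

A thin command-line wrapper is provided in `inst/cli/phylogeocat.R`:

```sh
Rscript inst/cli/phylogeocat.R all --config config.yaml --out results
```

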