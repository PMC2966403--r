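---
title: "Models and methods behind phylogeocat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phylogeocat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

phylogeocat implements a comparative-phylogeography workflow for short
mitochondrial fragments, together with a presence-only climate-envelope
niche model. This vignette is the package's own account of the statistics
it computes, the conventions it fixes where the literature leaves choices
open, and what its synthetic-data tests do and do not demonstrate.

## Sequence handling and haplotypes

Alignments are character matrices over `A,C,G,T,N,-`; input is
case-normalized and `U` is mapped to `T` with a warning. Two missing-data
policies are supported everywhere a comparison is made:
`complete-deletion` (the default, mirroring the convention of the widely
used population-genetics packages) removes any column containing `N` or
`-` in *any* sequence before comparison; `strict` compares sequences as
given. The choice matters: under complete deletion two sequences that
differ only at a masked column share a haplotype. Haplotype tables are
ordered by decreasing count with ties broken by first occurrence, so all
downstream outputs are deterministic.

Segregating sites are columns with two or more distinct `A/C/G/T`
symbols; each is classified as a transition (purine-purine or
pyrimidine-pyrimidine state pair) and/or transversion over its observed
state pairs, so a three-state column can contribute to both tallies.

## Diversity and neutrality

Gene diversity uses the small-sample estimator
`h = n/(n-1) (1 - Σ p_i²)` with Nei's (1987) sampling variance. θπ is the
mean pairwise difference count over all n(n-1)/2 pairs; its reported
standard deviation is Tajima's (1983) *total* variance (sampling plus
evolutionary), which is what the standard packages print in their
diversity tables. Watterson's θs = S/a₁ uses the unbiased estimator
S(S-1)/(a₁²+a₂) for θ² inside its variance.

Tajima's D uses the 1989 constants. Fu's Fs is computed from the Ewens
sampling formula: S′ = Pr(K ≥ k_obs | θ = θπ, n), with unsigned Stirling
numbers of the first kind evaluated in log space by the recurrence
|s(n+1,k)| = |s(n,k-1)| + n·|s(n,k)| (stable to n well beyond 55), and
Fs = ln(S′/(1−S′)). When S′ underflows to 0 or 1 the statistic is returned
as ±Inf with a boundary flag rather than an error.

**Null distributions.** p-values for D and Fs come from seeded neutral
constant-size coalescent simulations conditioned on θ̂ = θπ (1000 by
default). The simulations are infinite-sites while the observed statistics
come from finite observed alignments; this asymmetry follows the cited
convention and is intentional. Two conventions were fixed deliberately:

- The reported p is the *lower-tail* probability P(stat_sim ≤ stat_obs).
  For positive observed D this yields large p, matching how the standard
  packages print, e.g., D = 0.648 with p = 0.781. A two-sided option
  exists for D.
- Monte-Carlo p-values count the observed configuration in both numerator
  and denominator, p = (1 + #{sim ≤ obs})/(m + 1). This makes the null
  rejection rate at level α equal to ⌊α(m+1)⌋/(m+1) — never
  anticonservative. The package's calibration test (2000 constant-size
  replicates, 100 null simulations each) recovers the nominal 5% level
  exactly under this convention.

## Mismatch distributions and expansion dating

The sudden-expansion model: a population at equilibrium θ₀ expands
instantaneously to θ₁ at τ units of mutational time before the present.
The expected distribution of pairwise differences is

F(d) = F_e(d, θ₁) + e^{−τ(θ₁+1)/θ₁} Σ_{m=0}^{d} (τ^m/m!) [F_e(d−m, θ₀) − F_e(d−m, θ₁)]

with F_e(d, θ) = θ^d/(1+θ)^{d+1} the geometric equilibrium law. The
implementation is validated against direct numerical integration of the
coalescence-time mixture.

Fitting minimizes the sum of squared deviations between observed relative
frequencies and F over the observed difference classes, by a deterministic
coarse grid (τ and θ₀ including the boundary 0; θ₁ up to an upper search
bound of 99999, at which boundary estimates are reported, as is
conventional) followed by Nelder-Mead refinement; the grid optimum is kept
if refinement fails to improve. Confidence intervals and the SSD /
raggedness p-values use a parametric bootstrap: data are re-simulated
under the fitted model with the package's own coalescent simulator
(infinite sites) and re-fit.

Harpending's raggedness is computed on the zero-padded frequency vector,
r = Σ (x_i − x_{i−1})² including the leading and trailing steps, so a
point mass at d = 0 gives r = 2.

Expansion dating uses t = τ/(2µ) with µ = L × rate × generation time per
sequence per generation. The default rate is 1.3%/bp/Myr (the felid mtDNA
combination of cytochrome b at 1.38%/Myr and NADH5 at 1.22%/Myr) with a
one-year generation time; printed values are truncated to whole years
alongside full precision. τ = 2.605 and 4.240 on 601 bp give 166,709 and
271,342 years.

## AMOVA, Φ_ST and isolation by distance

Population structure uses the one-level haplotypic AMOVA of Excoffier,
Smouse & Quattro (1992) on pairwise difference counts treated as squared
distances: SS_total = Σ_{i<j} d_ij/N, within-population sums per
population, variance components via expected mean squares with unequal
sample sizes, and Φ_ST = σ²_among/(σ²_among + σ²_within). Much of the
empirical literature prints this statistic as F_ST; the package keeps the
Φ notation and documents the equivalence. Negative variance components are
retained (a flag is set) rather than truncated — small negative pairwise
values are a normal feature of the estimator under no structure.
Significance comes from permuting individuals among populations with sizes
held fixed (default 10,000 permutations, seeded), with the observed
configuration counted.

Geographic distances are haversine great-circle distances on a sphere of
radius 6371 km; population-to-population distance is the mean over
cross-population sample pairs. The Mantel test correlates lower triangles
without any transformation (raw Φ_ST against raw km), with a one-tailed
permutation p; for five or fewer populations the permutation distribution
is enumerated exhaustively, so small-instance p-values are exact.

Latitudinal band assignment follows printed band limits of 10-19.9°N,
20-28.9°N and 29-35°N; since the printed bands leave gaps, the package
fixes the closure rule as the half-open intervals [10,20), [20,29),
[29,35], assigning gap values to the lower band.

## Median-joining networks

The network algorithm follows Bandelt, Forster & Röhl (1999): iterate
(1) the ε-relaxed minimum spanning network under Hamming distance — an
edge (u,v) is kept when d(u,v) is within ε of the weight at which the two
components first connect during ascending Kruskal processing — and
(2) addition of novel quasi-median vectors for triples with at least two
MSN links (per-site majority consensus; sites where all three states
differ branch over the three choices, capped to avoid combinatorial
blow-up). After convergence, median vectors of degree ≤ 2 are pruned
iteratively. ε defaults to 0, the distributed program's default. All ties
break by lexicographic node index, so output is invariant to haplotype
input order; this is regression-tested. Characters are equally weighted.

## Trees

Jukes-Cantor distances use the closed form d = −(3/4)·ln(1 − 4p/3) with a
saturation error at p ≥ 0.75 naming the offending pair. Neighbour-joining
delegates to the standard Saitou-Nei implementation; negative branch
lengths are clamped to zero with the deficit moved to the sister branch
(path lengths through the parent preserved) and flagged. Bootstrap support
is site resampling: each replicate resamples columns, rebuilds the JC/NJ
tree, and support is the percentage of replicates containing each internal
bipartition of the point tree; saturated replicates are skipped and
counted. Likelihood tree search and substitution-model selection are out
of scope — the distance pathway carries the monophyly conclusions.

## BIOCLIM niche model

Variables are screened by pairwise Pearson correlation: while any pair has
|r| above the cut-off (0.7 by default) the worse-ranked member of the
worst pair is dropped, where rank comes from a caller-supplied priority
order — this encodes the practice of preferring climatic extremes when
statistics alone cannot choose.

Envelopes per variable are [q(tail), q(1−tail)] of the presence values
with tail = 0.025, using the linear-interpolation quantile (R type 7);
the choice of quantile rule moves bounds by less than one inter-point gap.
Suitability scoring uses the standard tent rule: per variable
s = 1 − 2|P − 0.5| with P the training percentile of the cell value (0
outside the envelope), combined across variables by the minimum. The exact
scoring of the historical GUI implementation is undocumented, so the
package fixes this standard formulation and additionally emits the raw
in-all-envelopes Boolean for comparison; which of the two the original
AUC used is likewise unstated, so both scores are available to the
evaluator.

Pseudo-absences are drawn uniformly without replacement from valid
(non-nodata) cells of the full analysis extent, seeded. Evaluation
follows the replicate protocol: ten random 75/25 presence splits, envelope
fit on the training portion, AUC (rank-based Mann-Whitney, ties half) of
test presences against freshly drawn pseudo-absences equal in number to
all presences. Per-variable threshold reports give the mean with a 95%
t-interval, the maximum, and the count of presences above a supplied
threshold — the summary used to argue a hard upper summer-temperature
limit (no presences above 38 °C in the motivating analysis).

Rasters are ESRI ASCII grids, north-up with cell-center registration; the
reader/writer is built in because the format is a dozen lines of header
plus a matrix, and round-trip fidelity is tested.

## Synthetic data: what it emulates, and what it does not

The coalescent generator simulates genealogies in units of N_e
generations (mtDNA: θ = 2N_e µ_seq), with mutations Poisson on branches at
θ/2 per lineage per unit. Three demographies cover the analysis
assumptions: constant size; sudden expansion (rate multiplier θ₁/θ₀
beyond τ/θ₁ time units back, with θ₀ = 0 collapsing remaining lineages at
the boundary); and a two-island model with scaled migration M and an
optional merge time. Finite-sites mutation places hits uniformly over L
positions with a transition bias (default ti/tv = 4.7, the ratio observed
in the motivating data, 28:6); infinite-sites mode gives each mutation its
own column and is used for oracle tests and the parametric bootstrap. The
climate generator produces linear row/column gradients plus seeded
Gaussian noise, and presence points are sampled uniformly from cells
satisfying a hard climatic predicate — emulating occupancy governed by a
summer-temperature ceiling.

Everything is bit-reproducible from (parameters, seed), and seeded
internals restore the caller's RNG stream.

These simulations validate the estimators under their own assumptions:
panmixia or clean two-deme structure, no recombination, no rate
heterogeneity among sites, no sequencing error, uniform sampling in space.
Passing tests therefore demonstrate correctness of the implementations and
calibration of the tests, not that real scat-derived mtDNA fragments meet
those assumptions; in particular real data bring missing bases, uneven
spatial sampling and possible homoplasy that the generator only partially
mimics (via its missing-data-free finite-sites model).

## Problem sizes and numerical choices

The test suite and acceptance script size their simulations to keep the
default run comfortably reproducible on a laptop: the type-I calibration
uses 2000 replicates of n = 20 with 100 null simulations each; τ recovery
uses 50 replicates at the study's stated conditions (n = 50, L = 601,
θ₀ = 1, θ₁ = 100, τ = 4); Φ_ST trends use 20 replicates per migration
rate; the BIOCLIM fixture uses a 40×40 grid with 140 presences, matching
the presence count of the motivating analysis. SSD minimization uses a
fixed grid plus Nelder-Mead (reltol 1e-10); bootstrap CIs are 2.5/97.5
percentiles; all permutation and simulation counts are explicit arguments
with seeded defaults, never wall-clock dependent.

## Known limitations

- Fu's Fs depends on the haplotype count after missing-data handling;
  different deletion policies can shift K by a few units and Fs by
  several units on real data with patchy coverage.
- The AMOVA is one-level (populations within total); hierarchical
  group/population/individual designs are not implemented.
- The quasi-median cap can, in principle, skip median vectors for highly
  homoplastic triples; for mtDNA-scale divergence this does not arise.
- The niche model is presence-only and threshold-based by design; it
  cannot weight variables, and AUC against pseudo-absences measures
  discrimination from background, not probability calibration.
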