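---
title: "Models and methods behind pondassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pondassembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pondassembly` implements the computational chain used to study how
bacterial and micro-eukaryotic communities of shallow Arctic thermokarst
ponds assemble, and how that assembly relates to dissolved greenhouse
gases. This vignette is the package's own account of the models, the
parameters that matter, the numerical choices, and what the synthetic-data
tests do and do not demonstrate about field data.

## The denoising model

Amplicon reads of a fixed-length marker are merged from overlapping pairs,
quality-filtered, dereplicated and clustered into "true" genotypes. Two
error processes are distinguished:

* **Propagating (PCR) errors**, rate `eps_pcr` per base per duplication:
  a substitution arising in cycle *c* is inherited by all descendant
  molecules, ending at a pool frequency of roughly `2^-c` relative to its
  template.
* **Non-propagating (sequencing) errors**, rate `eps_seq` per base per
  read, independent across reads.

Under exponential amplification a molecule sampled at the end has
undergone on average `cycles/2` duplications (each cycle, half the pool
consists of that cycle's new copies), so the effective per-base
substitution rate of a read is `eff = eps_seq + (cycles/2) * eps_pcr`.
The probability that a read of a parent reproduces the *d* specific
substitutions of a query is `(eff/3)^d`, giving the expected error-child
count `mu = N_parent * (eff/3)^d`. Queries are processed in decreasing
abundance order; a query is promoted to a genotype only if its count is
too high to be error-derived from every candidate parent within
`max_parent_dist` (default 10) substitutions:
`P(X >= count | X ~ Poisson(mu)) < alpha`. Reads of merged queries funnel
transitively into their ultimate ancestor's total, which is also the
abundance used for later parent tests.

**Why `alpha` defaults to 1e-20, not a conventional 1e-3.** The test is
per query, and a realistic run screens thousands of dereplicated error
variants; the expected number of falsely promoted genotypes is roughly
`n_queries * alpha`. At `alpha = 1e-3` a 50,000-read data set is
mathematically guaranteed several spurious genotypes — a calibrated test
promotes one in a thousand null queries by construction. Setting the
default to 1e-20 keeps the familywise expectation far below one while
costing essentially no sensitivity: a genuine genotype carries hundreds or
thousands of reads where `mu` is a few, so its tail probability is
astronomically small anyway (a 30-read query against `mu = 1` has
`P approx 8e-33` and is still promoted). Denoisers in wide use make the
same choice for the same reason (DADA2's analogous abundance p-value
threshold defaults to 1e-40). The rule itself, and its behaviour at
`alpha = 1e-3`, are unchanged and unit-tested; only the default level
reflects the multiplicity.

**Distances.** Amplicons are fixed-length, so the distance is Hamming on
equal-length sequences; sequences of unequal length (possible after
imperfect merging) are compared prefix-anchored with the terminal overhang
tolerated. An alternative UNOISE-style skew rule
`beta(d) = 1/2^(a d + 1)` is available behind `method = "unoise"` for
comparison.

**Chimera check.** Before a query is accepted as a genotype it is tested
against the whole accepted set: it is chimeric if some breakpoint
`0 < b < L` exists with the query exactly equal to one parent over
`[1, b]` and another over `(b, L]`, both parents at least
`min_parent_skew` (default 2) times more abundant, and the query distinct
from both. Only single-crossover chimeras with exact segment matches are
considered; multi-crossover chimeras are out of scope. Chimeric queries
are discarded and their reads are not funneled, so the read-count
conservation identity

```
sum(genotype totals) + chimeric reads + removed singletons = dereplicated reads
```

holds exactly and is asserted by the test suite.

## The synthetic read generator

The generator is the inverse of the denoiser's model. Each genotype is
amplified on an explicit bounded tree: a pool of (haplotype, abundance)
pairs starts from `n_templates` molecules (default 20,000), doubles each
cycle, acquires new single-substitution haplotypes as a Poisson arrival
process, and is rescaled proportionally to a cap of 2^16 molecules.
Two modelling choices deserve justification:

* **Template number.** With very few starting templates, a cycle-1 error
  is inherited by about 1/(2 n) of all reads — with n = 1000 that is a
  multi-read "jackpot" burst that no abundance-based test can distinguish
  from a real genotype. Real amplicon PCRs start from 10^4–10^6 template
  molecules; the default 20,000 keeps bursts far below one read while
  leaving errors genuinely propagating (tests demonstrate multi-read
  sharing explicitly with `n_templates = 20`).
* **Proportional rescaling at the cap.** Resampling the pool
  multinomially would make every post-cap lineage a critical branching
  process whose sizes drift with large variance — an artifact of the
  bounded tree, not of PCR, where pools are huge and lineage frequencies
  nearly deterministic. The pool is therefore rescaled proportionally;
  stochasticity remains in mutation arrivals and in the final read draw.

Chimeric reads are spliced from the two parents' *true* sequences at a
uniform internal breakpoint and then receive sequencing errors. Quality
strings are constant-Q with `Q = -10 log10(eps_seq)`; that is sufficient
to exercise the expected-errors filter, and per-base quality profiles are
deliberately out of scope.

## The metacommunity generator

Each of `n_sites` sites (two types, e.g. polygonal vs trough ponds,
environmental values -1 and +1) recruits `individuals_per_site`
individuals from a shared regional pool with rank-ordered lognormal
abundances. A fraction `w` (the recoverable truth) recruits
deterministically with Gaussian suitability
`reg_i * exp(-(env - opt_i)^2 / (2 sigma^2))` on a single environmental
axis; the remainder recruits by neutral lottery.

**Ecological drift.** A pure shared-pool multinomial lottery produces
communities that are genuinely *more similar than chance*: with identical
recruitment probabilities everywhere, every abundant taxon occurs at every
site and pairwise dissimilarities fall below any richness-preserving null
— the Raup-Crick index correctly reports RC < -0.95 throughout. Field
occupancy patterns are the opposite (in the motivating system only 2 of
~2500 bacterial OTUs occurred in all 20 ponds), because real neutral
assembly includes drift and priority effects. The neutral component
therefore draws each site's lottery weights from a Dirichlet distribution
with concentration `drift_theta * regional_abundances`
(`drift_theta = Inf` recovers the pure lottery). The defaults — pool 400,
lognormal sdlog 2, `drift_theta = 100`, 1000 individuals, 12 sites — were
calibrated once so that per-site richness (~85) and mean pairwise
Bray-Curtis dissimilarity (~0.5) fall in the range observed for the field
system (richness 60–420, dissimilarity ~0.67).

What passing tests show: that the null models detect the built-in
stochastic/deterministic contrast and that the denoiser inverts its own
error model. What they do not show: performance under real quality-score
miscalibration, indels, length variation, multi-axis niches or
phylogenetically conserved traits, none of which the generator emulates.

## Null models

The regional pool (occurrence frequencies and pooled relative abundances)
is always derived from the analyzed table itself. A null community for a
sample with richness S and N individuals draws S species without
replacement with probability proportional to occurrence frequency
(`species_weighting = "equiprobable"` is available), gives each one
individual, and assigns the remaining N - S multinomially proportional to
regional relative abundance restricted to the drawn set — so observed
richness and abundance totals are preserved exactly. One null draw per
sample per replicate serves all pairs, which is marginally identical to
per-pair draws at O(n) rather than O(n^2) cost;
`null_dissimilarity_distribution()` retains the per-pair form and is
checked against full enumeration on 3-species pools.

* **Raup-Crick:** `RC = 2 * [#(D_null < D_obs) + 0.5 #(ties)]/reps - 1`,
  with ties counted half (this matters at small rep counts and is
  documented behaviour). Bins: RC < -0.95 (more similar than chance),
  [-0.95, 0.95] (consistent with stochastic assembly), RC > 0.95.
* **NST:** selection strength `SS = (E - D)/E` when the observed D falls
  below the null expectation E, else `(D - E)/(D_max - E)` with
  `D_max = 1` for Bray-Curtis; `NST = 100 * mean(1 - SS)` over within- or
  between-group pairs. The two anchors — null-indistinguishable pairs give
  100%, maximally divergent pairs 0% — are enforced by tests rather than
  by matching any particular software's internals. `E = D_max` pairs are
  flagged and set to SS = 1. A bootstrap over samples within groups
  (999 draws, two-sided) tests group differences.
* **Occupancy stratification:** the table is restricted to OTUs present
  in at least k (cumulative, default) or exactly k ponds and NST is
  recomputed per level; k = 1 reproduces the unstratified value.
  Both modes exist because either reading of the occupancy classes is
  defensible; neither is asserted as canonical.
* **βMNTD/βNTI:** abundance-weighted mean nearest-taxon patristic
  distance, z-scored against `n_reps` shuffles of the tip labels across
  the whole tree (one shuffle per replicate, shared by all pairs). Pairs
  with zero null standard deviation are reported NA: notably, two samples
  with identical taxon sets have βMNTD = 0 under *every* shuffle, so
  their βNTI is undefined rather than negative — phylogenetic clustering
  is detectable only for communities confined to related taxa while the
  table contains others, and the tests exercise exactly that contrast.

Monte-Carlo settings in the shipped checks (200 null replicates for
RC/NST, 999 tip shuffles, 12 sites, pool 400, 50,000 reads for the
denoiser benchmark) are desk-scale study conditions chosen to keep the
whole suite in a few minutes; `n_reps = 1000` is the analysis default.

## Geochemistry

`K_H(T) = K_H25 * exp(coeff * (1/T - 1/298.15))` with compiled freshwater
constants (CO2: 0.0334 mol/L/atm, 2400 K; CH4: 1.4e-3, 1700 K) and 2018
atmospheric mixing ratios (407 ppm, 1.85 ppm), all configurable; no
salinity correction, as the systems are dilute tundra ponds. The headspace
inversion solves the mass balance of equilibrating 40 ml water with 20 ml
ambient air (ideal-gas headspace), subtracting the injected ambient
amount; a forward simulator of the same balance provides a round-trip
identity test (recovery to < 0.1% across concentrations and temperatures).
Negative balances are clamped to zero with a warning. The Box-Cox power
parameter is fitted by profile likelihood on a grid (default [-5, 5],
step 0.01) after scaling by the geometric mean — the estimate is
scale-invariant, and without the scaling an extreme lambda can collapse
the transformed values to a numerical constant and blow up the profile.
The isotopic correction of δ13C-CH4 for atmospheric contribution is not
implemented (its mixing model is not specified); only the concentration
correction is.

## Interfaces and determinism

All tables are TSV with OTUs as rows; reads are Phred+33 FASTQ (a
quality-range heuristic rejects files that look Phred+64); trees are
Newick via ape and must carry branch lengths for βNTI. Every stochastic
function takes an explicit seed and `run_pipeline()` derives all stage
seeds from one configuration seed, so reruns are byte-identical; the
manifest logs every default actually used (error rates, alpha, null
replicates, algorithm variants) together with per-stage read counts.
The exported functions and the YAML-configured `run_pipeline()` are the
package's interface; there is no separate shell executable.

## Known limitations

Indels, primer trimming, taxonomy assignment and tree inference are out
of scope (trees are consumed as input); the chimera model is single
crossover with exact segments; per-sample denoising is not offered —
denoising is pooled with per-sample count tracking, because the chimera
check is defined against the whole data set; NST bootstrap p-values are
approximate for small groups; and the synthetic generator's realism
limits, listed above, bound what green tests imply about field data.
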