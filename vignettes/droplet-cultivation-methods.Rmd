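---
title: "Models and methods: droplet cultivation design and strain-level profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: droplet cultivation design and strain-level profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the models implemented in `dropstrain`, the
assumptions behind them, the parameters that matter, and the limits of
what the simulation-backed tests can show about real data.

## 1. Poisson loading design

Partitioning a well-mixed dilute suspension into monodisperse droplets
puts a Poisson-distributed number of cells into each droplet:

$$P(X = n) = e^{-\lambda}\frac{\lambda^n}{n!}, \qquad \lambda = \rho V,$$

with $\rho$ the cell density (CFU/mL) and $V$ the droplet volume. Units
are fixed package-wide — diameters in µm, volumes in pL, densities in
CFU/mL — and conversions are explicit constants (1000 µm³ = 1 pL,
10⁹ pL = 1 mL), never inferred. At the design point $\lambda = 0.3$ in a
30 µm (≈14 pL) droplet, about 74% of droplets are empty, 22% hold
exactly one cell, and under 4% hold two or more, so nearly every grown
droplet is a clonal culture. The pmf is evaluated in log space
(`lgamma`) so occupancy probabilities stay accurate for $\lambda$ up to
~100 during design exploration. Rounded figures ("~14 pL", "~22%") are
presentation only; all internal values are full precision.

$\rho V$ at the commonly quoted density of $2\times10^7$ CFU/mL and
14 pL is 0.28; the package treats 0.3 as the design target and
$2\times10^7$ as its one-significant-figure realisation, and
`required_density()` returns the exact inverse
($2.14\times10^7$ CFU/mL).

## 2. The community simulator

`make_community()` draws species abundances from a log-normal
(sd(log) = 1.5 by default — a realistic skew for gut communities) and
splits each species among its strains with a symmetric Dirichlet
(α = 1). A configurable fraction of strains (default 20%) is forced
below $10^{-4}$ relative abundance, the "rare" regime (<0.01%) in which
bulk culture tends to lose lineages. Growth rates are uniform on
0.05–0.9 h⁻¹ per medium; rare strains draw from the lower half so they
are also slow growers. These defaults define the study conditions for
all tests; they are configuration, not fitted quantities.

`make_strain_genomes()` plants ground truth for the profilers: a
uniform-random ACGT reference per species, alternating ~900 bp coding
blocks reaching a target coding fraction (default 0.85), and per strain
Binomial(L, d) substitutions at uniform positions (default divergence
d = 0.01, the same-species regime). The planted variant lists are the
oracle for all SNV-recovery tests.

### Growth model

The incubation model is deliberately the simplest one that exhibits
competitive exclusion in bulk and its absence in droplets; no published
equations exist for this system, so the model is the package's own.
Every lineage $i$ grows logistically with a capacity shared among the
lineages of its compartment:

$$\frac{dN_i}{dt} = r_i N_i \left(1 - \frac{\sum_j N_j}{K}\right),$$

i.e. Lotka–Volterra with all competition coefficients equal. In
droplets the sum runs over the co-occupants of that droplet only and
$K$ is the droplet capacity (default 10⁴ cells, an order-of-magnitude
guess for ~14 pL; configurable). In bulk the sum runs over the whole
community with a vessel capacity (default 10⁹) and an inoculum of 10⁶
cells. Singly occupied droplets follow the closed-form logistic; mixed
droplets are integrated with `deSolve::ode`, once per distinct founder
composition. Zero-rate lineages keep their founding count. The default
horizon is 120 h with media labelled BHI and MRS, as configuration
defaults only.

Two consequences worth knowing when reading demo output:

* a rare strain profits from a droplet only if it can saturate it
  within the horizon, i.e. $r > \ln(K)/T \approx 0.077$ h⁻¹ at the
  defaults; slower strains decline in both formats, which the source
  system also reports for some taxa;
* at desk-scale droplet counts (10⁵ in the demo vs ~2×10⁸ in a real
  run) a $10^{-4}$ strain receives only ~3 founding cells, so stochastic
  dropout of ultra-rare strains is expected and is a faithful sampling
  effect, not a bug.

### Sequencing model

`sequence_to_pileup()` bypasses read simulation on purpose: per site,
depth is Poisson(mean coverage × species pool share) — plain Poisson
thinning — and each base is drawn from the within-species strain
mixture at that site, then flipped to one of the three other bases with
probability `error_rate` (strand-agnostic, uniform). This preserves
exactly the statistical structure the strain profiler assumes, which is
what read mapping would deliver downstream anyway. Marker counts for
the species profiler are Poisson with mean proportional to abundance ×
gene length / read length, so the length-normalised coverage estimator
is unbiased.

All stochastic operations derive a child seed from `(root seed,
operation label)` by a fixed hashing scheme (`derive_seed()`), so any
stage is bitwise reproducible regardless of call order.

## 3. Species profiling

Species coverage is the *mean* over a species' markers of
count × read length / gene length — the mean (rather than the sum) is
robust to unequal marker counts per species — normalised to relative
abundance per sample. Shannon diversity uses the natural log (the
common vegan convention; configurable by transforming the output);
Simpson is $1-\sum p^2$. Bray–Curtis and binary Jaccard distances come
from `vegan::vegdist`; the Jaccard presence threshold is strictly >0 by
default and configurable. PCoA is classical scaling
($B = -\tfrac12 J D^2 J$, eigendecomposition): negative eigenvalues are
dropped without Lingoes/Cailliez correction, axis proportions are taken
relative to the sum of positive eigenvalues, and an all-equal
(degenerate) matrix returns the available axes with a warning.

## 4. Strain profiling

The per-sample call at a site keeps the two most frequent bases (ties
broken by the fixed order A<C<G<T for determinism). Defaults — depth
≥5, minor allele frequency ≥0.05, minor count ≥2 — are deliberately
conservative desk-scale choices, exposed as arguments. The catalog
keeps sites with exactly two pooled alleles whose prevalence strictly
exceeds 5% of *covered* samples; using covered rather than all samples
as the denominator avoids penalising low-coverage samples. The
diversity statistic is (polymorphic coding catalog sites) / (coding bp
covered at the depth threshold) per sample; a total-length denominator
is available via `denominator = "total"`. Pileup positions are 1-based;
coding intervals follow the 0-based half-open BED convention; strand is
ignored because allele counts are strandless. Sample pairs are compared
by Jaccard distance over catalog sites covered in both, with an empty
union defined as distance 0 (with a warning).

## 5. Comparative genomics

**TETRA.** Overlapping 2/3/4-mers are counted on each contig plus its
reverse complement; z-scores use the second-order Markov expectation
$E = c_{123}c_{234}/c_{23}$ with its matching variance, zero where the
variance vanishes. Signatures are compared by Pearson correlation.
Uniform-random test genomes carry no higher-order signal, so
within-species correlations approach the published >0.99 regime only
when test genomes are generated with genuine 4-mer structure (the test
suite uses a skewed third-order Markov chain for this).

**ANIb.** Query genomes are cut into 1020 bp fragments; each fragment
is anchored by exact 15-mer seeds at fixed stride, requiring at least
two seeds agreeing on a diagonal band (±30 bp) before alignment —
random 100 kb genome pairs essentially never produce two consistent
seeds, which is what makes "no alignable fragments" the correct outcome
for unrelated genomes. Anchored fragments are aligned gapped
(match +1, mismatch −1, gap open −5, extend −2) and kept at ≥30%
identity over ≥70% of the fragment; ANI is the mean identity of kept
fragments. Both directions are reported and their mean is used for
classification; the 95% species threshold is inclusive (≥95 ⇒ same
species). Ambiguous bases are excluded from k-mer work and treated as
mismatches in alignment.

**Orthologs.** All-vs-all local alignment (BLOSUM62, gap −11/−1) with a
shared 5-mer prefilter; an edge requires alignment score / self-score
of the shorter protein ≥ 0.3. A normalised score replaces E-values
because E-values require database-size modelling; the threshold is a
flag. Inflation 1.0 is interpreted as plain connected components;
higher inflation is not implemented. Core clusters are those with every
genome represented.

**NJ.** Standard neighbour joining via `ape::nj`; negative branch
lengths are clamped to 0 with a warning, output is Newick.

## 6. Problem sizes and what the tests show

The default demo uses 5 species × 3 strains, 10⁵ droplets, 20 kb
genomes, 60× coverage, three replicates per medium — sizes chosen so
the full pipeline completes in a few minutes on one CPU while leaving
every statistical check well-powered. Monte-Carlo checks run at 10⁶
droplets; ANI properties use 50–100 kb genomes.

Passing tests demonstrate that the implementation is faithful to these
models and recovers planted truth under them. They do not show that the
models capture everything in real droplet metagenomics: there is no
read mapping or assembly, no chimeras, droplet merging or shrinkage, no
syntrophy or quorum-sensing dependence (droplets are sealed chambers —
lineages needing partners would fail in reality but grow here), no
strand bias or position-dependent sequencing error, and genome content
differences between strains (gene gain/loss) are not simulated — only
substitutions. Real marker databases, MIDAS internals and BLAST
E-value semantics are intentionally replaced by documented equivalents.
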