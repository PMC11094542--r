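---
title: "Models and methods behind crustassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crustassembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

crustassembly chains four quantitative analyses commonly applied to soil
(and in particular biocrust) microbiome surveys: eco-enzymatic
stoichiometry, abundant/rare community structure, phylogenetic null-model
community assembly, and RMT-thresholded co-occurrence networks. This
vignette explains each model, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical conventions adopted where the underlying literature is silent.

## Eco-enzymatic stoichiometry

Seven hydrolase activities are used: AG, BG, XS, CB acquire carbon, NAG and
LAP nitrogen, and AP phosphorus. Per sample the package computes the
log-ratio indices

* C:N = ln(BG) / ln(LAP + NAG)
* C:P = ln(BG) / ln(AP)
* N:P = ln(LAP + NAG) / ln(AP)

and the allocation vector with x = (BG + CB) / (BG + CB + AP),
y = (BG + CB) / (BG + CB + NAG + LAP), length = sqrt(x^2 + y^2) and
angle = atan(y / x) in degrees. A longer vector indicates stronger relative
carbon limitation; angles below 45 degrees indicate nitrogen limitation and
above 45 degrees phosphorus limitation. The quadrant classifier uses
(LAP + NAG)/AP against BG/(LAP + NAG) with reference lines at 1.

Conventions chosen where the formulas alone are ambiguous:

* The angle is the polar angle of the point (x, y) from the positive
  x-axis — the spreadsheet `ATAN2(X, Y)` convention. This makes a small x
  (relatively high AP allocation) give angles above 45 degrees, matching
  the phosphorus-limitation reading; a directional test pins this down.
* Ratios are undefined when any log argument is non-positive or a
  denominator activity is exactly 1; these raise errors rather than
  returning infinities.
* Z-scores use the population standard deviation (divide by n); a
  `bessel = TRUE` switch gives the sample version.
* Quadrant boundary values (axis exactly 1) fall into the
  non-carbon-limited class; the tie tolerance is configurable.

## Abundant and rare taxa

Mean relative abundance is taken across all samples of the *whole*
community (conversion to relative abundance always precedes any
subsetting). Taxa above 1% are abundant, below 0.1% rare, and the closed
interval between the cutoffs forms an explicit intermediate class so the
partition is total; both cutoffs are strict inequalities and configurable.
The copiotroph:oligotroph ratio sums relative abundances of ASVs whose
phylum maps to either life strategy; the shipped phylum map
(`default_strategy_map()`) is an editable stand-in for the literature-based
assignments, and unlisted phyla enter neither sum. A sample whose
oligotroph sum is zero gets a missing ratio, never an infinity.

## Community assembly (betaMNTD, betaNTI, Raup-Crick)

The between-community mean nearest taxon distance (betaMNTD) measures how
phylogenetically close each taxon in one sample is to its nearest relative
in the other. The incidence form pools the nearest-taxon distances of both
communities (the picante convention); the abundance-weighted form weights
them by within-sample relative abundance. The incidence form is the package
default: with ~100-taxon communities the weighted statistic is dominated by
one or two high-abundance taxa, which makes its null spread wide and blunts
the selection signal; the weighted form remains available via
`weighted = TRUE`.

betaNTI standardizes the observed betaMNTD against a taxa-shuffle null:
labels of the patristic distance matrix are permuted `n_null` times
(999 default) and betaNTI = (observed − null mean)/null sd. The default
shuffle scope is every tip of the supplied phylogeny, treating the tree as
the regional species pool; narrower scopes ("pool": taxa present in the
table; "union": each pair's own taxa) are available. The tree-wide default
matters: if the null can only rearrange taxa already in the community pair,
consistent selection of one clade is invisible to it. When the null spread
is zero (e.g. a star phylogeny, where the statistic is shuffle-invariant)
the pair is reported `undefined`, never 0.

The Raup-Crick score rebuilds each community of a pair `n_null` times at
its observed richness (taxa drawn with probability proportional to pool
occupancy, one individual each) and observed total reads (the remainder
distributed multinomially by pool-wide relative abundance), computes
Bray-Curtis between the null pair, and scales the observed value's position
to [−1, 1] with ties counted half.

The five-process partition applies the conventional thresholds: betaNTI
above +2 is heterogeneous selection, below −2 homogeneous selection;
otherwise Raup-Crick above +0.95 is dispersal limitation, below −0.95
homogenizing dispersal, and the rest undominated. Boundary values (exactly
±2 or ±0.95) fall in the non-selection / non-dispersal bands, and pairs
with undefined inputs are counted separately from the fractions, which are
normalized over defined pairs.

## Co-occurrence networks

Networks are built from Pearson correlations of ln(count + 1) (the
pseudo-count is configurable); ASVs constant after the transform carry no
signal and are excluded. The cutoff is chosen by a random-matrix-theory
scan: at each candidate threshold the spectrum of the hard-thresholded
matrix is unfolded (duplicate eigenvalues collapsed, cumulative spectral
density smoothed with a cubic spline), and the nearest-neighbour spacing
distribution is tested against the Poisson law e^(−s) by a chi-square
goodness-of-fit test (bins of width 0.1 up to s = 3, pooled to expected
counts of at least 5). The smallest threshold whose Poisson fit is not
rejected at 0.05 is selected — the point where correlated noise (Wigner-type
spacings) has been stripped and modular structure remains. The chi-square
test needs enough eigenvalues to have power; with fewer than roughly 100
taxa the scan can accept a threshold slightly below where a larger matrix
would settle, which is why the package's noise-stripping checks run at 200
taxa.

Topology metrics use the standard graph-theoretic definitions: average
degree 2E/N; mean local clustering with degree-<2 nodes contributing 0;
diameter and average path length on the largest connected component; Newman
modularity of the deterministic greedy agglomerative partition; and
relative modularity (Q − Q_null)/Q_null against degree-preserving
edge-rewiring nulls (100 by default, seeded). Modules are ranked by size
(module 1 = largest) and annotated with abundant/intermediate/rare
composition; modules with at least 5 nodes are flagged large.

Per-sample network complexity is a reconstruction choice (the source
literature plots per-sample complexity without defining it): each sample
induces the subgraph on its present ASVs; average degree, average
clustering and edge count are z-scored across samples (population SD;
properties constant across samples are dropped) and averaged into a
composite with mean 0. Complexity is then regressed on the enzyme C:N or
C:P ratio by ordinary least squares with a Pearson correlation test.

## The synthetic-data generator

The generator exists so every stage can be validated against known ground
truth. Its defaults are the package's reference study conditions: 20
samples, 100 taxa, 2000 reads per sample, a lognormal metacommunity
(sigma = 1.5, giving a small number of dominants over a long rare tail so
the 0.1%/1% partition is non-degenerate), and a unit-depth Yule phylogeny.
One run seed expands into fixed per-stage child seeds, so each stage is
individually reproducible.

Per-taxon environmental optima evolve by Brownian motion from a root value
of 0, with the tree's node depths raised to an exponent of 0.3 before
simulation (an early-burst / strong-conservatism transform). Plain Brownian
motion gives traits whose level sets are scattered across the tree, so an
environment filter would select a phylogenetically random set and no
phylogenetic assembly test could ever see it; concentrating trait variance
on deep branches makes trait neighbourhoods coincide with clades, which is
the premise of betaNTI-based inference.

Regime mechanisms, with each regime's detectability rationale:

* **Heterogeneous selection** — Gaussian niche filter
  exp(−s (optimum − env)^2) with s = 10, environments spread over the 5th
  to 95th percentiles of the realized optima, a lognormal demographic
  lottery (sd 1), and an establishment floor that zeroes filter values
  below 0.01 so no straggler reads from far-off clades appear. Different
  samples favour different clades, so observed turnover is phylogenetically
  broader than the null expects.
* **Homogeneous selection** — all samples share one environment matching
  the *derived optimum of a focal clade*: one mid-size clade (15-30% of
  taxa) carries a trait innovation of 5 sd on its stem (a jump placed on
  top of the Brownian motion), the filter is broad (s = 2), and an
  establishment lottery removes each taxon from each sample with
  probability 0.5. Replicate communities are then different subsets of the
  same clade: observed nearest-taxon distances are systematically shorter
  than the tree-wide null. Without the jump this regime is structurally
  undetectable — a trait window on a Brownian trait is not a clade — which
  is why the derived-niche model is part of the regime's definition here.
* **Dispersal limitation** — each sample's species pool is a contiguous arc
  of about 20% of the taxa on a randomized taxon ring, placed independently
  per sample. Arcs give the strong between-sample segregation that drives
  Raup-Crick toward +1 while remaining phylogenetically random (betaNTI
  stays in the null band). Uniform independent subsets would carry no
  segregation relative to the occupancy null and would be indistinguishable
  from chance.
* **Homogenizing dispersal** — one shared founding community is drawn from
  the metacommunity at 2.5x the sample depth and every sample is a
  multinomial draw from it. Samples are then more similar than the
  occupancy-based Raup-Crick null expects, pushing the score toward −1.
  Detectability requires per-sample richness to subsample the pool (the
  occupancy null must be able to miss dominants), which sets the 2000-read
  default depth.
* **Neutral** — samples are independent multinomial draws from the
  metacommunity. betaNTI is null-consistent by construction; note that
  independent draws from one metacommunity are, ecologically, perfectly
  mixed, so their Raup-Crick scores sit near the homogenizing end.

Soil variables are drawn around baselines typical of subtropical biocrust
topsoils with multiplicative lognormal noise. Enzyme scenarios fix the
expected allocation angle (exactly 45 degrees for `balanced`, about 38 for
`N`, about 52 for `P`) and jitter each activity multiplicatively; with the
default noise (sd 0.05) the per-sample classification margin is several
degrees.

What the generator does **not** emulate: sequencing error and chimeras,
compositional biases of extraction/PCR, spatially explicit metacommunity
structure, interaction-driven co-occurrence (network edges in synthetic
data arise from shared habitat responses and sampling, not direct
interactions), and realistic taxonomy (phylum labels are random draws from
a fixed 10-phylum list with a declared copiotroph/oligotroph split).
Passing tests therefore demonstrate correctness of the statistical
machinery under a known model, not field realism.

## Numerical choices and degenerate inputs

* All randomized procedures (null models, permutation tests, rewiring
  nulls, the generator) consume explicit seeds; pipeline stages derive
  child seeds from one run seed by fixed offsets.
* Permutation p-values use the add-one estimator
  (1 + #{null ≥ observed})/(1 + n_perm) and can never be 0.
* Ties in the Raup-Crick null count half, with a 1e-10 comparison
  tolerance.
* PCoA drops negative eigenvalues from the variance-explained denominator
  and truncates k with a warning when fewer positive eigenvalues exist;
  axis signs are arbitrary.
* Empty networks, samples with empty induced subgraphs, all-undefined
  assembly pairs, zero-variance vectors and zero-sum samples all raise
  errors or produce missing values explicitly rather than silently
  propagating NaN.
* Problem sizes in the test-suite (e.g. 6-tip trees for brute-force
  equivalence, 200-taxon matrices for spectral checks, 499 null draws for
  regime recovery) were chosen as the smallest sizes at which each
  statistical property is stable.

## Known limitations

* The RMT scan requires roughly 30+ taxa for its spectral statistics and
  can refuse (with an error) when every candidate threshold yields a
  degenerate spectrum.
* betaNTI magnitudes scale with community richness; at desk scale the
  homogeneous-selection signal depends on the clade-structured niche model
  described above.
* Relative modularity is defined against rewired nulls here; published
  tables using other (unstated) definitions are not comparable.
* The copiotroph/oligotroph map is a configurable stand-in, not a
  literature reproduction.
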