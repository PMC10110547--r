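---
title: "Methods: trait-based tropicalisation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-based tropicalisation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tropicalize)
```

This vignette is the package's account of its own methods: the models and
procedures, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical and design choices
made where the methodology left them open. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The scientific problem

As oceans warm, tropical reef fishes shift poleward into transitional and
temperate communities ("tropicalisation"). Whether that invasion proceeds
evenly across ecosystem functions — herbivory, predation, planktivory,
corallivory — and what controls its pace, are community-level questions.
The package operationalises them with three linked measurements along a
latitudinal gradient: a per-transect *tropicalisation footprint* for each
trait-defined functional group, the *leading edge* where each group's
footprint collapses 20-fold, and kernel-based *functional-niche* area and
overlap metrics that separate two candidate mechanisms — environmental
filtering (tropical niche contraction poleward) and competition with
resident temperate species (niche overlap).

## Community zonation

Sites are clustered into latitudinal community types from a site-by-species
matrix of `log(1 + mean transect biomass)` using Bray–Curtis dissimilarity
and UPGMA, then cut at a configured number of zones (default 6). Zones are
relabelled A, B, C, … in order of increasing mean absolute site latitude;
zone A — the lowest-latitude, coral-dominated community — is the reference
for all footprints.

Choices made where the procedure was open:

* **Zero handling in the log transform.** Biomass matrices contain
  legitimate zeros, so the transform is `log(1 + x)` — the standard guard —
  rather than a bare logarithm.
* **Empty-site pairs.** Bray–Curtis is undefined between two all-zero rows;
  the package emits a configurable sentinel (default 0) with a warning
  instead of propagating NaN.
* **Number of zones.** Zone count is an input, not estimated; the
  stability machinery (`bootstrap_stability()`) can be pointed at the site
  matrix to support the choice, but community zonation in transitional
  seascapes is ultimately a judgement call.
* **Representative zone latitude.** The mean of member-site absolute
  latitudes (configurable to min or max). Latitudes are stored signed;
  every gradient analysis uses absolute latitude so that both hemispheres
  share one poleward axis.

## Functional groups from mixed-type traits

Species are clustered on Gower distances over five traits: diet and habitat
association (nominal, 0/1 mismatch), body size and depth range
(log-transformed, range-scaled absolute difference), and aggregation
(ordinal). Missing trait values are never imputed: a trait missing in
either species of a pair is excluded and the mean renormalised over the
comparable traits. A trait with zero observed range contributes zero but
still counts as comparable. The ordinal trait is mapped to equally spaced
ranks — classic Gower ordinal handling.

Cluster-count selection uses a bootstrap stability profile: each iteration
drops 5% of species, recomputes Gower distances **scaled by the full-table
trait ranges** (so distances are comparable across iterations), re-clusters,
and records the bootstrap partition's mean silhouette width, the clusterwise
Jaccard match to the original partition (each original cluster matched to
its best bootstrap cluster, unweighted mean — Hennig-style), and the
unadjusted Rand index (the adjusted version is reported alongside).
`select_k()` implements an explicit stand-in for visual inspection: the
smallest k at a local silhouette maximum with mean Jaccard ≥ 0.75, falling
back to the silhouette argmax with a warning. The full profile is always
returned because no fixed rule reproduces expert inspection; the silhouette
is computed on the bootstrap partition (the natural choice when the
bootstrap tree is the object whose stability is in question).

Groups holding ≥ 2% of species are flagged "major" (configurable); group
characterisation reports within-group trait-level frequencies, with the
dominant diet and habitat levels flagged for naming groups.

## The tropicalisation footprint and its leading edge

For functional group *i* at transect *j*,
`BT_ij = b_ij / b̄_i`, where `b_ij` sums the biomass of the group's
tropical species on the transect and `b̄_i` is the mean of those totals over
**all** reference-zone transects — including transects where the group is
absent. Including zeros is deliberate: the reference mean is defined for
every transect, and excluding zeros would bias it upward and shrink every
footprint. Community rows use all tropical species regardless of group. By
construction the mean footprint over reference transects is exactly 1 for
every group — an invariant the tests assert.

Footprints are fourth-root transformed (variance-taming, zero-respecting)
and modelled within each non-reference zone as
`bt^(1/4) ~ group, random = ~1 | site` with the community total as the
baseline factor level, so each group coefficient *is* the tested departure
from the community expectation (α = 0.05). This baseline-level design is a
choice: the alternative — fitting groups only and testing against the
community post hoc — was rejected because it double-uses the community
data. Singular fits fall back to ordinary least squares with a warning. A
contrast that is zero to numerical precision is never flagged as a
departure, whatever its (equally degenerate) standard error implies. No
multiplicity correction is applied across zones (a Benjamini–Hochberg
option exists, off by default).

The leading edge is the first zone, scanning poleward, whose
back-transformed modelled mean falls below 0.05 (a 20-fold decline).
Classes relative to the community edge: same zone — or poleward of it —
is `as_expected`; one zone equatorward `below_expectation`; two or more
`well_below_expectation`; never crossing, `does_not_decline`
(excluded from driver models by default, mergeable on request). The
poleward case is folded into `as_expected` because a group outrunning the
community cannot meaningfully be "below expectation". Edge latitude is the
zone's representative latitude. A smaller threshold can never yield a more
equatorward edge — a monotonicity the tests exercise.

## Functional niches in trait space

The Gower matrix is embedded by principal coordinates analysis with the
Cailliez correction: when the double-centred matrix is not positive
semi-definite, the smallest constant c making all off-diagonal
dissimilarities Euclidean is added. The embedding comes from `ape::pcoa`;
the constant itself is recomputed from the standard 2n × 2n companion
eigenproblem (the two are cross-checked in tests by verifying the corrected
configuration reproduces input + c exactly). The first four axes are
retained and all six unordered axis pairs form 2-D functional spaces,
weighted by the summed variance fractions of their axes (weights normalised
to 1).

Within one plane, the niche of a guild at a site is the 99% utilisation
distribution of a product-Gaussian kernel over the guild's species points:

* **Bandwidth** per axis is the bivariate normal reference rule of kernel
  home-range estimation, `h = sd · n^(-1/6)`, with a scalar multiplier.
* **Grid**: 150 × 150 cells over the pooled two-guild extent padded by one
  bandwidth; both guilds of a site share one grid so masks intersect
  cell-exactly.
* **Isopleth**: the smallest set of highest-density cells whose summed
  probability reaches 0.99; area = cell count × cell area.
* **Minimum points**: 3 distinct species (home-range tools demand ≥ 5
  relocations; 3 keeps sparse high-latitude guilds estimable and is flagged
  in output). Below that the niche is *undefined* — flagged, never silently
  zero.

Overlap is the fraction of tropical niche cells also covered by the
temperate mask. Per-pair overlaps are averaged with the axis-pair weights,
and if any pair shows exactly zero overlap the site average is forced to
zero. Tropical niche area is also expressed relative to the group's
tropical area over the **pooled** reference-zone sites (the
environmental-filtering signal); the proportion may exceed 1 (a site richer
than the reference pool is possible) and is not clipped. Species enter
kernels unweighted; presence at a site means positive biomass on any of the
site's transects.

One behaviour worth knowing: at small point counts the kernel area is
dominated by the bandwidth halo and by outlying species, so losing species
does not automatically shrink a niche — the area contracts only when the
*spread* of the retained species contracts. This is a property of all
kernel home-range estimators at low n, not an implementation artefact; the
tests demonstrate contraction under filtering that removes functionally
marginal species first.

## Driver inference

Within groups, Kendall rank correlations relate site-level mean footprints
to niche metrics, after removing pairs with a zero footprint (which force
the niche metrics to zero too and would otherwise inflate the
correlation). Across groups and regions, each candidate driver is the
response in a model against the leading-edge class: gamma GLMs (log link)
for guild biomass maxima, quasi-binomial GLMs for overlap and area
proportions, quasi-Poisson for species richness, a linear model for the
realised upper thermal limit, and chi-square association tests (no
continuity correction; a note fires when expected counts fall below 5) for
diet, habitat position and region. Quasi-family inference uses
analysis-of-deviance F with Pearson dispersion — the conventional
counterpart of those families; the point estimates coincide with the
non-quasi fits, as a test asserts. Rows with undefined responses are
dropped per test; a response surviving in fewer than two classes skips that
test with a note. The battery is uncorrected for multiplicity by default,
with Benjamini–Hochberg values appended for optional use.

## The synthetic-community generator

The generator exists to make every downstream stage testable against known
truth. Its defaults define the reference study conditions: two regions
(one per hemisphere) × 30 sites × 4 transects, 300 species in 9 trait
archetypes, six contiguous 2° latitude zones spanning 23–35° absolute
latitude. Tropical biomass of group *i* declines exponentially
(log-linearly) with absolute latitude, parameterised by the latitude of its
20-fold decline relative to the reference-zone centre — so the leading edge
is an explicit simulation parameter. Temperate biomass rises exponentially
(0.15 per degree). Species occupancy windows are contiguous zone bands;
within a group the species most deviant from the trait archetype (by
Gower-style distance to the archetype) terminate one or two zones before
the group's edge, so environmental filtering removes functionally marginal
species first and tropical niche area genuinely contracts poleward.
Detection is abundance-dependent (rare species are missed more often, as in
visual surveys), per-transect group presence is Bernoulli with probability
collapsing beyond the group's edge (so zero-footprint transects occur and
the zero-removal and zero-forcing rules are exercised), and biomass noise
is lognormal per transect with a shared lognormal site effect. All
thinning and noise terms are mean-compensated, so the configured decline
profile is the *expectation* of the generated data; a regression test
verifies the fitted log-linear trend crosses 1/20 of the reference mean
within ±0.5° of the configured latitude.

Design decisions behind the default parameter values:

* **Decline latitudes** {33.2, 33.2, 33.2, 33.2, 25.3, 29.3, 29.3, 31.3,
  29.3}° sit clearly inside their zones, away from band boundaries,
  because a zone-resolved leading edge is only well-defined when the
  crossing is not at a boundary. Group base biomasses are dominated by the
  far-reaching groups, which places the community-level edge in the
  highest-latitude zone and yields all three expectation classes, matching
  the qualitative pattern such gradients show.
* **Noise levels** (transect lognormal σ = 0.25, site effect σ = 0.05,
  within-range occupancy ≈ 0.99) were fixed by a design-stage power
  analysis: they are the levels at which the zone-level mixed-model
  estimates resolve adjacent zones at roughly three standard errors given
  30 sites × 4 transects, so the configured truth is identifiable at the
  survey size the conditions prescribe. Real reef surveys are far noisier
  (transect-level coefficients of variation often exceed 100%); the
  generator's role is to validate machinery against known truth, and
  passing recovery tests therefore does **not** demonstrate performance at
  field noise levels.
* **Sites are stratified**: five per band, evenly spread with ±0.1°
  placement jitter, as a designed survey would space them. Random
  placement makes the reference-zone normaliser itself a large noise
  source, which degrades every footprint downstream.
* **Trait noise**: nominal traits deviate from the archetype with
  probability 0.02, sizes and depths are lognormal around the modal value
  (sdlog 0.12), aggregation takes ±1 steps with probability 0.1, and
  missingness defaults (depth range 3%, diet 0.2%) mirror the sparsity
  typical of curated reef-fish trait compilations.

What the generator does **not** emulate: ocean currents and temperature
fields, individual movement, phylogeny, seasonal turnover, observer bias
beyond abundance-dependent detection, or the heavy-tailed biomass noise of
real surveys. No generative model exists for the empirical system; all
distributional forms here are documented stand-ins.

## Numerical choices and degenerate inputs

* UPGMA ties are broken by input index order (the `hclust` convention), so
  partitions are reproducible; grouping is invariant to species row order.
* Gower errors on a species pair with no comparable traits, naming the
  pair; validation of survey and trait tables is total (row-numbered
  diagnostics, no silent coercion).
* `pcoa_cailliez()` errors when more axes are requested than positive
  eigenvalues (e.g. collinear configurations).
* Kernel niches are undefined — flagged, not zero — below 3 distinct
  points or at zero spread; an undefined tropical niche contributes no
  overlap row.
* Groups with zero reference-zone biomass are excluded from footprint
  analysis with a warning (their footprint is undefined).
* All generator randomness flows from one seed through fixed sub-streams,
  so identical configurations are byte-identical and the trait table is
  reproducible standalone.

## Problem sizes used by the test suite

The suite exercises the full default conditions (300 species, 60 sites)
where recovery is the claim under test, and smaller single-region
configurations (120 species, 18 sites), reduced bootstrap counts (20–30
iterations) and coarser kernel grids (60–100 cells) where the claim is
structural rather than statistical — sizes chosen to keep each property
checkable in seconds while leaving the statistical claims at full scale.

## Known limitations

* Kernel-UD areas at low species counts are bandwidth-dominated (see
  above); comparisons of areas across sites with very different richness
  should be read with care.
* `select_k()` cannot reproduce expert dendrogram inspection; it is a
  transparent default, and the stability profile should always be examined.
* The leading edge inherits the zonation: a mis-clustered zone moves the
  edge by whole zones, and zone labels (not latitudes) are the resolution
  of the statement.
* Quasi-likelihood F tests at very small group counts (the 16–18 rows of a
  two-region design) are approximate; the permutation-calibration test
  bounds the practical size distortion near 5%.
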