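---
title: "From glacier retreat to lake microbiome: the cryoflux methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From glacier retreat to lake microbiome: the cryoflux methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoflux)
```

cryoflux quantifies how a slowly retreating Antarctic glacier seeds the
microbiome of the perennially ice-covered lake it terminates in. The chain
has four quantitative links, each a module of this package: how fast the
ice front retreats and how much ice volume that sweeps into the lake
(`glacier_geometry`); what fraction of the glacier surface is covered by
cryoconite holes, the sediment-floored melt pits that concentrate microbial
biomass (`cryoconite_imaging`); how those two combine into a volumetric
flux of cryoconite material and its share of the annual melt and of the
lake volume (`flux_budget`); and what the amplicon sequence data say about
community structure and about which habitats actually act as sources for
the lake's benthic mats (`community_analysis`, `source_tracking`). A
generator module produces every input class with known ground truth, so
the whole chain is testable without any field data.

## Glacier geometry

A digitized glacier–lake boundary is an ordered list of pixel coordinates
with a scale in meters per pixel. Retreat between two epochs is measured
along the image y axis — the mean y of each boundary is taken and the
difference converted to meters — not along local boundary normals. This
matches how multi-decadal imagery is practically compared after
registration: the flow direction is aligned with the image axis, and the
generator orients its synthetic boundaries the same way. The retreat rate
is the mean offset divided by the year span.

Melt volume is the integral of lake depth over the region swept by the
boundary between two epochs. The true subaqueous shape of the ice front is
unknown, so two bracketing scenarios are computed: the boundary replaced by
its endpoint chord (an ice cliff meeting the lakebed as a straight wall)
and the digitized surface polyline extruded vertically. The reported value
is their mean, with half their range as the uncertainty. Integration is by
cell-center inclusion on the bathymetry raster: a cell contributes its full
area times its depth when its center falls inside the swept polygon. Grid
resolution controls the error; on a paraboloid basin with a closed-form
volume the numeric integral converges with observed order at least one in
cell size, and `exact = TRUE` additionally subsamples boundary cells when
the raster is coarse. `nodata` cells contribute zero with a warning, which
is the conservative choice for cells outside the surveyed basin.

## Cryoconite coverage

Surface images are contrast-stretched (percentile stretch, rank-preserving),
thresholded with global Otsu by default (the threshold is configurable
because drone mosaics with uneven illumination may need a fixed cutoff),
and the dark foreground is labeled with 8-connectivity. Components smaller
than 5 px are treated as noise; both choices are exposed. Each region is
summarized by the ellipse with the same second central moments as its
pixel set, and its roundness is

$$\mathrm{roundness} = \frac{4\,A}{\pi\, L_{\mathrm{major}}^2},$$

which is 1 for a disk, $b/a$ for an ellipse with semi-axes $a > b$, and
near 0 for thin bars. Only regions with roundness strictly greater than
0.6 count as cryoconite holes; this removes elongated dark features such
as moraine sediment bands, which would otherwise inflate coverage. A
variant formula with an additive denominator ($4A/(\pi + L^2)$) circulates
in some method descriptions; it is not scale-invariant and not bounded by
1, so cryoflux treats it as an audit option (`literal_plus`) rather than a
default. Coverage is computed per image and then aggregated per region as
mean and sample (n−1) standard deviation of percentages.

The scene generator paints near-circular holes (roundness ≥ 0.9 by
construction) totaling a requested area fraction — the last hole's radius
is chosen so the painted pixel count lands within 0.1 percentage points of
the target — plus elongated bars (aspect ≥ 4, roundness below the filter)
as moraine-like confounders, none touching. What passing tests show is
that segmentation plus the roundness filter recovers known planted areas
on high-contrast scenes; they do not show robustness to shadows, specular
ice, partial snow cover, or holes under thick ice lids, which real imagery
contains.

## Flux budget

The budget arithmetic is deliberately plain: a duration-weighted mean of
epoch retreat rates; each epoch's share of cumulative retreat (with a
fixed boundary length this is also its share of melt volume); the annual
melt as a percentage of lake volume; and the cryoconite volumetric flux

$$\Phi = c \cdot h \cdot \dot A,$$

with $c$ the coverage fraction, $h$ the cryoconite layer thickness
(default 0.01 m) and $\dot A$ the swept area per year, either supplied
directly or computed as weighted retreat rate times reference boundary
length. Low and high flux bounds use the lowest and highest regional
coverages with a single swept area; every report carries the inputs used.
The default lake volume is 0.872 km³.

## Community analysis

The pipeline starts at a denoised RSV table (RSV = ribosomal sequence
variant, synonymous with ASV); read processing and taxonomy assignment are
upstream and out of scope. Any RSV observed in a negative control is
removed from every sample — blank extractions flag reagent and handling
contaminants, and a contaminant's absence from some true samples is no
evidence of its authenticity in others. Alpha diversity (observed
richness, Shannon in natural log, inverse Simpson) is computed on raw
counts; no rarefaction is applied anywhere, but a diagnostic warning is
issued when library sizes span more than a 10-fold range, since unequal
depth then contributes to richness differences. Beta diversity is
Bray–Curtis on relative abundances, ordinated by classical scaling of the
Gower-centered matrix; negative eigenvalues are reported but excluded from
explained-variance proportions.

Group comparisons of alpha indices are gated by a Shapiro–Wilk test on
pooled within-group residuals at α = 0.05: ANOVA with Tukey HSD when
residuals look normal, Kruskal–Wallis with Dunn's tie-corrected post hoc
(Bonferroni-adjusted) otherwise. Groups with a single member are excluded
rather than tested. Differential abundance uses per-RSV two-sided
Mann–Whitney tests on relative abundances with Benjamini–Hochberg
adjustment; RSVs with constant relative abundance are reported as NA
rather than p = 1, so they do not dilute the adjustment. PERMANOVA
(`vegan::adonis2`) and ANOSIM run with a caller-supplied seed and are
bit-for-bit reproducible. Genus sharing collapses the table to per-habitat
genus presence sets and reports the full intersection lattice (disjoint
cells summing to the distinct-genus total) plus pairwise shared counts;
RSVs unassigned at the genus level are excluded by default because a
shared "unassigned" label is not evidence of a shared genus.

## Source tracking

The sampler is a collapsed Gibbs mixture over per-sequence source labels.
Each sink sequence $i$ of taxon $t_i$ carries a label $z_i$ over $J$ known
sources plus an Unknown source with no training data, updated by

$$P(z_i = v \mid z_{-i}) \propto
\frac{n_{t_i v} + c^{-i}_{t_i v} + \alpha_v}
     {N_v + C^{-i}_v + T\alpha_v}\,(C^{-i}_v + \beta),$$

with $n$ the fixed training counts (zero for Unknown), $c$ the current
sink assignment counts, $T$ the taxon count, $\alpha_v$ = 0.001 for known
sources and 0.1 for Unknown, and $\beta$ = 10 pseudocounts on the mixing
proportions — the canonical settings of the published algorithm, which
names no values for this study. Ten independent restarts each discard 100
burn-in sweeps and retain 25 draws thinned by 10; proportions are the
posterior mean assignment fractions averaged over restarts, and the
across-restart standard deviation is reported as Monte-Carlo spread.

Two design points deserve explanation. First, initialization: starting all
labels uniformly at random (Unknown included) hands the Unknown source a
quarter of the sink, from which it learns the sink's own composition and
then explains the data exactly as well as the true source — a
label-switching race that ends in arbitrary splits (observed: a sink
identical to a known source averaging ~0.5/0.5 against Unknown with
restart SD ≈ 0.25). cryoflux therefore starts every sequence on a known
source, drawn proportional to the sources' smoothed likelihoods, so
Unknown only accumulates sequences the known sources cannot explain; a
sink on taxa absent from all sources still goes ≥ 0.9 to Unknown within a
few sweeps. `init = "uniform"` restores the naive start. Second,
exchangeability: permuting the source order permutes the estimates, but
only to Monte-Carlo precision, not bit-for-bit — any categorical sampler
that walks a cumulative sum over a single RNG stream maps the same random
draws to different labels after reordering.

Sources are built by pooling all samples of a habitat (sum by default,
consistent with the no-rarefaction stance; rarefied pooling is a flag for
when one deep sample would otherwise dominate a habitat). Leave-one-out
validation holds out each source-labelled sample, rebuilds the pools, and
reports how much of it is assigned back to its own environment —
identical environments split evenly, which is the correct degenerate
answer.

## Synthetic data and what passing means

Every generator is a pure function of (seed, parameters); one master seed
fans out to per-generator substreams through a counter-based hash, so
adding a generator never perturbs the others. Library sizes are drawn
uniformly over 3,545–50,838 reads, the depth range typical of the amplicon
data this pipeline targets. Habitat base compositions are sparse Dirichlet
draws (concentration 0.3 over 300 RSVs) with per-sample
Dirichlet-multinomial noise at precision θ = 200 — distinct habitats, noisy
replicates. `share_profiles = TRUE` gives all habitats one base
composition for exchangeability checks. Sinks are multinomial draws from
stated mixtures of the habitat compositions plus a novel profile for the
residual Unknown fraction. Contaminant RSVs appear in negative controls
and are spiked into all samples; effect RSVs are fold-shifted in one
habitat, drawn from a configurable abundance band (default 0.002–0.01)
because a fold change planted on a near-zero-mass RSV is undetectable in
principle, while one planted on a dominant RSV perturbs the closed
composition enough that every other RSV shifts too.

Problem sizes in the default test suite are deliberately modest — 512 px
scenes, 300-RSV tables, 10-sink recovery runs, 199–999 permutations — and
the methods are exercised at those sizes; nothing in the implementation
depends on them. The differential-abundance recovery check runs at 100
RSVs and θ = 10,000: with 300 tests, the Benjamini–Hochberg rank-1
threshold (1.7e-4) lies below the smallest p-value an 8-vs-8 Mann–Whitney
approximation can produce (~9e-4), so no planted effect could ever be
declared at the larger table size — a useful reminder that FDR-controlled
discovery at small n is limited by the test's granularity, not by effect
size.

## Known limitations

The geometry module assumes registered, y-axis-aligned imagery and does
not perform registration; retreat along strongly curved fronts is not
captured by mean-y offsets. Coverage estimation has no illumination model
beyond the global threshold. The flux budget propagates only the
half-range and SD bookkeeping it is given, not full uncertainty. The
source tracker models taxon exchangeability within sources and will share
proportions arbitrarily among identical sources. Synthetic communities
have no phylogenetic structure, sequencing-error profile, or spatial
autocorrelation, so passing tests demonstrate correctness of the
computations on data matching the stated generative model, not robustness
to every artifact of real surveys.
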