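# cryoflux

Quantifying how a retreating glacier seeds the microbiome of the
ice-covered lake at its terminus.

Slow-retreating Antarctic glaciers deliver ice — and everything living on
and in it — directly into perennially ice-covered lakes. The most
biologically active part of that delivery is the cryoconite layer:
sediment-floored melt holes on the glacier surface that concentrate
microbial biomass. cryoflux implements the full quantitative chain for
glaciologists and microbial ecologists studying such systems:

1. **Glacier geometry** — terminus retreat rates from digitized
   glacier–lake boundaries, and swept melt volume by integrating a
   bathymetric grid over the region between two epoch boundaries, under
   two bracketing ice-front scenarios (endpoint chord vs. digitized
   polyline), reported as mean ± half-range.
2. **Cryoconite imaging** — fractional hole coverage from glacier-surface
   images: percentile contrast stretch, Otsu threshold, 8-connected
   components, ellipse-moment shape descriptors, and a roundness filter
   (keep regions with roundness `4A / (π L²) > 0.6`) that rejects
   elongated moraine sediment.
3. **Flux budget** — duration-weighted retreat rates, epoch shares of
   cumulative melt, and the cryoconite volumetric flux
   `Φ = coverage × thickness × swept area/yr` as percentages of annual
   melt and lake volume.
4. **Community analysis** — RSV/ASV tables: negative-control contaminant
   removal, alpha diversity (observed, Shannon, inverse Simpson; no
   rarefaction), Bray–Curtis + PCoA, Shapiro-gated ANOVA/Kruskal–Wallis
   with Tukey/Dunn post hocs, Mann–Whitney + Benjamini–Hochberg
   differential abundance, seeded PERMANOVA/ANOSIM, and habitat
   genus-sharing lattices.
5. **Source tracking** — a collapsed-Gibbs Dirichlet-multinomial sampler
   (Rcpp) apportioning each sink community among known source habitats
   plus an Unknown component:
   `P(z_i = v) ∝ (n_tv + c_tv + α_v) / (N_v + C_v + Tα_v) · (C_v + β)`.
6. **Synthetic data** — seeded generators for every input class with
   known ground truth (retreat rates, basin volumes, painted hole areas,
   source mixtures, planted contaminants and effects).

See `vignettes/glacier-lake-pipeline.Rmd` for the methods in detail.

## Worked example

Flux-budget arithmetic on the historical epoch inputs (rates in m/a,
volumes in m³):

```r
library(cryoflux)
ep <- epoch_rates(c(1939, 1995), c(1995, 2015), c(1.16, 5.76))
weighted_mean_rate(ep)   # 2.37 m/a long-term average
epoch_share(ep, 2)       # 63.9 % of the melt in the last 20 years
flux_budget(ep, coverage_low = 0.0173, coverage_high = 0.0636,
            swept_area_m2_per_a = 2.13e4, annual_melt_m3_per_a = 1.03e6)
#> Weighted retreat rate: 2.37 m/a
#> Cryoconite flux: 3.68 - 13.55 m3/a
#> Max flux = 0.00132% of annual melt, 1.55e-06% of lake volume
```

So the cryoconite contribution is bounded by a few to ~14 m³ per year —
about a millionth of the annual melt volume — yet source tracking below
shows its community is a disproportionate source for the lake.

End to end on a synthetic scenario with known truth:

```r
d <- file.path(tempdir(), "demo")
simulate_scenario(d, seed = 1, n_scenes = 2)  # boundaries, bathymetry,
                                              # scenes, community tables
cfg <- load_config()
cfg$scenario_dir <- d
cfg$outdir <- file.path(tempdir(), "demo_out")
s <- run_pipeline(cfg)

s$retreat_rates_m_per_a       # 1.160 5.760  (generator truth: 1.16, 5.76)
s$weighted_mean_rate_m_per_a  # 2.37
s$coverage_regions
#>      region n_images mean_pct  sd_pct
#> 1 interface        2     6.36  0.0040   (truth 6.36 %)
#> 2   moraine        2     1.73  0.0005   (truth 1.73 %)
s$n_removed_control_rsvs      # 7 — exactly the planted contaminants
s$anosim_r                    # 1, permanova p = 0.001
round(s$source_proportions[, c("cryoconite", "glacier_ice",
                               "terrestrial", "Unknown")], 3)
#>  0.446  0.263  0.193  0.074   (sink truth: 0.5, 0.3, 0.2, 0)
```

Every stage writes TSV/JSON outputs plus a `summary.json` under
`cfg$outdir`; reruns with the same config and seed are byte-identical.

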