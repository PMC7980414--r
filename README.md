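# srfoci

Quantifying the spatial organization of DNA double-strand-break repair
proteins at replication-associated damage foci, from single-molecule
localization microscopy (SMLM/STORM) data.

When a replication fork collides with a trapped topoisomerase lesion it
collapses into a single-ended double-strand break that must be repaired by
homologous recombination. SMLM imaging of such nuclei yields per-channel
tables of fluorophore localizations (x, y in nm): a nascent-DNA (naDNA)
channel marking replication domains, plus one or two immunolabeled repair
proteins. `srfoci` turns those tables into quantitative statements at
three scales:

1. **Is a protein at damage foci beyond chance?** Per nucleus, the
   colocalization ratio

   *R* = (real inter-channel cluster overlaps) / (mean overlaps after
   Monte Carlo re-placement of the protein's clusters uniformly within
   the nuclear ROI),

   so *R* = 1 is exactly chance-level overlap, and each nucleus is its
   own normalization for density, cluster size and nuclear geometry.
2. **Which proteins co-occupy a focus?** Per-focus presence calls for two
   costained proteins, summarized as both / A-only / B-only percentages
   and conditional-recruitment (dependence) scores.
3. **Are co-occupying proteins complexed?** Intensity-weighted
   center-of-mass distances *d* between the two protein subfoci of each
   three-color-positive focus, the histogram of *d* fitted with a one- or
   two-component Gaussian model (AICc-selected), components classified
   proximal (*mu* < 135 nm, consistent with a complex given labeling
   errors) or distal (up to 250–300 nm), and the fit expanded into a 2D
   association-distribution map
   *M(x, y) = sum_i w_i G(x; mu_i, s_i) G(y; 0, s_i)*.

A kinetics layer aggregates per-nucleus ratios over recovery time
(0–16 h) and conditions, with pooled two-sample t tests against undamaged
controls. Because no public SMLM dataset accompanies this analysis, the
package ships a synthetic-nucleus generator with an explicit labeling
error budget — localization precision 5–10 nm, rigid antibody displacement
10–20 nm per label, residual two-color mapping error 10–20 nm, Poisson
blinking (mean 8 localizations/molecule) — so every stage is testable
against known ground truth, including the dual-label baseline (one
species stained in two colors) that anchors the 135 nm proximal cutoff.

## Worked example

Simulate a small damage-and-recovery experiment (protein recruited to
foci at 1 h after damage, absent in controls), run Tier 1 and the
kinetics layer:

```r
library(srfoci)
cfg <- run_config(seed = 11)
design <- data.frame(condition = c("control", "CPT"), time_h = c(0, 1),
                     n_nuclei = c(10, 10), pA = c(0, 0.06))
cohort <- simulate_cohort(design, scene_params(proteins = "A",
                                               n_background = c(A = 30L),
                                               pB = 0), cfg)
tier1 <- run_tier1(cohort, cfg)
run_kinetics(tier1, cfg)
#>   condition time_h      metric mean    se  n p_vs_control significant
#> 1   control      0 ratio_count 1.49 0.501 10           NA       FALSE
#> 2       CPT      1 ratio_count 3.61 0.584 10       0.0131        TRUE
```

Control nuclei sit at chance level (ratio ~1, not significant); damaged
nuclei are enriched ~3.6-fold over their own randomizations (p = 0.013,
pooled t test vs control). Tiers 2 and 3 on a two-protein cohort:

```r
coh2 <- simulate_cohort(data.frame(condition = "CPT", time_h = 1,
                                   n_nuclei = 6),
                        scene_params(pA = 0.9, pB = 0.9,
                                     arrangement_mix = 0.6), cfg)
t3 <- run_tier3(coh2, cfg)
t3$fit
#> <distance_fit: n = 233, k = 2 components, bin 20 nm>
#>   weight   mean    sd
#> 1   0.51  24.19 18.44
#> 2   0.49 205.97 56.93
#>   proximal fraction (d < 135 nm): 0.541
t3$call
#> <proximity_call: mixed (w_prox 0.51, w_dist 0.49, cutoff 135 nm)>
```

The planted 60/40 proximal/distal mix is recovered as a two-component
fit: a proximal component at 24 nm (pairs in a complex, distance set by
labeling errors alone) and a distal one at 206 nm, called "mixed".
`plot(t3$fit)` draws the histogram with the fitted mixture;
`plot(t3$map)` draws the association map; `run_tier2()` gives the
per-focus presence table.

Real data enter through `read_localizations()` (delimited tables with a
column-mapping `loc_dialect()`, nm or camera-pixel units),
`read_roi()` (polygon vertices), and `fit_channel_map()` /
`apply_channel_map()` for polynomial two-color registration.

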