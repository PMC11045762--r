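# saxdev

Development of cortico-cortical functional connectivity along the
sensorimotor–association (S-A) axis.

`saxdev` is an R package for developmental neuroimaging connectomics. It asks
a specific scientific question: *does the way functional connectivity changes
with age across the cortex follow the cortical hierarchy?* The S-A axis
orders cortical regions from primary sensorimotor cortex (low ranks) to
transmodal association cortex (high ranks); the developmental hypothesis is
that connectivity of low-ranking regions strengthens through childhood and
adolescence while connectivity of high-ranking regions weakens, so the
spatial pattern of connectivity increasingly resembles the hierarchy itself.

The package provides a tested, reusable implementation of the full analysis
chain, exercised end-to-end on synthetic cohorts with planted hierarchical
age effects:

- **Connectivity metrics** — per-subject Pearson connectivity matrices from
  concatenated parcellated BOLD timeseries; regional FC strength (mean edge
  strength of a region to all others, signed / absolute / positive-only
  variants); between- and within-network connectivity; network-pair means;
  edge-level connectivity; optional parcel-level global signal regression.
- **Age models** — per-region GAMs, `y ~ s(age, k = 3) + sex + mean_fd`,
  thin-plate regression splines fit by REML (via mgcv). The age effect size
  is the change in adjusted R² between the full model and a reduced model
  with no age term (ΔR²adj), signed by the age slope of the equivalent
  linear model, with an F comparison for significance and
  Benjamini–Hochberg FDR across regions.
- **Axis tools** — derive an S-A-style axis by rank-averaging feature maps,
  parcellate unit-level axes, summarize ranks by network.
- **Spatial inference** — spin-based spatial permutation tests: uniformly
  random rotations of the spherical parcel geometry (mirrored across
  hemispheres, hemisphere-locked reassignment) build a null distribution for
  the Spearman/Pearson correlation between an effect map and axis ranks,
  `p_spin = (1 + #{|r_null| >= |r_obs|}) / (n_rot + 1)`.
- **Age-resolved alignment** — model-predicted FC strength on a 200-age grid,
  10,000 draws from each regional GAM's posterior, and the per-age median and
  95% credible interval of the across-region correlation with axis ranks.
- **Edge topography** — per-edge age effects and a symmetric tensor-product
  smooth of the signed effects over the pair of endpoint ranks
  (`effect ~ te(rank_1, rank_2)`), plus seed-based edge profiles.
- **Synthetic cohorts** — a generator that plants a hierarchy-aligned age
  effect in a factor model of parcel timeseries (plus age-confounded head
  motion) and records the ground truth, so every claim above can be tested
  against a known answer.
- **Pipeline** — `run_full_pipeline()` orchestrates QC (motion and scan-time
  exclusion), concatenation, metrics, models, alignment and edge analyses
  from one config, deterministically under a fixed seed.

## Worked example

```r
library(saxdev)

# a 100-parcel bilateral parcellation and a 300-subject cohort with a
# planted hierarchical age effect
parc <- make_parcellation(100, seed = 1)
sim  <- simulate_cohort(parc, n_subjects = 300, seed = 2)

# subject-level connectivity and regional FC strength
conn <- lapply(split(sim$runs$ts, sim$runs$subject_id),
               function(runs) connectivity_matrix(concat_runs(runs)))
conn <- conn[sim$cohort$subject_id]
metrics <- regional_metric_table(conn, parc, "fc_strength")

# per-region age effects with FDR
effects <- fit_age_effects(metrics, sim$cohort)

# alignment of the age-effect map with the S-A axis + spin test
eff_map <- effects$signed_effect[match(parc$parcel_id, effects$parcel_id)]
perms <- generate_spin_permutations(parc, n_rot = 1000, seed = 3)
spin_test_correlation(eff_map, parc$sa_rank, perms, method = "spearman")
#> # A tibble: 1 x 4
#>        r   p_spin method   n_rot
#>    <dbl>    <dbl> <chr>    <dbl>
#> 1 -0.992 0.000999 spearman  1000
```

The Spearman correlation of **-0.992** says the planted pattern was
recovered: regions low on the axis (sensorimotor) show positive age effects
and regions high on the axis (association) show negative ones, so the axis
rank explains essentially all of the variation in the simulated developmental
effects. The spin p-value of **0.000999** is the smallest value attainable
with 1,000 rotations — the observed alignment exceeded every
spatial-autocorrelation-preserving null. (Real cohorts in this literature
show the same sign with |r| around 0.6–0.7; the synthetic cohort is built
cleaner than nature.)

Plot helpers: `plot_alignment()`, `plot_trajectories()`,
`autoplot()` on an age-resolved result, and `plot_rank_surface()`.

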