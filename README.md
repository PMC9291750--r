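# dispersoc

Classify **social** and **spatial natal dispersal** in multi-level
fission-fusion societies from photographic mark-resight data.

In species whose stable social communities overlap in space — the
motivating system is a savanna giraffe metapopulation with ~12 adult-female
communities of 60-90 animals — a maturing animal can disperse *socially*
(switch to a different community while staying near its birth area),
*spatially* (move away while keeping its natal associations), both, or
neither. Distance alone cannot see the social component. dispersoc turns a
detection table (individual × sighting, with group, location, sex, age
class, height) into a four-level dispersal record per calf:

- an adult-female association network (simple ratio index, gambit of the
  group) partitioned into communities by weighted-modularity maximization;
- per-calf community timelines (majority vote over the adult females in
  each group) classified by temporal rules: permanent post-weaning switch =
  social dispersal, excursions with return = exploratory visits;
- net displacement vs. age against a community-specific threshold, the
  radius of the mean adult-female 95% kernel home range
  (r = sqrt(A/π)), with a local-linear smoothed-crossing confirmation that
  separates true dispersal from *sorties* (single-occasion excursions);
- photogrammetric ageing by inverting a von Bertalanffy growth curve,
  anchored on each animal's young detections;
- the statistical stage: mixed logistic sex-difference models
  (community random intercept), a four-level multinomial dispersal-type
  model with AICc model ranking, Akaike weights, relative risk ratios and
  observed-value-averaged predicted probabilities, Welch/Wilcoxon
  utilities, and count-table summaries.

A synthetic-society simulator (`simulate_society()`) generates detection
tables with planted community memberships, dispersal fates, ages and
sorties, so every stage is testable end to end without field data.

## Worked example

```r
library(dispersoc)

cfg <- sim_config(n_communities = 4, members_per_community = c(14, 16),
                  n_calves = 30, seed = 11)
soc <- simulate_society(cfg)
soc
#> <society>
#>   3186 detections of 60 adults + 30 calves in 4 communities

an <- run_dispersal_analysis(soc$detections, seed = 1)
an
#> <dispersal_analysis>
#>   30 calves classified against 4 communities (Q = 0.618)
#>
#>    none  social spatial    both    <NA>
#>      10       7       3       9       1

an$thresholds
#> # A tibble: 4 x 5
#>   community n_members mean_area_km2 threshold_km imputed
#>       <int>     <int>         <dbl>        <dbl> <lgl>
#> 1         1        14          110.         5.93 FALSE
#> 2         2        16          120.         6.19 FALSE
#> 3         3        14          115.         6.04 FALSE
#> 4         4        16          113.         5.98 FALSE

summarize_types(tidy(an))$by_sex
#> # A tibble: 2 x 4
#>   sex   n_total n_dispersed prop_dispersed
#>   <chr>   <int>       <int>          <dbl>
#> 1 F          15           6          0.4
#> 2 M          14          13          0.929
```

Each community's threshold sits near 6 km because each simulated adult
female's 95% home-range isopleth is ~115 km² (5.991πσ² with σ = 2.5 km),
and sqrt(115/π) ≈ 6.05 km. Of 30 calves, 19 dispersed in some form and one
was undetermined (too few assigned detections); comparing
`tidy(an)$dispersal_class` with `soc$truth$fate` shows 90% agreement with
the planted fates on this small society (97% at the default 12-community
scale). Fitted objects follow broom conventions (`tidy()`, `glance()`),
and `autoplot()` methods cover displacement series and predicted
probability curves.

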