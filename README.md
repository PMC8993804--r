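# rhizotrace

Belowground carbon accounting for ¹³C/¹⁴C pulse-labeled cropping systems.

Deep-rooted perennials such as lucerne (*Medicago sativa*) and kernza
(*Thinopyrum intermedium*) move freshly assimilated carbon into soil as
**rhizodeposits** — exudates, mucilage and sloughed root cells — whose fate
decides whether that carbon is respired away or stabilized in soil organic
matter. Field experiments quantify this with repeated ¹³CO₂/¹⁴CO₂ pulse
labeling followed by depth-stratified sampling of roots, rhizosphere soil
and bulk soil. `rhizotrace` implements the full desk side of such an
experiment for isotope ecologists and agroecosystem scientists:

* **Isotope conversions** — δ¹³C/δ¹⁵N (vs VPDB / air-N₂) ↔ atom percent,
  atom% excess over unlabeled backgrounds, ¹⁴C activity excess (Bq g⁻¹).
* **Tracer mass balance** — per depth interval, the percent of belowground
  tracer lost via rhizodeposition and the net rhizodeposited C (and N):

  ```
  %ClvR = 100 · ¹⁴C_soil(rhizosphere + adjusted bulk) /
                (¹⁴C_bulk + ¹⁴C_rhizosphere + ¹⁴C_root)

  net rhizodeposition = %ClvR · root C / (100 − %ClvR)
  ```

  with the bulk-soil pool adjusted for unrecovered root fragments washed
  from a soil subsample, and optional conversion of mg kg⁻¹ concentrations
  to Mg ha⁻¹ stocks.
* **Compound-specific isotope probing** — correction of biomarker δ¹³C for
  derivatization carbon (two-pool mixing), instrument offset/drift/amount
  effects (least squares on co-analyzed standards), ¹³C incorporation per
  compound, and carbon-weighted pool summaries for PLFA (living microbial
  biomass), amino sugars (necromass) and amino acids.
* **Relative microbial stabilization (RMS)** —
  `RMS = log₁₀(weighted APE_AS / weighted APE_PLFA)`; RMS > 0 means tracer
  is entering the persistent necromass pool rather than short-lived
  biomass.
* **Treatment statistics** — Fligner-Killeen and Shapiro–Wilk assumption
  checks with an automatic log transform, crossed-factor ANOVA, Tukey HSD
  with compact letter display, and the fertilizer-subplot merge rule for
  kernza at 100 vs 200 kg N ha⁻¹.
* **A forward simulator** of the whole labeled experiment (plots ×
  species × depths, dose schedule following the 5 mL per 20 cm plant-height
  rule, lognormal measurement noise) that carries its ground truth, so
  every stage can be tested against known answers.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe; results have `tidy()`/`glance()` methods and
ggplot2 `autoplot()`/`plot_*()` builders.

## Worked example

```r
library(rhizotrace)
library(dplyr)

# simulate the default field design: 3 plots x {lucerne, kernza-100N,
# kernza-200N} x 4 depth intervals, with 5 % measurement noise
sim <- simulate_tracer_experiment(scenario_config(seed = 1))

run <- run_rhizo_pipeline(sim$samples, sim$biomarkers)

run$partition |>
  group_by(species, depth_top_cm, depth_bottom_cm) |>
  summarise(clvr = mean(clvr_percent),
            net  = mean(net_rhizo_c_mg_per_kg), .groups = "drop") |>
  filter(species == "lucerne")
#> # A tibble: 4 × 5
#>   species depth_top_cm depth_bottom_cm  clvr   net
#>   <chr>          <dbl>           <dbl> <dbl> <dbl>
#> 1 lucerne            0              25  10.2  63.6
#> 2 lucerne           25              50  11.9  31.8
#> 3 lucerne           50             100  14.1  20.1
#> 4 lucerne          100             150  16.5  11.6
```

About 10–16 % of the belowground tracer is recovered in soil rather than
roots (`clvr`), rising with depth, which translates into 12–64 mg net
rhizodeposited C per kg soil given the simulated root C profile. The RMS
stage summarizes where that carbon ends up microbially:

```r
run$rms |>
  filter(species == "lucerne", defined) |>
  group_by(depth_top_cm) |>
  summarise(rms = mean(rms))
#> # A tibble: 4 × 2
#>   depth_top_cm    rms
#>          <dbl>  <dbl>
#> 1            0 -1.17
#> 2           25 -0.906
#> 3           50 -0.729
#> 4          100 -0.538
```

Negative values say the tracer sits mostly in living biomass (PLFA); the
monotone rise with depth mirrors the configured increase in necromass
allocation — deeper soil stabilizes a larger share of rhizodeposits.
`plot_depth_profile(run$partition, "net_rhizo_c_mg_per_kg")` and
`autoplot(run$rms)` draw the corresponding profiles.

Because the simulation carries its truth, you can check the pipeline
end to end:

```r
noise_free <- simulate_tracer_experiment(
  scenario_config(seed = 1, noise_cv = 0, delta_noise_sd = 0))
part <- partition_rhizodeposition(noise_free$samples)
max(abs(part$clvr_percent - noise_free$truth$true_clvr_percent))
#> [1] 1.776357e-15
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the mass-balance
model and its assumptions, the correction chain for compound-specific
δ¹³C, the RMS index and its interpretation limits, what the synthetic
generator does and does not emulate, and the package's numerical choices.
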