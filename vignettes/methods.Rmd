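---
title: "Methods: tracer mass balance, biomarker probing, and the RMS index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracer mass balance, biomarker probing, and the RMS index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizotrace)
library(dplyr)
```

`rhizotrace` computes net rhizodeposition and the microbial fate of
rhizodeposited carbon from dual ¹³C/¹⁴C (plus ¹⁵N) pulse-labeling field
data. This vignette explains the models the package implements, the
assumptions behind them, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## Isotope arithmetic

δ notation is converted to atom percent with the exact mixing form
$AP = 100\,\frac{R(\delta/1000+1)}{1+R(\delta/1000+1)}$, where $R$ is the
heavy/light ratio of the reference standard. The package fixes
$R_\mathrm{VPDB} = 0.0111802$ for carbon and $R_\mathrm{air} = 0.0036765$
for nitrogen; both are ordinary `iso_standard` objects and can be replaced.
Enrichment is always a *difference*: atom% of the labeled sample minus
atom% of its unlabeled counterpart (atom% excess, APE), or for radiocarbon
the difference of activities in Bq g⁻¹ dry sample. ¹⁴C stays on the
activity scale throughout — the mass balance only ever uses activity
differences and their ratios, so no decay correction or specific-activity
conversion is needed or attempted.

Below-background (negative) excess is preserved and flaggable via
`flag_below_background()`, never silently truncated, so that sums of pools
remain additive. The one place a clamp exists is the fragment-adjusted bulk
pool (below), where a negative value is physically impossible and indicates
measurement noise; there the clamp is explicit, logged, and switchable
(`clamp = FALSE`).

## The tracer mass balance

For each plot × species × depth interval the compartment pools are

* bulk soil: excess activity (Bq g⁻¹) × the full quantity of soil sampled,
* rhizosphere soil: excess activity × rhizosphere dry mass,
* roots: excess activity × root dry mass,
* unrecovered root fragments: fragments are washed from a *subsample* of
  the bulk soil, so their tracer content is scaled to the whole sample by
  the soil-mass ratio.

Fragments are roots that ended up in the bulk-soil pool; the bulk pool is
therefore *adjusted* by subtracting the fragment content, and the fragment
content is counted on the root side. The percent of belowground tracer
lost via rhizodeposition and the net rhizodeposition are

$$\%ClvR = 100\;\frac{^{14}C_{rhizo} + {}^{14}C_{bulk,adj}}
  {^{14}C_{bulk,adj} + {}^{14}C_{rhizo} + {}^{14}C_{root} + {}^{14}C_{frag}},
\qquad
Net = \frac{\%ClvR \times root\,C}{100 - \%ClvR}.$$

With this denominator the soil share and the root share sum exactly to the
total recovered tracer, so the identity $Net/(Net + rootC) = \%ClvR/100$
holds to machine precision — this mass-conservation identity is asserted in
the tests at $10^{-12}$. A `strict_literal = TRUE` mode reproduces the
printed form of the denominator (raw bulk + rhizosphere + root including
fragments); because the raw bulk pool still contains the fragment tracer,
that form double-counts fragments and yields a slightly smaller %ClvR. The
package computes both on request and treats the conserving form as the
default; the choice matters at the percent level only when fragment pools
are large.

The nitrogen analog substitutes mg ¹⁵N excess (APE × compartment N mass)
for ¹⁴C activity pools and is otherwise the same algebra; when the relative
¹⁵N pool proportions equal the ¹⁴C proportions the two %ClvR values agree
exactly, which is one of the acceptance checks.

Everything is computed per plot first and only then averaged across plots
(n = 3 in the emulated design); raw readings are never pooled across
plots. Area stocks (Mg ha⁻¹) are obtained from concentrations as
`conc × bulk density × thickness × 10⁻⁴`, verified in tests against an
explicit unit expansion.

**Assumptions.** Sampling recovers the relevant pools at each depth;
backgrounds measured on unlabeled field material are representative per
depth and compartment; isotope readings are linear in pool content. "Net"
rhizodeposition is what remains recoverable at sampling — no root turnover
or gross-flux model is implied.

## Compound-specific corrections

Biomarker δ¹³C arrives as derivative measurements. Two corrections apply in
a fixed order:

1. **Instrument model** (offset, linear drift per run index, linear
   amount dependence against log peak amount), fitted by least squares to
   co-analyzed standards of known δ. The amount term uses the simplest
   standard form — linear in log(amount) — because only the existence of
   the effect, not its shape, is established practice.
2. **Derivatization dilution**: the derivative is a two-pool mixture of
   analyte and reagent carbon, inverted on the δ scale as
   $\delta_a = ((n_a+n_d)\delta_m - n_d\delta_r)/n_a$. An exact
   atom-fraction-scale mode exists; at natural-abundance reagent values the
   two agree to well under 0.01 ‰, and the δ-scale linear form is the
   default, as is standard in compound-specific work.

Reagent δ¹³C values are required inputs with no default — they are
laboratory-specific and unpublishable defaults would be silently wrong.
Per-compound analyte carbon counts, added-carbon counts and molar masses
ship in `biomarker_reference()` (FAME +1 C for PLFAs, aldononitrile
acetates +8 C for hexosamines and +6 C for muramic acid, +5 C for
amino-acid derivatives). These counts are package choices — the derivative
chemistry is protocol-dependent — and any user table with the same columns
can be supplied instead. Carbon mass fractions are computed from the
analyte molar mass.

Pool membership is fixed: amino sugars are GlcN, GalN, MurN, ManN; amino
acids are the 11-entry panel (alanine, Asx, Glx, glycine, isoleucine,
lysine, phenylalanine, Pro/Thr, serine, tyrosine, valine); anything else in
those classes is rejected. Pools aggregate per sample as total
concentration, total analyte C, total ¹³C incorporation, and the
carbon-weighted APE = 100 × total ¹³C excess / total C. An empty class is
an *absent pool*, not a zero — downstream indices mark it undefined.

## The RMS index

$$RMS = \log_{10}\frac{\overline{APE}_{AS}}{\overline{APE}_{PLFA}}$$

compares how much of the incorporated tracer sits in microbial necromass
residues (amino sugars) versus living biomass membranes (PLFA). RMS > 0:
necromass-dominated, the more stabilized fate; RMS < 0: biomass-dominated,
a short-lived pool. The index is *comparative only* — across depths and
species — and says nothing about absolute stability of the carbon.

The log base is 10 by default and configurable; it is recorded in every
output row so values are never compared across bases silently. RMS is
undefined when either pool is absent or its weighted APE is at or below
background; such rows carry `defined = FALSE` and a reason string, never a
silent NaN. The amino-acid pool is reported (root exudate quality) but by
construction never enters RMS. Depths below 100 cm are computed when pools
exist but tagged `in_reported_range = FALSE`, since the emulated design
reports the index for 0–100 cm.

## The synthetic experiment

`scenario_config()` + `simulate_tracer_experiment()` forward-simulate the
field design: three replicate plots of lucerne and kernza at 100 and
200 kg N ha⁻¹, four depth intervals (0–25, 25–50, 50–100, 100–150 cm),
repeated ¹³C/¹⁴C-CO₂ pulses whose solution volume follows the 5 mL per
20 cm plant-height rule (26 pulses growing from 10 to 110 cm by default),
and a trace ¹⁵N addition. Belowground tracer at each depth splits
root : rhizodeposit as $(1-f) : f$ with $f$ the per-depth true ClvR
fraction; rhizodeposits split bulk : rhizosphere 3:1; 5 % of root tracer
sits in unrecovered fragments; biomarker ¹³C splits between amino sugar and
PLFA pools by the per-depth necromass fraction, which fixes the true RMS.

Defaults the design had to choose (the emulated study reports totals, not
fractions) are documented as illustrative: true ClvR fractions
0.10/0.12/0.14/0.16 and root C 600/250/120/60 mg C kg⁻¹ by depth — chosen
so that whole-profile net rhizodeposition sits near one-eighth of root C,
the magnitude reported for deep-rooted perennials; belowground allocation
40 % of the assimilated dose with depth weights 0.50/0.25/0.15/0.10;
background δ¹³C −27 ‰ (C3 soil), δ¹⁵N +5 ‰, ¹⁴C background 0.1 Bq g⁻¹;
necromass fractions 0.35/0.50/0.60/0.70 rising with depth.

Noise reflects how the two instrument families err: masses, concentrations
and activities get multiplicative lognormal noise with mean 1 and CV
`noise_cv` (default 0.05); δ values get additive Gaussian noise
(`delta_noise_sd`, default 0.15 ‰). Each plot draws from its own RNG
substream derived from the seed, so adding plots does not reshuffle
existing ones, and the caller's RNG state is untouched.

**What passing tests show — and what they do not.** The generator writes
its truth before noise, so noise-free runs must invert exactly and noisy
runs must recover truth statistically; the test suite asserts both. But the
simulation is an idealization: backgrounds are exactly representative,
compartment separation is perfect, noise is independent across rows, and
allocation fractions are parameters rather than plant physiology. Passing
against it validates the *arithmetic and statistical machinery*, not field
recovery rates. One quantitative caveat is worth stating: %ClvR is a ratio
of noisy pool sums, and a plug-in ratio estimator carries a positive
second-order bias of order the squared pool CV (≈ +1 % relative at 10 %
measurement noise, since each pool multiplies two noisy measurements). At
realistic replication this bias is far below measurement scatter, but a
large enough Monte Carlo can resolve it; it is a property of the estimator
the field uses, not of this implementation.

## Statistical stage

Assumption checks follow the conventional workflow: Fligner-Killeen for
variance homogeneity across factor-level groups and Shapiro–Wilk on
residuals; if either rejects at α = 0.05 the response is log-transformed
(an error with advice if values are non-positive). ANOVA is a fixed-effects
crossed-factor `aov()`; subplots are averaged to plot means before analysis
(the merge rule below), making the plot the experimental unit — whether the
original workflow used a plot random effect is not stated anywhere, and the
fixed-effects-on-plot-means reading is the simplest consistent one. Tukey
HSD provides pairwise comparisons; compact display letters come from an
insert-absorb pass over the significant-pair matrix (ties broken by group
mean order) and are cross-checked against `multcomp::cld()` in the tests.

The kernza fertilizer rates (100/200 kg N ha⁻¹) are subplots within field
plots: when no requested variable differs between them (paired t-test by
plot and depth, α = 0.05), subplot values are averaged within plot and
labeled plain `kernza`; otherwise the table is returned unchanged with a
per-variable report. The operation is idempotent.

## Numerical choices and limitations

* Tolerances: δ ↔ atom% round trips hold to 10⁻¹⁰ ‰ over δ ∈ [−900, 10000];
  dilution forward-then-correct to 10⁻⁹ ‰; the mass-balance identity to
  10⁻¹². These are asserted, not aspirational.
* Degenerate inputs: zero recovered tracer is an error naming the sample
  (a 0/0 %ClvR has no meaning); negative adjusted bulk clamps to 0 with a
  warning; %ClvR ≥ 100 is rejected before the net-rhizodeposition division.
* Problem sizes in the tests and the acceptance script — 200 Monte-Carlo
  replicates for parameter recovery, 2000 null simulations for the type-I
  calibration, 300-point property sweeps — were chosen as the smallest
  sizes at which the Monte-Carlo error is comfortably below the effects
  being checked.
* The package does not model gross rhizodeposition, root turnover, shoot
  mass balance, chromatographic peak processing, or any of the sequencing
  side of such experiments.
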