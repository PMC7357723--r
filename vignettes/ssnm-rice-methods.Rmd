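---
title: "Field-specific nutrient management for irrigated rice: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-specific nutrient management for irrigated rice: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssnmrice)
```

## The problem

Rice fields in intensive Asian irrigated systems are small and variable in
indigenous nutrient supply, yet fertilizer advice is usually a uniform
blanket dose for a whole region. Site-specific nutrient management (SSNM)
replaces the blanket dose with a per-field calculation: a realistic target
yield for *this* field and season, an N rate sized to the targeted yield
gain, and P and K rates derived from a nutrient input–output balance. This
package implements that calculation for the Cauvery Delta double-rice
system (seasons *kuruvai*, *samba*, *thaladi*), together with the
economics and balance accounting used to evaluate it on farm.

## Target yield

The engine starts from the farmer's reported historical yield $Y_h$ and a
varietal baseline window $[B_{lo}, B_{hi}]$ supplied by local expertise:

$$Y_t = \mathrm{clamp}(Y_h + \Delta,\; B_{lo},\; B_{hi}) - \pi_{late},$$

bounded below by $Y_h$ and above by $Y_h + \Delta_{max}$. Defaults:
increment $\Delta = 1.0$ Mg ha⁻¹, cap $\Delta_{max} = 2.5$ Mg ha⁻¹. The
lateness penalty $\pi_{late}$ applies only where a season defines a
cutoff; the shipped calibration penalizes kuruvai crops established after
15 June by 0.4 Mg ha⁻¹ and leaves samba and thaladi without a cutoff,
matching the deployed behaviour (a cutoff can be configured for any season
as an opt-in, since late thaladi establishment demonstrably depresses
yield). The penalty value itself is not published; 0.4 Mg ha⁻¹ is our
calibration, recovered from the season's mean historical (4.8) and mean
target (5.4) yields given that every kuruvai trial was transplanted late.
The exact deployed target-yield table is not public either, which is why
increment, window, cutoff and penalty are all configuration rather than
code.

## Rate equations

**Nitrogen (yield gain).** $FN = 1000\,(Y_t - Y_{0N})/AE$, with $AE$ the
agronomic efficiency (kg grain per kg N; the calibration uses 15 in
kuruvai and 14 in the two rainy seasons, inside the tool's 14–15 range)
and $Y_{0N}$ the yield without fertilizer N. $Y_{0N}$ is rarely known
per field, so it defaults to $Y_t - g$ with a configured attainable gain
$g$ (1.8 Mg ha⁻¹ kuruvai, 1.82 elsewhere); a direct estimate can be passed
when available.

**Phosphorus (full maintenance).** $FP = Y_t\,(c^{grain}_P + f\,c^{straw}_P)$,
where $f = 1$ if straw is removed and $1 - r$ (retention efficiency
$r = 0.8$) on residue-retained fields. Achieving the target therefore
closes the P balance at exactly zero — the defining property of full
maintenance.

**Potassium (partial maintenance).**
$$FK = \max\{0,\; Y_t\,(c^{grain}_K + c^{straw}_K) - K_{irr} - K_{res} + \Delta K\},$$
with irrigation input $K_{irr}$ = 25/8/4 kg ha⁻¹ per season (from a mean
tube-well water K concentration of 2.6 mg L⁻¹), residue input
$K_{res}$ = previous yield × $c^{straw}_K$ × $r$ on residue-retained
fields, and targeted drawdown $\Delta K$ = −30/−33/−4 kg ha⁻¹. When the
floor is not hit, the realized K balance at target achievement equals
$\Delta K$ identically — the property the test suite checks across
thousands of simulated fields.

**Removal coefficients.** The deployed coefficients are not published, so
they were calibrated once against the published per-season rate and target
means and then frozen as configuration: $c^{grain}_P = 2.2$,
$c^{straw}_P = 0.39$, $c^{grain}_K = 2.25$, $c^{straw}_K = 13.5$ kg per Mg
grain. The straw share of K (86%) sits at the top of the 80–85% range
typical of rice, and the P total (2.59 kg Mg⁻¹) is within the usual
2.5–3 range. These are parameters, never literals in logic; a user with
local uptake data should override them.

**Rounding.** Nutrient rates round to 1 kg ha⁻¹, scheduled doses to
0.5 kg ha⁻¹ (largest-remainder repair so splits conserve totals exactly),
product masses to 0.1 kg internally and 0.5 kg in the rendered hand-out —
all halves away from zero. Farmers weigh fertilizer in practical units;
the cost of the 1-kg rate grid is a balance residual of at most
±0.5 kg ha⁻¹, which is why the balance-identity tests use an inclusive
half-kilogram tolerance.

## Scheduling

Panicle initiation is placed by subtracting a fixed
reproductive-plus-ripening offset (65 d) from the variety's in-field
duration (total duration minus seedling age for transplanted crops). The
early dose sits at day 7 (always within the required 11 days) and active
tillering midway between early dose and PI, rounded down. Both the offset
and the early day are configuration: the deployed stage arithmetic is not
published, and these defaults have the property that a 110-day variety
transplanted with 25-day seedlings — the typical kuruvai case — puts PI at
day 20, correctly triggering the documented switch from the 24/38/38 N
distribution to three equal doses (the switch is strict: PI at exactly
30 d keeps 24/38/38). The blanket reference schedule is fixed: 150 kg N
and 42 kg K ha⁻¹ in four equal splits, 22 kg P ha⁻¹ basal.

## Product allocation

The early application satisfies P *exactly* with the first P-bearing
product in the farmer's stated preference order, counts that product's N
and K contributions, fills remaining K with the farmer's K source (muriate
of potash otherwise) and tops up remaining N with urea — the top-up is
floored at zero when a compound source oversupplies N. Later applications
are urea for N and muriate of potash for K, by rule. This is deliberately
*not* least-cost blending: the deployed policy fixes source roles, and the
package reproduces that policy. Elemental contents use the standard grade
conversions (P = P₂O₅ × 0.436, K = K₂O × 0.830); the shipped catalog can
be replaced by any CSV with the same columns.

## Economics and balances

Per field: total fertilizer cost = product bags (price per 50 kg) plus
9.5 US$ ha⁻¹ labor per application; PFP = 1000·GY/FN (undefined, and
signalled, at FN = 0); gross return above fertilizer cost = GY × 222
US$ Mg⁻¹ − cost; added net benefit = difference in gross return between
two treatments on the same field. Summaries compute per field first and
average second. Exceedance curves are empirical and *inclusive*
(P(ANB ≥ t), ties exceed), making the loss probability exactly
1 − P(ANB ≥ 0); the published description of the risk curves does not fix
the tie convention, so the inclusive one is committed here for
determinism. Balances account fertilizer, irrigation-water K and residue
K against crop removal at the achieved yield, with the same coefficients
as the rate equations (single source of truth); irrigation water carries
no P, and pathways other than crop removal (leaching, volatilization,
manure) are out of scope by design.

## The synthetic population generator

`sample_population()` emulates the *structure* of the on-farm trial
populations: per-season field counts (14/40/20), truncated-normal
historical yields (means 4.8/4.8/4.4, SD 0.8/0.8/0.6, ranges matching the
interviewed populations), sowing windows (8–23 Jun, 28 Aug–30 Sep,
8 Oct–18 Nov), residue retained only in thaladi, farmer's-practice rates
drawn from wide uniform ranges (N 95–150, P 8–34, K 20–80 kg ha⁻¹) so that
both under- and over-application occur, and a yield response
$\min(a Y_t,\; Y_{0N} + AE\cdot FN/1000) + \varepsilon$ with seasonal
attainment $a$ = 0.98/0.91/0.67 and noise SD 0.4 Mg ha⁻¹. Truncated
normals are drawn by rejection (exact at these sizes); everything is
deterministic under the spec's seed.

What the generator does *not* emulate: soil heterogeneity, the yield
effects of N-timing quality and zinc that separated farmer practice from
the engine's recommendation in the real trials, within-season weather, or
spatial correlation. Passing tests on these fixtures therefore
demonstrates the internal consistency of the engine (identities,
conservation, monotonicity, determinism) and its agreement with the
published calibration points — not field performance.

## Numerical and degenerate-input choices

* Dates are calendar dates; day 0 is the establishment day.
* Interviews are validated at construction with field-level messages;
  historical yields outside 3.0–8.0 Mg ha⁻¹ are rejected as implausible.
* A growth duration too short to place PI after the early dose is an
  error, as is a seedling age at or beyond the variety duration.
* The K-rate floor at zero breaks the drawdown identity by construction;
  the balance tests only assert the identity away from the floor.
* `exceedance_curve` requires a non-empty sample; empty treatment pairs
  in the evaluation pipeline produce a warning and a skipped output, not
  a failure.

## Problem sizes

The shipped tests run the full pipeline over populations of roughly a
thousand simulated fields (about three seconds), the calibration checks on
single fields, and the property suites on grids of a few hundred parameter
combinations — sizes chosen to exercise every branch while keeping the
suite quick to run during development.

## Known limitations

Zinc is a fixed 25 kg ha⁻¹ zinc-sulfate line item, not a diagnosed rate.
Target yields ignore establishment date outside kuruvai by default
(configurable), ignore weather and irrigation-supply forecasts, and the
baseline windows ship as illustrative per-season varietal defaults in the
generator rather than a maintained varietal database. The K drawdown
policy is a short-term economic optimum; nothing here simulates long-term
soil-K trajectories. The economics assume a single support price and
exclude all non-fertilizer costs, which is valid for treatment comparisons
within a field but not for whole-farm budgeting.
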