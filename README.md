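# ssnmrice

Field-specific fertilizer recommendations for irrigated rice, built on
site-specific nutrient management (SSNM) principles as calibrated for the
Cauvery Delta (Tamil Nadu, India) double-rice system. The package is for
agronomists and extension tools that need to turn a short pre-season farmer
interview into a dated, product-level fertilizer plan, and for researchers
evaluating such recommendations against a blanket regional dose (BFR) or the
farmer's own practice (FFP) in on-farm trials.

## The method

For one field the engine computes, in order:

1. **Target yield** `Y_t` — the farmer's reported historical yield plus a
   fixed increment (default +1.0 Mg ha⁻¹), clamped into the baseline yield
   window of the selected variety, reduced by a penalty when the crop is
   established after the seasonal cutoff (kuruvai, after 15 June), never
   below the historical yield and never more than 2.5 Mg ha⁻¹ above it.
2. **N rate** by the yield-gain approach:
   `FN = 1000 · (Y_t − Y_0N) / AE`, where `Y_0N` is the yield without
   fertilizer N and `AE` the agronomic efficiency of applied N
   (14–15 kg grain per kg N).
3. **P rate** by full maintenance: fertilizer P equals estimated crop P
   removal at the target yield, so achieving the target closes the soil P
   balance at zero.
4. **K rate** by partial maintenance:
   `FK = max(0, K_removal(Y_t) − K_irrigation − K_residue + ΔK)`, where
   `ΔK` is the targeted (negative) soil-K drawdown — −30/−33/−4 kg K ha⁻¹
   in kuruvai/samba/thaladi — and irrigation water supplies 25/8/4 kg K ha⁻¹.
5. **Schedule** — three applications: early (≤ 11 days after establishment,
   24% of N plus all P and 50–58% of K), active tillering (38% of N) and
   panicle initiation (38% of N plus the remaining K); three equal N doses
   when panicle initiation falls earlier than 30 days after establishment.
6. **Products** — event rates become masses of the farmer-selected
   commercial sources (DAP, MOP, SSP, compound fertilizers), with urea
   topping up N, scaled to the field area.

Companion modules compute trial economics — total fertilizer cost (products
plus 9.5 US$ ha⁻¹ labor per application), partial factor productivity
`PFP = 1000 · GY / FN`, gross return above fertilizer cost at the 222
US$ Mg⁻¹ support price, added net benefit and exceedance-risk curves — and
post-hoc P/K input–output balances, plus a synthetic trial-population
generator for testing.

## Worked example

```r
library(ssnmrice)
iv  <- read_interview(system.file("extdata", "interview_example.json",
                                  package = "ssnmrice"))
rec <- recommend(iv)
rec
```

```
FIELD-SPECIFIC FERTILIZER RECOMMENDATION (rice)
Field: demo-001   Season: kuruvai   Area: 0.50 ha   Variety: ADT 43
Crop established: 2014-07-05
Target yield: 5.4 Mg/ha
Fertilizer rates: N 120, P 14, K 30 kg/ha (elemental)

DAE   Stage                Product        kg (field)
7     early                DAP                  35.0
7     early                MOP                  16.5
7     early                urea                 30.0
13    active_tillering     urea                 43.5
20    panicle_initiation   urea                 43.5
20    panicle_initiation   MOP                  13.5

Fertilizer cost: 44.91 US$ (products 30.66 + labor 14.25)
```

The historical yield of 4.8 Mg ha⁻¹ plus the 1.0 increment, minus the 0.4
late-transplanting penalty, gives the 5.4 Mg ha⁻¹ target. The 1.8 Mg ha⁻¹
targeted gain at AE 15 gives 120 kg N ha⁻¹; P removal at the target gives
14 kg P ha⁻¹; K removal minus 25 kg irrigation K and the 30 kg allowed
drawdown gives 30 kg K ha⁻¹. The 110-day variety transplanted with 25-day
seedlings puts panicle initiation at day 20 (< 30), so N goes out in three
equal 40-kg doses; the 0.5-ha field halves every product mass. Closing the
loop:

```r
b <- estimate_balance(rec$rates, rec$target_yield,
                      default_season_params("kuruvai"), iv$prev_residue)
b
#> P balance:    0.0 kg/ha  (fertilizer 14 - removal 14.0)
#> K balance:  -30.1 kg/ha  (fertilizer 30 + irrigation 25 + residue 0.0 - removal 85.1)
```

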